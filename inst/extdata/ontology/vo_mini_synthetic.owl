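<?xml version="1.0"?>
<!-- Hand-constructed miniature influenza-vaccine hierarchy (synthetic
     subset for tests and examples; ids with the 91 block are invented,
     VO_0000047 / VO_0001236 / VO_0000001 are the well-known identifiers). -->
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/VO_0000001">
    <rdfs:label>vaccine</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/VO_9100000">
    <rdfs:label>influenza vaccine</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_0000001"/>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/VO_0001236">
    <rdfs:label>trivalent influenza vaccine</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_9100000"/>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/VO_9100006">
    <rdfs:label>inactivated influenza vaccine</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_9100000"/>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/VO_9100005">
    <rdfs:label>live attenuated influenza vaccine</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_9100000"/>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/VO_9100001">
    <rdfs:label>Fluarix</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_0001236"/>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_9100006"/>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/VO_9100002">
    <rdfs:label>Fluvirin</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_0001236"/>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_9100006"/>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/VO_0000047">
    <rdfs:label>Fluzone</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_0001236"/>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_9100006"/>
  </owl:Class>
  <owl:Class rdf:about="http://purl.obolibrary.org/obo/VO_9100004">
    <rdfs:label>FluMist</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_0001236"/>
    <rdfs:subClassOf rdf:resource="http://purl.obolibrary.org/obo/VO_9100005"/>
  </owl:Class>
</rdf:RDF>
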