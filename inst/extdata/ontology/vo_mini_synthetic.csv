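id,label,parents
VO_0000001,vaccine,
VO_9100000,influenza vaccine,VO_0000001
VO_0001236,trivalent influenza vaccine,VO_9100000
VO_9100006,inactivated influenza vaccine,VO_9100000
VO_9100005,live attenuated influenza vaccine,VO_9100000
VO_9100001,Fluarix,VO_0001236|VO_9100006
VO_9100002,Fluvirin,VO_0001236|VO_9100006
VO_0000047,Fluzone,VO_0001236|VO_9100006
VO_9100004,FluMist,VO_0001236|VO_9100005
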