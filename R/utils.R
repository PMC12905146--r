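#' @keywords internal
"%||%" <- function(x, y) if (is.null(x)) y else x

# Empty-string and NA are both "no value" in CSV-born records.
is_blank <- function(x) {
  is.null(x) | is.na(x) | (is.character(x) & !is.na(x) & trimws(x) == "")
}

# Scalar version tolerating NULL / length-0.
blank1 <- function(x) {
  if (is.null(x) || length(x) == 0) return(TRUE)
  isTRUE(is_blank(x[[1]]))
}

#' Run code with a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so seeded
#' generators do not perturb the session RNG stream.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# CURIE-style ontology identifier, e.g. VO_0001236 or GO:0006955.
looks_like_curie <- function(x) {
  is.character(x) && length(x) == 1 && !is.na(x) &&
    grepl("^[A-Za-z][A-Za-z0-9]*[_:][A-Za-z0-9_.-]+$", x)
}

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty CSV (no header): ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    na.strings = character()),
    error = function(e) stop("malformed CSV ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  # read.csv silently recycles ragged rows; detect them explicitly.
  nfield <- utils::count.fields(path, sep = ",", quote = "\"", blank.lines.skip = TRUE)
  if (length(unique(nfield)) > 1) {
    bad <- which(nfield != nfield[1])[1]
    stop("malformed CSV (ragged row) in ", path, " at line ", bad, call. = FALSE)
  }
  df
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# Deterministic zero-padded id maker: id_seq("SUBJ", 3) -> SUBJ0003
id_seq <- function(prefix, i, width = 4) {
  sprintf("%s%0*d", prefix, width, i)
}
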