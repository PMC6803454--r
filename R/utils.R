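## Internal helpers shared across modules.

## Classed error constructor so callers can test on condition class
## (e.g. "duplicateIdError") rather than matching message text.
mStop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "metannotError")))
}

## Locale-independent ordering; all deterministic writers sort with this.
ordC <- function(...) order(..., method = "radix")

sortC <- function(x) x[ordC(x)]

## Fixed float formats used in every report writer so that identical inputs
## produce byte-identical outputs: depths/abundances at 4 decimals, e-values
## with 1 significant digit.
fmtDepth <- function(x) sprintf("%.4f", x)
fmtEvalue <- function(x) sprintf("%.1e", x)

## Parameter hash for resumable stages: canonical JSON of the relevant
## config subset, digested with the file-based md5 from tools (no external
## digest dependency).
paramHash <- function(x) {
  ord <- function(v) {
    if (is.list(v)) {
      v <- v[sortC(names(v))]
      lapply(v, ord)
    } else v
  }
  txt <- jsonlite::toJSON(ord(x), auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(txt), tf)
  unname(tools::md5sum(tf))
}

## Write lines with "\n" endings regardless of platform.
writeLinesC <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
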