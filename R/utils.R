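# Internal helpers shared across modules.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes, in alphabetical order. All
#' peptides, patterns and antigen sequences in this package are strings over
#' this alphabet (patterns additionally use `.` as a single-position
#' wildcard).
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`; the global
# RNG state is restored afterwards so callers' streams are not disturbed.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a deterministic sub-seed (< 2^31) from a master seed and a stage
# label, so each pipeline stage has its own reproducible stream.
seed_stream <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 131 + c) %% 1000000007
  as.integer((as.double(seed) %% 2147483629 * 7919 + h) %% 2147483629 + 1)
}

# Byte-order (C locale) string sort, for deterministic output ordering.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
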