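# Internal helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a 32-bit safe stream seed from a master seed and an index.
# Stable across platforms; keeps per-genome randomness independent of
# generation order.
#' @noRd
derive_seed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647  # 2^31 - 1
  s <- (as.double(seed) %% m)
  # two rounds of a multiplicative-congruential mix; products stay < 2^53
  s <- (s * 48271) %% m
  s <- (s + as.double(index) * 69621) %% m
  s <- (s * 16807) %% m
  as.integer(s)
}

# Deterministic JSON writer used by every module that emits results.
#' @noRd
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# Deterministic TSV writer (no quoting surprises, fixed NA string).
#' @noRd
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @noRd
read_tsv_file <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    na.strings = "", check.names = FALSE)
}

# Case-insensitive fixed substring match of any keyword against a string
# vector; returns logical vector over x.
#' @noRd
matches_any_keyword <- function(x, keywords) {
  x <- tolower(x)
  out <- rep(FALSE, length(x))
  for (kw in tolower(keywords)) {
    out <- out | grepl(kw, x, fixed = TRUE)
  }
  out
}
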