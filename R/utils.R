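#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation: mixes an integer master seed with any
# number of integer stage/replicate indices into a seed in [1, 2^31 - 2].
# Multiplier kept small so every intermediate product stays exactly
# representable in a double (< 2^53).
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  m <- 2147483647
  x <- 0
  for (i in ids) {
    x <- (x * 69069 + (abs(i) %% m) + 12345) %% m
  }
  as.integer(x %% (m - 2L) + 1L)
}

# Normalize genus labels for panel matching: strip a GreenGenes-style rank
# prefix ("g__"), surrounding whitespace and brackets, and case-fold.
normalize_genus <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("^g__", "", x)
  x <- gsub("^\\[|\\]$", "", x)
  tolower(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == round(x) && x >= 0

# Full-precision numeric formatting used by all table writers so that
# write -> read round-trips reproduce values to ~1e-16 and identical inputs
# yield byte-identical files.
format_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}
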