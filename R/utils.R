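# internal helpers shared across modules

# Normalize numeric text from spreadsheet-style exports: unicode minus signs,
# surrounding whitespace, and scientific-notation variants ("2.08E-08").
# Returns a numeric vector with NA where parsing fails.
parse_numeric <- function(x) {
  x <- as.character(x)
  x <- gsub("−|–", "-", x)       # unicode minus / en-dash
  x <- gsub("[[:space:],]", "", x)
  suppressWarnings(as.numeric(x))
}

# Uppercase, trim, drop empties; used for every symbol vector entering the
# package so set operations are always on a single case convention.
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[!is.na(x) & nzchar(x)]
}

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stop_direnrich <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# log-sum-exp over a vector of log-values; stable for long tails
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
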