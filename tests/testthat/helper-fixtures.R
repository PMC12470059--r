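# shared fixtures and independent oracles

# random scored table for property tests
random_scored <- function(n, seed, p_missing = 0.05) {
  withr::with_seed(seed, {
    de <- de_table(sprintf("R%04d", seq_len(n)),
                   log2fc = round(rnorm(n, 0, 2), 3),
                   padj = {
                     p <- runif(n)
                     p[runif(n) < p_missing] <- NA
                     # force score ties via duplicated (lfc, padj) pairs
                     p
                   })
    score_and_classify(de)
  })
}

# O(n^2) selection-sort oracle for the ranking order, written against the
# stated tie rule rather than against order(): a beats b if s is larger,
# then padj smaller, then |log2fc| larger, then symbol earlier; untested
# (NA s) records always lose, and sort among themselves by symbol.
brute_force_rank <- function(records) {
  beats <- function(i, j) {
    si <- records$s[i]; sj <- records$s[j]
    if (is.na(si) && is.na(sj)) return(records$symbol[i] < records$symbol[j])
    if (is.na(si)) return(FALSE)
    if (is.na(sj)) return(TRUE)
    if (si != sj) return(si > sj)
    if (records$padj[i] != records$padj[j]) return(records$padj[i] < records$padj[j])
    ai <- abs(records$log2fc[i]); aj <- abs(records$log2fc[j])
    if (ai != aj) return(ai > aj)
    records$symbol[i] < records$symbol[j]
  }
  idx <- seq_len(nrow(records))
  out <- integer(0)
  while (length(idx)) {
    best <- idx[1]
    for (j in idx[-1]) if (beats(j, best)) best <- j
    out <- c(out, best)
    idx <- setdiff(idx, best)
  }
  records[out, , drop = FALSE]
}

# independent upper-tail oracle (different code path: stats::phyper)
fisher_oracle <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

# enumerate every 2x2 table with total M
all_tables <- function(M) {
  g <- expand.grid(a = 0:M, b = 0:M, c = 0:M)
  g <- g[g$a + g$b + g$c <= M, , drop = FALSE]
  g$d <- M - g$a - g$b - g$c
  g
}

# synthetic stand-in universe + target sets realizing given (n, a) counts
# against an Up partition of size K inside a background of size M
counts_fixture <- function(M, K, spec) {
  syms <- sprintf("U%05d", seq_len(M))
  up <- syms[seq_len(K)]
  u <- universe(syms, up, character(0), alpha = 0.05)
  sets <- lapply(names(spec), function(nm) {
    n <- spec[[nm]]["n"]; a <- spec[[nm]]["a"]
    gene_set(nm, c(up[seq_len(a)], syms[(K + 1):(K + n - a)]),
             regulator_direction = "down")
  })
  names(sets) <- names(spec)
  list(universe = u, sets = sets)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
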