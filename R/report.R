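fmt_sig3 <- function(x) {
  ifelse(is.na(x), "NA", format(signif(x, 3), scientific = x < 1e-3,
                                trim = TRUE))
}

#' Render a human-readable enrichment report
#'
#' Lays out one row per test with display rounding: OR and CI to 2 decimals,
#' p and q to 3 significant figures. Machine outputs (TSV/JSON written by
#' [run_pipeline()]) keep full precision; rounding happens only here.
#'
#' @param results An `enrichment_result` (or NULL/empty).
#' @return Character vector of report lines.
#' @export
render_report <- function(results) {
  if (is.null(results) || nrow(results) == 0L) return("no tests run")
  rows <- vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    if (r$filter_status != "tested") {
      sprintf("%-28s %9d %11d %s", r$set, r$n, r$a,
              paste0("[not tested: ", r$filter_status, "]"))
    } else {
      sprintf("%-28s %9d %11d %6.2f  [%.2f, %.2f]  %s  %s",
              r$set, r$n, r$a, r$odds_ratio, r$ci_low, r$ci_high,
              fmt_sig3(r$p), fmt_sig3(r$q))
    }
  }, "")
  c(sprintf("%-28s %9s %11s %6s  %-14s %-9s %s",
            "Target Set", "Size (n)", "Overlap (a)", "OR", "95% CI",
            "p", "q (BH)"),
    rows)
}
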