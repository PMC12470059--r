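#' Exclude marker genes from a universe
#'
#' Removes the union of the supplied marker-panel symbols from the
#' background and both direction partitions, yielding the marker-excluded
#' universe used in composition-confounding sensitivity re-tests. With empty
#' panels the universe is returned unchanged.
#'
#' @param universe A `universe`.
#' @param panels List of `gene_set` objects (marker panels), a single
#'   `gene_set`, or a character vector of symbols.
#' @return A `universe` with the markers removed.
#' @export
exclude_markers <- function(universe, panels) {
  stopifnot(inherits(universe, "universe"))
  if (inherits(panels, "gene_set")) panels <- list(panels)
  syms <- if (is.character(panels)) normalize_symbols(panels) else
    unique(unlist(lapply(panels, `[[`, "symbols")))
  bg <- setdiff(universe$background, syms)
  if (length(bg) == 0L) {
    stop_direnrich("background is empty after marker exclusion")
  }
  universe(bg, setdiff(universe$up, syms), setdiff(universe$down, syms),
           universe$alpha)
}

#' Default neuron/glia stratum map from marker panels
#'
#' Genes in the neuron panel are assigned to the `"neuron"` stratum; genes in
#' the union of the astrocyte/microglia/oligodendrocyte/endothelial panels to
#' `"glia"`; genes in both are left unassigned (ambiguous), as are all other
#' genes. This operationalizes a neuron-enriched vs glia-enriched background
#' split by marker membership; supply your own map to override.
#'
#' @param panels Named list of `gene_set` marker panels; the neuron panel is
#'   identified by a name matching `"neuron"` (case-insensitive).
#' @return Named character vector mapping symbol to stratum label.
#' @export
default_strata <- function(panels) {
  nm <- tolower(vapply(panels, `[[`, "", "name"))
  is_neuron <- grepl("neuron", nm)
  neuron <- unique(unlist(lapply(panels[is_neuron], `[[`, "symbols")))
  glia <- unique(unlist(lapply(panels[!is_neuron], `[[`, "symbols")))
  both <- intersect(neuron, glia)
  neuron <- setdiff(neuron, both)
  glia <- setdiff(glia, both)
  c(setNames(rep("neuron", length(neuron)), neuron),
    setNames(rep("glia", length(glia)), glia))
}

#' Split a universe into per-stratum universes
#'
#' Each stratum's universe is the original background/up/down intersected
#' with the genes assigned to that stratum; unassigned genes are excluded
#' from every stratum. Strata with no up and no down genes are flagged
#' untestable (returned with an `untestable` attribute) rather than dropped.
#'
#' @param universe A `universe`.
#' @param strata Named character vector mapping symbol to stratum label, or a
#'   two-column data.frame (symbol, stratum).
#' @return Named list of `universe` objects, one per stratum label.
#' @export
stratify <- function(universe, strata) {
  stopifnot(inherits(universe, "universe"))
  if (is.data.frame(strata)) {
    strata <- setNames(as.character(strata[[2]]),
                       normalize_symbols(strata[[1]]))
  } else {
    names(strata) <- normalize_symbols(names(strata))
  }
  labels <- sort(unique(unname(strata)))
  out <- lapply(labels, function(lb) {
    syms <- names(strata)[strata == lb]
    bg <- intersect(universe$background, syms)
    if (length(bg) == 0L) return(NULL)
    u <- universe(bg, intersect(universe$up, syms),
                  intersect(universe$down, syms), universe$alpha)
    attr(u, "untestable") <- (u$K_up == 0L && u$K_down == 0L)
    u
  })
  names(out) <- labels
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0L) {
    stop_direnrich("no stratum intersects the universe background")
  }
  if (!any(vapply(out, function(u) u$K_up > 0 || u$K_down > 0, TRUE))) {
    stop_direnrich("every stratum lacks up/down genes; nothing is testable")
  }
  out
}

# verdict for one (primary, variant) pair of enrichment rows
.verdict <- function(pri, var) {
  need <- c("odds_ratio", "ci_low", "ci_high")
  if (any(is.na(unlist(pri[need]))) || any(is.na(unlist(var[need])))) {
    return("untestable")
  }
  lp <- log(pri$odds_ratio)
  lv <- log(var$odds_ratio)
  if (lp == 0 || lv == 0 || sign(lp) == sign(lv)) {
    # same direction: attenuated when the variant point estimate falls
    # outside the primary CI on the side toward OR = 1
    toward_one <- if (lp > 0) var$odds_ratio < pri$ci_low
                  else var$odds_ratio > pri$ci_high
    if (isTRUE(toward_one)) "attenuated" else "consistent"
  } else {
    excludes_one <- var$ci_low > 1 || var$ci_high < 1
    if (excludes_one) "reversed" else "attenuated"
  }
}

#' Direction-consistency report across enrichment re-runs
#'
#' Compares a primary enrichment run against named sensitivity variants
#' (marker-excluded, per-stratum, ...) test by test. Verdicts:
#' `consistent` — log-OR signs agree and the variant point estimate stays
#' within (or beyond) the primary CI; `attenuated` — signs agree but the
#' variant estimate falls outside the primary CI on the side toward 1, or
#' the sign flips without the variant CI excluding 1; `reversed` — sign
#' flips and the variant CI excludes 1; `untestable` — a statistic is
#' missing (filtered set, empty stratum cell).
#'
#' @param primary An `enrichment_result`.
#' @param variants Named list of `enrichment_result` objects covering the
#'   same test (set) names.
#' @return A `consistency_report` data.frame: one row per (variant, test)
#'   with both ORs/CIs and the verdict.
#' @export
consistency_report <- function(primary, variants) {
  stopifnot(is.data.frame(primary), is.list(variants))
  if (is.null(names(variants)) || any(!nzchar(names(variants)))) {
    stop_direnrich("variants must be a named list")
  }
  rows <- list()
  for (vn in names(variants)) {
    v <- variants[[vn]]
    if (!setequal(v$set, primary$set)) {
      stop_direnrich("variant '%s' tests different set names than the primary run", vn)
    }
    for (s in primary$set) {
      pri <- primary[primary$set == s, , drop = FALSE]
      var <- v[v$set == s, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, set = s,
        primary_or = pri$odds_ratio, primary_ci_low = pri$ci_low,
        primary_ci_high = pri$ci_high,
        variant_or = var$odds_ratio, variant_ci_low = var$ci_low,
        variant_ci_high = var$ci_high,
        verdict = .verdict(pri, var), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("consistency_report", "data.frame")
  out
}
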