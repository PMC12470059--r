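#' Build the expressed-gene universe
#'
#' The background is every gene with a non-missing adjusted p-value; the Up
#' and Down partitions are the significant genes in each direction at the
#' classification `alpha`. All set-overlap tests are performed against this
#' universe.
#'
#' @param records A `scored_table` from [score_and_classify()] (a bare
#'   `de_table` is scored on the fly).
#' @param alpha Significance threshold (strict `<`); default 0.05.
#' @return A `universe`: list with `background`, `up`, `down` symbol vectors,
#'   `alpha`, and counts `M`, `K_up`, `K_down`.
#' @export
build_universe <- function(records, alpha = 0.05) {
  if (!"s" %in% names(records)) records <- score_and_classify(records, alpha)
  ok <- !is.na(records$padj)
  if (!any(ok)) stop_direnrich("empty universe: every record has missing padj")
  bg <- records$symbol[ok]
  up <- records$symbol[ok & as.character(records$direction) == "UP"]
  down <- records$symbol[ok & as.character(records$direction) == "DOWN"]
  universe(bg, up, down, alpha)
}

#' Construct a universe from explicit symbol sets
#'
#' Low-level constructor used by [build_universe()], the sensitivity module
#' and tests.
#'
#' @param background,up,down Symbol vectors; `up` and `down` must be disjoint
#'   subsets of `background`.
#' @param alpha The significance threshold the partitions were called at.
#' @return A `universe`.
#' @export
universe <- function(background, up, down, alpha = 0.05) {
  background <- unique(normalize_symbols(background))
  up <- unique(normalize_symbols(up))
  down <- unique(normalize_symbols(down))
  if (!all(up %in% background) || !all(down %in% background)) {
    stop_direnrich("up/down partitions must be subsets of the background")
  }
  if (length(intersect(up, down))) {
    stop_direnrich("up and down partitions must be disjoint")
  }
  structure(list(background = background, up = up, down = down, alpha = alpha,
                 M = length(background), K_up = length(up),
                 K_down = length(down)),
            class = "universe")
}

#' @export
print.universe <- function(x, ...) {
  cat(sprintf("universe: M = %d background genes; K_up = %d, K_down = %d (alpha %g)\n",
              x$M, x$K_up, x$K_down, x$alpha))
  invisible(x)
}

#' Construct a 2x2 contingency table
#'
#' Cell convention for a target set T tested against a direction set D inside
#' a background of size M: `a = |T intersect D|`, `b = |T| - a`,
#' `c = |D| - a`, `d = M - a - b - c`.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop_direnrich("contingency cells must be non-negative integers")
  }
  structure(setNames(as.list(as.integer(round(cells))), names(cells)),
            class = "contingency_table")
}

#' Reconstruct a contingency table from summary counts
#'
#' Builds the 2x2 table from a set size `n`, overlap `a`, direction-set size
#' `K` and background size `M` — the four numbers typically printed in an
#' enrichment report.
#'
#' @param n Target-set size within the background.
#' @param a Overlap with the direction set.
#' @param K Direction-set size.
#' @param M Background size.
#' @return A `contingency_table` `(a, n - a, K - a, M - n - K + a)`.
#' @export
reconstruct_contingency <- function(n, a, K, M) {
  contingency_table(a, n - a, K - a, M - n - K + a)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table: a=%d b=%d c=%d d=%d (M=%d)\n",
              x$a, x$b, x$c, x$d, x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Direction-aware contingency table for a target set
#'
#' @param target A `gene_set` (restricted to the background beforehand or
#'   here; any out-of-background symbols are dropped silently into `n`).
#' @param universe A `universe`.
#' @param direction `"up"` or `"down"` — which partition to test against.
#' @return A `contingency_table`.
#' @export
make_contingency <- function(target, universe, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(universe, "universe"))
  D <- if (direction == "up") universe$up else universe$down
  if (length(D) == 0L) {
    stop_direnrich("direction set '%s' is empty in this universe", direction)
  }
  syms <- if (inherits(target, "gene_set")) target$symbols else
    unique(normalize_symbols(target))
  syms <- syms[syms %in% universe$background]
  a <- sum(syms %in% D)
  contingency_table(a, length(syms) - a, length(D) - a,
                    universe$M - length(syms) - length(D) + a)
}

# log hypergeometric pmf over a support vector k, via log-gamma
hyper_lpmf <- function(k, M, K, n) {
  lchoose(K, k) + lchoose(M - K, n - k) - lchoose(M, n)
}

#' One-sided Fisher exact p-value (alternative: greater)
#'
#' Computes the exact hypergeometric upper tail \eqn{P(X \ge a)} for the
#' observed overlap under fixed margins, by direct summation of the log-gamma
#' pmf over the support `a..min(n, K)` with a stable log-sum-exp. No
#' continuity approximation is involved; `a = 0` returns exactly 1.
#'
#' @param t A `contingency_table`.
#' @return p-value in `(0, 1]`.
#' @examples
#' fisher_one_sided(contingency_table(1, 1, 1, 1))  # 5/6
#' @export
fisher_one_sided <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  M <- t$a + t$b + t$c + t$d
  K <- t$a + t$c
  n <- t$a + t$b
  if (t$a == 0L) return(1)
  support <- t$a:min(n, K)
  p <- exp(logsumexp(hyper_lpmf(support, M, K, n)))
  min(max(p, .Machine$double.xmin), 1)
}

# apply Haldane-Anscombe policy; returns numeric cells (possibly +0.5)
ha_cells <- function(t, ha_policy = c("when_needed", "always", "never")) {
  ha_policy <- match.arg(ha_policy)
  cells <- c(t$a, t$b, t$c, t$d)
  ha <- switch(ha_policy,
               when_needed = any(cells == 0),
               always = TRUE,
               never = FALSE)
  if (!ha && ha_policy == "never" && t$b * t$c == 0) {
    stop_direnrich("zero denominator cell with ha_policy = 'never'; odds ratio undefined")
  }
  list(cells = cells + if (ha) 0.5 else 0, ha_applied = ha)
}

#' Cross-product odds ratio with optional Haldane-Anscombe correction
#'
#' `OR = (a d)/(b c)` on the raw cells. Under the default `when_needed`
#' policy, 0.5 is added to all four cells if and only if any cell is zero
#' (flagged in the result); `always` corrects unconditionally; `never`
#' errors on a zero cell.
#'
#' @param t A `contingency_table`.
#' @param ha_policy `"when_needed"` (default), `"always"`, or `"never"`.
#' @return List with `or` and `ha_applied`.
#' @export
odds_ratio <- function(t, ha_policy = c("when_needed", "always", "never")) {
  stopifnot(inherits(t, "contingency_table"))
  h <- ha_cells(t, ha_policy)
  x <- h$cells
  list(or = (x[1] * x[4]) / (x[2] * x[3]), ha_applied = h$ha_applied)
}

#' Woolf (logit) confidence interval for the odds ratio
#'
#' On the (possibly Haldane-Anscombe-corrected) cells:
#' \eqn{\exp(\ln OR \pm z \sqrt{1/a + 1/b + 1/c + 1/d})} with
#' `z = qnorm((1 + level)/2)`. The same cells are used for the point estimate
#' and the interval.
#'
#' @param t A `contingency_table`.
#' @param level Confidence level; default 0.95.
#' @param ha_policy As in [odds_ratio()].
#' @return Named numeric `c(low, high)`.
#' @export
woolf_ci <- function(t, level = 0.95,
                     ha_policy = c("when_needed", "always", "never")) {
  stopifnot(inherits(t, "contingency_table"),
            is.numeric(level), level > 0, level < 1)
  h <- ha_cells(t, ha_policy)
  x <- h$cells
  if (any(x == 0)) stop_direnrich("zero cell after correction; CI undefined")
  z <- qnorm((1 + level) / 2)
  lor <- log((x[1] * x[4]) / (x[2] * x[3]))
  se <- sqrt(sum(1 / x))
  c(low = exp(lor - z * se), high = exp(lor + z * se))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH: with p-values ranked ascending, `q(i) = min_{j >= i}
#' p(j) * m / j`, capped at 1, returned in the original input order. Apply it
#' separately per pre-specified test family; no cross-family pooling is done
#' here.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated; missing values do not count toward `m`).
#' @return q-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.0137, 2.56e-9, 1.87e-4))  # smallest q = 7.68e-9
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop_direnrich("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0L) return(q)
  ord <- ok[order(p[ok])]
  stepped <- p[ord] * m / seq_len(m)
  q[ord] <- pmin(rev(cummin(rev(stepped))), 1)
  q
}

#' Run direction-aware enrichment over a collection of gene sets
#'
#' For each set: restrict to the background, optionally apply ORA-style size
#' and overlap filters (term size within `[term_min, term_max]` after
#' restriction, overlap at least `min_overlap`; filtered sets are reported
#' but not tested), build the direction-aware 2x2 table, and compute the
#' one-sided Fisher p, odds ratio, Woolf CI and expected overlap
#' `n * K / M`. BH adjustment is applied within each declared family only;
#' with `families = NULL` all tested sets form one family.
#'
#' Direction policy: `"up"`/`"down"` test every set against that partition;
#' `"auto"` uses each set's `regulator_direction` tag — a down-regulated
#' regulator is tested against the UP partition (de-repression) and an
#' up-regulated one against DOWN.
#'
#' @param universe A `universe`.
#' @param sets List of `gene_set` objects.
#' @param direction `"up"`, `"down"`, or `"auto"`.
#' @param families `NULL`, or a named list of character vectors of set names;
#'   each vector is one BH family. Unknown names error.
#' @param term_min,term_max,min_overlap ORA filters (defaults 5, 500, 2).
#' @param size_filter Logical; apply the filters (default `TRUE`). Disable
#'   for small pre-specified families where every test is reported.
#' @param ha_policy,level Passed to [odds_ratio()] / [woolf_ci()].
#' @return An `enrichment_result` data.frame with one row per set: `set`,
#'   `tier`, `direction`, `n`, `a`, `expected_a`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p`, `q`, `ha_applied`, `filter_status`, `family`.
#' @export
run_enrichment <- function(universe, sets,
                           direction = c("up", "down", "auto"),
                           families = NULL,
                           term_min = 5L, term_max = 500L, min_overlap = 2L,
                           size_filter = TRUE,
                           ha_policy = "when_needed", level = 0.95) {
  direction <- match.arg(direction)
  stopifnot(inherits(universe, "universe"))
  if (inherits(sets, "gene_set")) sets <- list(sets)
  nm <- vapply(sets, `[[`, "", "name")
  names(sets) <- nm

  if (!is.null(families)) {
    unknown <- setdiff(unlist(families), nm)
    if (length(unknown)) {
      stop_direnrich("family member(s) not among the supplied sets: %s",
                     paste(unknown, collapse = ", "))
    }
  }

  rows <- lapply(sets, function(s) {
    dir_i <- if (direction == "auto") {
      if (is.null(s$regulator_direction)) {
        stop_direnrich("set '%s' lacks a regulator_direction tag required by direction = 'auto'",
                       s$name)
      }
      if (s$regulator_direction == "down") "up" else "down"
    } else direction
    restricted <- restrict_to_background(s, universe)$set
    n <- length(restricted$symbols)
    tab <- make_contingency(restricted, universe, dir_i)
    K <- tab$a + tab$c
    status <- "tested"
    if (isTRUE(size_filter)) {
      if (n < term_min) status <- "below_term_min"
      else if (n > term_max) status <- "above_term_max"
      else if (tab$a < min_overlap) status <- "below_min_overlap"
    }
    if (status == "tested") {
      orr <- odds_ratio(tab, ha_policy)
      ci <- woolf_ci(tab, level, ha_policy)
      data.frame(set = s$name, tier = s$tier, direction = dir_i,
                 n = n, a = tab$a, expected_a = n * K / universe$M,
                 odds_ratio = orr$or, ci_low = ci[["low"]],
                 ci_high = ci[["high"]], p = fisher_one_sided(tab),
                 q = NA_real_, ha_applied = orr$ha_applied,
                 filter_status = status, stringsAsFactors = FALSE)
    } else {
      data.frame(set = s$name, tier = s$tier, direction = dir_i,
                 n = n, a = tab$a, expected_a = n * K / universe$M,
                 odds_ratio = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_, q = NA_real_, ha_applied = NA,
                 filter_status = status, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  res$family <- NA_character_
  if (is.null(families)) {
    res$family <- "all"
    idx <- which(res$filter_status == "tested")
    res$q[idx] <- bh_adjust(res$p[idx])
  } else {
    for (fam in names(families)) {
      idx <- which(res$set %in% families[[fam]])
      res$family[idx] <- fam
      tested <- idx[res$filter_status[idx] == "tested"]
      res$q[tested] <- bh_adjust(res$p[tested])
    }
  }
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "universe_counts") <- c(M = universe$M, K_up = universe$K_up,
                                    K_down = universe$K_down)
  res
}

#' Calibrate a background size from a reported odds ratio
#'
#' Reproduction utility: given a published row (`OR`, set size `n`, overlap
#' `a`, direction-set size `K`) but no printed background size, invert the
#' cross-product relation — `d = round(OR * b * c / a)`, `M = a + b + c + d`
#' — and report the residual between the implied and reported OR.
#'
#' @param reported_or Published odds ratio (> 0).
#' @param a Overlap count (>= 1).
#' @param n Set size (with `b = n - a >= 1`).
#' @param K Direction-set size (with `c = K - a >= 1`).
#' @return List with `M`, `d`, and `residual = |a d / (b c) - reported_or|`.
#' @examples
#' calibrate_background(6.57, a = 4, n = 8, K = 2923)$M  # 22105
#' @export
calibrate_background <- function(reported_or, a, n, K) {
  b <- n - a
  cc <- K - a
  if (a < 1 || b < 1 || cc < 1 || reported_or <= 0) {
    stop_direnrich("need a >= 1, n - a >= 1, K - a >= 1, reported_or > 0")
  }
  d <- round(reported_or * b * cc / a)
  list(M = a + b + cc + d, d = d,
       residual = abs(a * d / (b * cc) - reported_or))
}
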