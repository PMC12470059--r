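#' Simulation configuration
#'
#' Parameters of the synthetic DE-table generator. Defaults describe a bulk
#' cortical DE contrast of realistic scale: 20,000 expressed genes of which
#' 15% are truly up- and 12.5% truly down-regulated (matching a mild
#' up-regulation excess, ratio ~1.2), mean true effects of 1.5 log2 units
#' with per-gene effect noise 0.3, and a shared standard error 0.3 for the
#' test statistic — under which roughly 3,000 genes are called Up at
#' BH-adjusted 0.05. The planted target set defaults to 600 genes with a
#' membership-vs-Up-call odds ratio of 1.8.
#'
#' @param M Number of genes.
#' @param pi_up,pi_down Fractions of truly up-/down-regulated genes
#'   (`pi_up + pi_down < 1`).
#' @param mu_up,mu_down Mean true |effect| in log2 units for each class.
#' @param sigma_e Per-gene sd of observed effect around the true effect.
#' @param se Standard error of the effect estimate used by the z test.
#' @param n_target Expected planted target-set size.
#' @param omega Planted odds ratio between target membership and an observed
#'   UP call.
#' @param panel_sizes Named integer vector of marker-panel sizes per cell
#'   type.
#' @param panel_up_rate Fraction of each panel drawn preferentially from
#'   UP-called genes (0 = unconfounded panels).
#' @param seed Default RNG seed for all downstream generation.
#' @return A validated `sim_config`.
#' @export
sim_config <- function(M = 20000L,
                       pi_up = 0.15, pi_down = 0.125,
                       mu_up = 1.5, mu_down = 1.5,
                       sigma_e = 0.3, se = 0.3,
                       n_target = 600L, omega = 1.8,
                       panel_sizes = c(astrocyte = 50L, microglia = 50L,
                                       oligodendrocyte = 50L,
                                       endothelial = 50L, neuron = 50L),
                       panel_up_rate = 0,
                       seed = 1L) {
  cfg <- list(M = as.integer(M), pi_up = pi_up, pi_down = pi_down,
              mu_up = mu_up, mu_down = mu_down, sigma_e = sigma_e, se = se,
              n_target = as.integer(n_target), omega = omega,
              panel_sizes = panel_sizes, panel_up_rate = panel_up_rate,
              seed = as.integer(seed))
  if (cfg$M < 10) stop_direnrich("M must be at least 10")
  if (pi_up < 0 || pi_down < 0 || pi_up + pi_down >= 1) {
    stop_direnrich("need pi_up, pi_down >= 0 and pi_up + pi_down < 1")
  }
  if (any(c(mu_up, mu_down, sigma_e, se, omega) <= 0)) {
    stop_direnrich("mu_up, mu_down, sigma_e, se, omega must be positive")
  }
  if (cfg$n_target < 1 || cfg$n_target >= cfg$M) {
    stop_direnrich("n_target must be in [1, M)")
  }
  if (panel_up_rate < 0 || panel_up_rate > 1) {
    stop_direnrich("panel_up_rate must be in [0, 1]")
  }
  if (sum(panel_sizes) >= cfg$M) {
    stop_direnrich("total panel size must be below M")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a DE summary table with known ground truth
#'
#' Generative model, per gene: a true state (null / up / down) drawn with
#' probabilities `(1 - pi_up - pi_down, pi_up, pi_down)`; true effect 0,
#' `mu_up`, or `-mu_down`; observed `log2fc = effect + N(0, sigma_e)`;
#' two-sided p from `z = log2fc / se` under the standard normal; `padj` by
#' BH over all `M` genes. The RNG is R's default Mersenne-Twister; output is
#' bit-reproducible from `(config, seed)`.
#'
#' @param config A `sim_config`.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return List with `table` (a `de_table`, symbols `G00001...`) and `truth`
#'   (data.frame: `symbol`, `true_state`, `true_effect`).
#' @export
simulate_de_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    M <- config$M
    symbol <- sprintf("G%05d", seq_len(M))
    state <- sample(c("null", "up", "down"), M, replace = TRUE,
                    prob = c(1 - config$pi_up - config$pi_down,
                             config$pi_up, config$pi_down))
    effect <- ifelse(state == "up", config$mu_up,
                     ifelse(state == "down", -config$mu_down, 0))
    log2fc <- effect + rnorm(M, 0, config$sigma_e)
    p <- 2 * pnorm(-abs(log2fc / config$se))
    padj <- bh_adjust(p)
    list(table = de_table(symbol, log2fc, padj),
         truth = data.frame(symbol = symbol, true_state = state,
                            true_effect = effect, stringsAsFactors = FALSE))
  })
}

# Solve the membership probabilities (p0 for non-UP genes, p1 for UP genes)
# such that the membership-vs-UP-call odds ratio is omega and the expected
# set size is n_target: p1 = omega p0 / (1 + (omega - 1) p0);
# K p1 + (M - K) p0 = n_target. Bisection on p0 (expected size is strictly
# increasing in p0).
plant_probs <- function(omega, n_target, M, K) {
  if (omega == 1) {
    p <- n_target / M
    return(list(p0 = p, p1 = p))
  }
  p1_of <- function(p0) omega * p0 / (1 + (omega - 1) * p0)
  expected <- function(p0) K * p1_of(p0) + (M - K) * p0
  lo <- 0
  hi <- 1
  if (expected(hi) < n_target - 0.5) {
    stop_direnrich("no solution with p1 < 1; reduce omega or n_target")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (expected(mid) < n_target) lo <- mid else hi <- mid
    if (abs(expected(mid) - n_target) < 0.5) break
  }
  p0 <- (lo + hi) / 2
  p1 <- p1_of(p0)
  if (p1 >= 1) stop_direnrich("no solution with p1 < 1; reduce omega or n_target")
  list(p0 = p0, p1 = p1)
}

#' Plant a target gene set with a controlled association odds ratio
#'
#' Samples target membership independently per gene with probability `p1`
#' for genes called UP in the supplied universe and `p0` otherwise, where
#' `(p0, p1)` solve the planted odds ratio
#' `p1 (1 - p0) / (p0 (1 - p1)) = omega` and expected size
#' `K p1 + (M - K) p0 = n_target`. Planting is against the *observed* Up
#' calls, so `ln(omega)` is exactly the log-odds association that downstream
#' enrichment estimates — no attenuation bookkeeping is needed.
#'
#' @param universe A `universe` built from the simulated table.
#' @param omega Planted odds ratio (> 0).
#' @param n_target Expected set size.
#' @param seed RNG seed.
#' @param name,tier Passed to [gene_set()].
#' @return A `gene_set` tagged `regulator_direction = "down"` (its members
#'   emulate targets of a down-regulated regulator).
#' @export
plant_target_set <- function(universe, omega, n_target, seed,
                             name = "planted_targets", tier = "custom") {
  stopifnot(inherits(universe, "universe"))
  pr <- plant_probs(omega, n_target, universe$M, universe$K_up)
  with_seed(seed, {
    is_up <- universe$background %in% universe$up
    prob <- ifelse(is_up, pr$p1, pr$p0)
    member <- runif(universe$M) < prob
    gene_set(name, universe$background[member], tier = tier,
             regulator_direction = "down")
  })
}

#' Simulate disjoint cell-type marker panels and a stratum map
#'
#' Draws disjoint random panels of the configured sizes from the universe
#' background. With `panel_up_rate > 0`, that fraction of each panel is
#' drawn from UP-called genes (when available), emulating composition
#' confounding — a marker panel enriched in the direction signal. The
#' stratum map follows [default_strata()]: neuron panel vs the union of the
#' remaining panels.
#'
#' @param config A `sim_config` (panel sizes, confounding rate).
#' @param universe A `universe` from the simulated table.
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return List with `panels` (named list of `gene_set`, tier `"marker"`)
#'   and `strata` (named character vector).
#' @export
simulate_marker_panels <- function(config, universe,
                                   seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(universe, "universe"))
  sizes <- config$panel_sizes
  if (sum(sizes) > universe$M) {
    stop_direnrich("requested panel sizes exceed the universe size")
  }
  with_seed(seed, {
    avail <- universe$background
    panels <- list()
    for (ct in names(sizes)) {
      k <- sizes[[ct]]
      n_up <- round(config$panel_up_rate * k)
      up_avail <- intersect(avail, universe$up)
      n_up <- min(n_up, length(up_avail), k)
      chosen <- character(0)
      if (n_up > 0) chosen <- sample(up_avail, n_up)
      rest <- setdiff(avail, chosen)
      chosen <- c(chosen, sample(rest, k - n_up))
      panels[[ct]] <- gene_set(ct, chosen, tier = "marker",
                               source = "simulated")
      avail <- setdiff(avail, chosen)
    }
    list(panels = panels, strata = default_strata(panels))
  })
}
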