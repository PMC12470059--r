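test_that("build_universe partitions the scored table", {
  sc <- score_and_classify(de_table(
    sprintf("G%02d", 1:10),
    log2fc = c(2, 1, 3, -1, 0.5, -0.2, 1, -1, 2, -2),
    padj = c(0.01, 0.02, 0.001, 0.04, 0.5, 0.9, NA, NA, 0.2, 0.3)))
  u <- build_universe(sc)
  expect_equal(u$M, 8L)
  expect_equal(u$K_up, 3L)
  expect_equal(u$K_down, 1L)
  expect_setequal(c(u$up, u$down, setdiff(u$background, c(u$up, u$down))),
                  u$background)
  all_na <- de_table(c("A", "B"), c(1, 2), c(NA, NA))
  expect_error(build_universe(score_and_classify(all_na)), "empty universe")
  # random tables: counts equal brute-force filters
  sc2 <- random_scored(500, seed = 21)
  u2 <- build_universe(sc2)
  expect_equal(u2$M, sum(!is.na(sc2$padj)))
  expect_equal(u2$K_up, sum(sc2$direction == "UP"))
  expect_equal(u2$K_down, sum(sc2$direction == "DOWN"))
})

test_that("make_contingency builds direction-aware 2x2 tables", {
  u <- universe(sprintf("G%02d", 1:20), sprintf("G%02d", 1:5),
                sprintf("G%02d", 6:8))
  t0 <- make_contingency(gene_set("empty", character(0)), u, "up")
  expect_equal(unlist(t0[c("a", "b", "c", "d")]),
               c(a = 0L, b = 0L, c = 5L, d = 15L))
  t1 <- make_contingency(gene_set("s", c("G01", "G02", "G10", "NOTBG")), u,
                         "up")
  expect_equal(unlist(t1[c("a", "b", "c", "d")]),
               c(a = 2L, b = 1L, c = 3L, d = 14L))
  expect_error(make_contingency(gene_set("s", "G01"),
                                universe(c("A", "B"), "A", character(0)),
                                "down"),
               "empty")
  # reconstructed published-style tables from summary counts
  func <- reconstruct_contingency(n = 8, a = 4, K = 2923, M = 22105)
  expect_equal(unlist(func[c("a", "b", "c", "d")]),
               c(a = 4L, b = 4L, c = 2919L, d = 19178L))
  clip <- reconstruct_contingency(n = 640, a = 138, K = 2923, M = 22105)
  expect_equal(unlist(clip[c("a", "b", "c", "d")]),
               c(a = 138L, b = 502L, c = 2785L, d = 18680L))
})

test_that("fisher_one_sided is exact", {
  expect_equal(fisher_one_sided(contingency_table(0, 5, 10, 100)), 1)
  # full enumeration of C(4,2) = 6 draws gives P(X >= 1) = 5/6
  expect_equal(fisher_one_sided(contingency_table(1, 1, 1, 1)), 5 / 6,
               tolerance = 1e-12)
  expect_equal(fisher_one_sided(contingency_table(4, 4, 2919, 19178)),
               0.0137, tolerance = 0.002)
})

test_that("fisher_one_sided equals the hypergeometric oracle on all small tables", {
  for (M in c(1, 7, 23, 40)) {
    g <- all_tables(M)
    got <- mapply(function(a, b, c, d)
      fisher_one_sided(contingency_table(a, b, c, d)),
      g$a, g$b, g$c, g$d)
    want <- fisher_oracle(g$a, g$b, g$c, g$d)
    want[g$a == 0] <- 1
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
})

test_that("hypergeometric pmf sums to one over its support", {
  withr::with_seed(4, {
    for (i in 1:25) {
      M <- sample(10:10000, 1)
      K <- sample(1:(M - 1), 1)
      n <- sample(1:(M - 1), 1)
      support <- max(0, n + K - M):min(n, K)
      total <- sum(exp(direnrich:::hyper_lpmf(support, M, K, n)))
      expect_lt(abs(total - 1), 1e-12)
    }
  })
})

test_that("odds_ratio honors the Haldane-Anscombe policy", {
  r <- odds_ratio(contingency_table(1, 1, 1, 1))
  expect_equal(r$or, 1)
  expect_false(r$ha_applied)
  rz <- odds_ratio(contingency_table(0, 5, 10, 100))
  expect_true(rz$ha_applied)
  expect_equal(rz$or, (0.5 * 100.5) / (5.5 * 10.5), tolerance = 1e-12)
  expect_equal(odds_ratio(contingency_table(138, 502, 2785, 18680))$or,
               1.84, tolerance = 0.005)
  always <- odds_ratio(contingency_table(1, 1, 1, 1), "always")
  expect_true(always$ha_applied)
  expect_equal(always$or, 1)
  expect_error(odds_ratio(contingency_table(3, 0, 5, 7), "never"), "zero")
})

test_that("woolf_ci matches published-style intervals and its properties", {
  ci <- woolf_ci(contingency_table(10, 10, 10, 10))
  expect_equal(ci[["low"]], 1 / ci[["high"]], tolerance = 1e-12)
  expect_equal(woolf_ci(contingency_table(4, 4, 2919, 19178)),
               c(low = 1.64, high = 26.27), tolerance = 0.005)
  expect_equal(woolf_ci(contingency_table(15, 27, 2908, 19155)),
               c(low = 1.94, high = 6.88), tolerance = 0.005)
  # interval brackets the OR and shrinks with the level
  t1 <- contingency_table(12, 30, 44, 90)
  or1 <- odds_ratio(t1)$or
  ci95 <- woolf_ci(t1, 0.95)
  ci80 <- woolf_ci(t1, 0.80)
  expect_true(ci95[["low"]] <= or1 && or1 <= ci95[["high"]])
  expect_true(ci80[["low"]] > ci95[["low"]] && ci80[["high"]] < ci95[["high"]])
})

test_that("bh_adjust is standard step-up BH", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  q <- bh_adjust(c(0.0137, 2.56e-9, 1.87e-4))
  expect_equal(q[2], 7.68e-9, tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(6, {
    for (i in 1:10) {
      p <- runif(sample(1:50, 1))
      q <- bh_adjust(p)
      expect_equal(q, p.adjust(p, "BH"))         # independent oracle
      expect_true(all(q >= p & q <= 1))
      expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone along sorted p
      perm <- sample(length(p))
      expect_equal(bh_adjust(p[perm]), q[perm])  # permutation invariance
    }
  })
})

test_that("run_enrichment reproduces the three-tier reconstruction", {
  fx <- counts_fixture(M = 22105, K = 2923,
                       spec = list(functional = c(n = 8, a = 4),
                                   clip = c(n = 640, a = 138),
                                   validated_any = c(n = 42, a = 15)))
  res <- run_enrichment(fx$universe, fx$sets, direction = "up",
                        families = list(mir = c("functional", "clip",
                                                "validated_any")),
                        size_filter = FALSE)
  expect_equal(res$odds_ratio, c(6.57, 1.84, 3.66), tolerance = 0.005)
  expect_equal(res$ci_low, c(1.64, 1.52, 1.94), tolerance = 0.005)
  expect_equal(res$ci_high, c(26.27, 2.24, 6.89), tolerance = 0.005)
  expect_equal(res$p[1], 0.0137, tolerance = 0.002)
  expect_equal(res$expected_a, res$n * 2923 / 22105)
  expect_false(any(res$ha_applied))
  # q within the family via step-up over the three computed p-values
  expect_equal(res$q, bh_adjust(res$p))
  # the "auto" policy maps these down-regulated-regulator sets to "up"
  auto <- run_enrichment(fx$universe, fx$sets, direction = "auto",
                         size_filter = FALSE)
  expect_equal(auto$p, res$p)
  expect_equal(auto$direction, rep("up", 3))
})

test_that("ORA filters exclude without testing, and families are enforced", {
  fx <- counts_fixture(M = 500, K = 100,
                       spec = list(tiny = c(n = 3, a = 2),
                                   small_overlap = c(n = 10, a = 1),
                                   big = c(n = 50, a = 20)))
  res <- run_enrichment(fx$universe, fx$sets, direction = "up",
                        size_filter = TRUE)
  expect_equal(res$filter_status,
               c("below_term_min", "below_min_overlap", "tested"))
  expect_true(all(is.na(res$p[1:2])))
  expect_false(is.na(res$q[3]))
  expect_error(run_enrichment(fx$universe, fx$sets, direction = "up",
                              families = list(f = "missing_set")),
               "missing_set")
  # auto direction requires the regulator tag
  untagged <- gene_set("u", fx$sets$big$symbols)
  expect_error(run_enrichment(fx$universe, list(untagged), "auto"),
               "regulator_direction")
})

test_that("every reported p equals exhaustive enumeration on a small universe", {
  withr::with_seed(14, {
    syms <- sprintf("G%02d", 1:40)
    u <- universe(syms, sample(syms, 12), character(0))
    sets <- lapply(1:6, function(i)
      gene_set(paste0("S", i), sample(syms, sample(5:20, 1))))
    res <- run_enrichment(u, sets, direction = "up", size_filter = FALSE)
    for (i in seq_len(nrow(res))) {
      expect_equal(res$p[i],
                   fisher_oracle(res$a[i], res$n[i] - res$a[i],
                                 12 - res$a[i],
                                 40 - res$n[i] - 12 + res$a[i]),
                   tolerance = 1e-12)
    }
  })
})

test_that("expected_a telescopes over a tiling partition", {
  withr::with_seed(15, {
    syms <- sprintf("G%03d", 1:300)
    u <- universe(syms, sample(syms, 60), character(0))
    groups <- split(syms, rep(1:5, each = 60))
    sets <- lapply(names(groups), function(g)
      gene_set(paste0("part", g), groups[[g]]))
    res <- run_enrichment(u, sets, direction = "up", size_filter = FALSE)
    expect_equal(sum(res$a - res$expected_a), 0, tolerance = 1e-9)
  })
})

test_that("direction symmetry: flipping signs and direction is a no-op", {
  cfg <- sim_config(M = 2000, seed = 23)
  sim <- simulate_de_table(cfg)
  sc <- score_and_classify(sim$table)
  u <- build_universe(sc)
  target <- plant_target_set(u, 1.8, 120, seed = 24)
  res_up <- run_enrichment(u, target, direction = "up", size_filter = FALSE)
  flipped <- score_and_classify(de_table(sc$symbol, -sc$log2fc, sc$padj))
  u_f <- build_universe(flipped)
  res_down <- run_enrichment(u_f, target, direction = "down",
                             size_filter = FALSE)
  for (col in c("n", "a", "odds_ratio", "ci_low", "ci_high", "p", "q")) {
    expect_equal(res_down[[col]], res_up[[col]])
  }
})

test_that("calibrate_background inverts the cross-product relation", {
  cal <- calibrate_background(6.57, a = 4, n = 8, K = 2923)
  expect_equal(cal$M, 22105)
  expect_equal(cal$d, 19178)
  expect_lt(cal$residual, 0.005)
  expect_equal(calibrate_background(1.0, a = 1, n = 2, K = 2)$M, 4)
  expect_error(calibrate_background(2, a = 0, n = 5, K = 10), "a >= 1")
  # round trip: the calibrated background reproduces the input OR
  withr::with_seed(33, {
    for (i in 1:10) {
      a <- sample(2:20, 1); n <- a + sample(1:30, 1); K <- a + sample(1:500, 1)
      or_in <- runif(1, 0.5, 8)
      M <- calibrate_background(or_in, a, n, K)$M
      tab <- reconstruct_contingency(n, a, K, M)
      expect_equal(odds_ratio(tab)$or, or_in,
                   tolerance = 1 / (tab$b * tab$c / tab$a) + 1e-6)
    }
  })
})
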