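test_that("parse_de_table reads well-formed exports and normalizes numerics", {
  f <- write_lines_tmp(c("Gene.symbol\tlogFC\tadj.P.Val",
                         "MIR219A2\t−3.005\t2.08E-08",
                         "slc16a12\t4.094\t5.67e-15",
                         " Ogn \t4.372\t2.85e-13"))
  de <- parse_de_table(f, col_symbol = "Gene.symbol", col_log2fc = "logFC",
                       col_padj = "adj.P.Val")
  expect_s3_class(de, "de_table")
  expect_equal(nrow(de), 3L)
  expect_equal(de$symbol, c("MIR219A2", "SLC16A12", "OGN"))
  # unicode minus and upper/lower-case scientific notation both parse
  expect_equal(de$log2fc[1], -3.005)
  expect_equal(de$padj[1], 2.08e-8)
  expect_equal(attr(de, "n_unparseable"), 0L)
})

test_that("duplicate symbols are resolved per policy", {
  lines <- c("symbol\tlog2fc\tpadj",
             "X\t1.0\t0.01", "X\t2.0\t0.002", "Y\t1.5\t0.03")
  f <- write_lines_tmp(lines)
  expect_warning(de <- parse_de_table(f), "duplicate")
  expect_equal(nrow(de), 2L)
  expect_equal(de$padj[de$symbol == "X"], 0.002)  # min-padj kept

  f2 <- write_lines_tmp(lines)
  expect_warning(de2 <- parse_de_table(f2, duplicate_policy = "drop_all"),
                 "dropped")
  expect_equal(de2$symbol, "Y")
})

test_that("parse errors are informative; unparseable numerics become missing", {
  f <- write_lines_tmp(c("symbol\tlog2fc\tpadj", "A\t1\t0.1"))
  expect_error(parse_de_table(f, col_padj = "nope"), "nope")
  f2 <- write_lines_tmp("symbol\tlog2fc\tpadj")
  expect_error(parse_de_table(f2), "empty")
  f3 <- write_lines_tmp(c("symbol\tlog2fc\tpadj",
                          "A\t1.2\tnot_a_number", "B\t1\t0.2"))
  de <- parse_de_table(f3)
  expect_equal(attr(de, "n_unparseable"), 1L)
  expect_true(is.na(de$padj[de$symbol == "A"]))
  expect_equal(as.character(score_and_classify(de)$direction),
               c("UNTESTED", "NS"))
})

test_that("score_and_classify matches printed worked examples and edge rules", {
  de <- de_table(c("SLC16A12", "MIR219A2", "FLAT", "ZERO", "FLOORED"),
                 log2fc = c(4.094, -3.005, 7.3, 0, 2),
                 padj = c(5.670e-15, 2.080e-8, 1.0, 0.001, 0))
  sc <- score_and_classify(de)
  expect_equal(sc$s[1], 4.094 * -log10(5.670e-15), tolerance = 1e-12)
  expect_equal(sc$s[1], 58.320, tolerance = 0.01)
  expect_equal(sc$s[2], 23.088, tolerance = 0.01)
  expect_equal(as.character(sc$direction[1:2]), c("UP", "DOWN"))
  # -log10(1) = 0 and not significant
  expect_equal(sc$s[3], 0)
  expect_equal(as.character(sc$direction[3]), "NS")
  # zero fold change has undefined direction even when significant
  expect_equal(as.character(sc$direction[4]), "NS")
  # padj = 0 floored at 1e-300, keeping S finite
  expect_equal(sc$s[5], 2 * 300)
  # strict inequality at the threshold
  at <- score_and_classify(de_table("A", 1, 0.05))
  expect_equal(as.character(at$direction), "NS")
})

test_that("classification is a partition and scores are sign-symmetric", {
  for (seed in c(2, 42)) {
    sc <- random_scored(300, seed)
    expect_true(all(sc$s >= 0, na.rm = TRUE))
    expect_equal(sum(table(sc$direction)), nrow(sc))
    flipped <- score_and_classify(
      de_table(sc$symbol, -sc$log2fc, sc$padj))
    expect_equal(flipped$s, sc$s)
    expect_equal(sum(flipped$direction == "UP"), sum(sc$direction == "DOWN"))
    expect_equal(sum(flipped$direction == "DOWN"), sum(sc$direction == "UP"))
  }
})

test_that("rank_by_score applies the documented tie rules", {
  sc <- score_and_classify(de_table(
    c("A", "B"), c(1, 1), c(0.05 / 10^5, 0.05 / 10^7)))
  expect_equal(rank_by_score(sc)$symbol, c("B", "A"))  # larger s first
  # equal s, tie broken by smaller padj
  de2 <- score_and_classify(de_table(c("A", "B"), c(2, 1),
                                     c(1e-2, 1e-4)))
  de2$s <- c(4, 4)
  expect_equal(rank_by_score(de2)$symbol, c("B", "A"))
  # equal s and padj, tie broken by larger |log2fc|
  de3 <- score_and_classify(de_table(c("A", "B"), c(2, -3), c(1e-2, 1e-2)))
  de3$s <- c(4, 4)
  expect_equal(rank_by_score(de3)$symbol, c("B", "A"))
})

test_that("rank_by_score agrees with the brute-force sort oracle", {
  for (seed in c(7, 19)) {
    n <- if (seed == 7) 120 else 1000
    sc <- random_scored(n, seed)
    # inject exact ties
    sc$log2fc[1:10] <- 1.5
    sc$padj[1:10] <- 0.01
    sc <- score_and_classify(de_table(sc$symbol, sc$log2fc, sc$padj))
    got <- rank_by_score(sc)$symbol
    want <- brute_force_rank(sc)$symbol
    expect_equal(got, want)
  }
})

test_that("volcano_coordinates exports reference lines and top-k labels", {
  sc <- random_scored(200, seed = 5)
  v <- volcano_coordinates(sc, alpha = 0.05, k_labels = 15)
  expect_equal(v$hline, -log10(0.05))
  expect_equal(round(v$hline, 3), 1.301)
  expect_equal(v$vline, 0)
  expect_equal(nrow(v$points), nrow(sc))
  expect_true(all(v$points$class %in% c("sig-up", "sig-down", "ns")))
  # labels are the top 15 per direction under the ranking oracle
  ranked <- brute_force_rank(sc)
  expect_equal(v$labels$up,
               head(ranked$symbol[as.character(ranked$direction) == "UP"], 15))
  expect_equal(v$labels$down,
               head(ranked$symbol[as.character(ranked$direction) == "DOWN"], 15))
  # all-NS table yields no labels
  ns <- score_and_classify(de_table(c("A", "B"), c(1, -1), c(0.5, 0.9)))
  vns <- volcano_coordinates(ns)
  expect_equal(length(vns$labels$up) + length(vns$labels$down), 0L)
  expect_error(volcano_coordinates(sc, k_labels = -1), "non-negative")
})
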