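#' Parse a differential-expression export table
#'
#' Reads a delimited DE results table (e.g. a GEO2R-style export) and returns
#' a standardized `de_table` with one row per gene symbol. Numeric fields are
#' parsed tolerantly: scientific-notation variants (`"2.08E-08"`, `"2.08e-8"`)
#' and the Unicode minus sign are normalized. Rows whose adjusted p-value (or
#' fold change) cannot be parsed are kept as padj-missing records and counted;
#' they are later classified `UNTESTED`.
#'
#' @param path Path to a TSV/CSV file with a header row, or a character vector
#'   of lines (useful for tests).
#' @param col_symbol,col_log2fc,col_padj Names of the columns carrying the
#'   gene symbol, the log2 fold change (positive = up-regulated in the case
#'   group) and the BH-adjusted p-value.
#' @param sep Field separator; `NULL` (default) auto-detects via
#'   [data.table::fread()].
#' @param duplicate_policy How to resolve rows sharing a symbol after
#'   normalization: `"min_padj"` (default) keeps the row with the smallest
#'   adjusted p-value (NA last; ties broken by larger |log2fc|) and records a
#'   warning; `"drop_all"` removes every duplicated symbol entirely.
#' @return A `data.frame` of class `de_table` with columns `symbol`, `log2fc`,
#'   `padj`, and attributes `provenance` (source and parse options) and
#'   `n_unparseable` / `n_duplicates`.
#' @examples
#' txt <- c("Gene.symbol\tlogFC\tadj.P.Val",
#'          "MIR219A2\t-3.005\t2.08E-08",
#'          "slc16a12\t4.094\t5.67e-15")
#' de <- parse_de_table(textConnection(txt), col_symbol = "Gene.symbol",
#'                      col_log2fc = "logFC", col_padj = "adj.P.Val")
#' de$symbol
#' @export
parse_de_table <- function(path,
                           col_symbol = "symbol",
                           col_log2fc = "log2fc",
                           col_padj = "padj",
                           sep = NULL,
                           duplicate_policy = c("min_padj", "drop_all")) {
  duplicate_policy <- match.arg(duplicate_policy)

  if (inherits(path, "connection")) {
    lines <- readLines(path)
    dt <- data.table::fread(text = lines, sep = sep %||% "auto",
                            colClasses = "character", header = TRUE)
    src <- "<connection>"
  } else if (length(path) == 1L && file.exists(path)) {
    dt <- data.table::fread(path, sep = sep %||% "auto",
                            colClasses = "character", header = TRUE)
    src <- path
  } else {
    dt <- data.table::fread(text = path, sep = sep %||% "auto",
                            colClasses = "character", header = TRUE)
    src <- "<text>"
  }

  for (cl in c(col_symbol, col_log2fc, col_padj)) {
    if (!cl %in% names(dt)) {
      stop_direnrich("column '%s' not found in DE table (columns: %s)",
                     cl, paste(names(dt), collapse = ", "))
    }
  }
  if (nrow(dt) == 0L) stop_direnrich("DE table is empty after the header row")

  symbol <- toupper(trimws(dt[[col_symbol]]))
  keep <- !is.na(symbol) & nzchar(symbol)
  if (!all(keep)) {
    warning(sprintf("%d row(s) with empty gene symbol dropped", sum(!keep)))
  }
  log2fc <- parse_numeric(dt[[col_log2fc]])[keep]
  padj <- parse_numeric(dt[[col_padj]])[keep]
  symbol <- symbol[keep]

  bad_padj <- !is.na(padj) & (padj < 0 | padj > 1)
  if (any(bad_padj)) {
    warning(sprintf("%d padj value(s) outside [0,1] set to missing",
                    sum(bad_padj)))
    padj[bad_padj] <- NA_real_
  }
  # a record with unparseable log2fc cannot be scored either
  padj[is.na(log2fc)] <- NA_real_
  n_unparseable <- sum(is.na(padj))

  out <- data.frame(symbol = symbol, log2fc = log2fc, padj = padj,
                    stringsAsFactors = FALSE)

  n_dup <- sum(duplicated(out$symbol))
  if (n_dup > 0L) {
    if (duplicate_policy == "min_padj") {
      ord <- order(out$symbol, is.na(out$padj), out$padj, -abs(out$log2fc))
      out <- out[ord, , drop = FALSE]
      out <- out[!duplicated(out$symbol), , drop = FALSE]
      warning(sprintf("%d duplicate symbol row(s) resolved by smallest padj",
                      n_dup))
    } else {
      dup_syms <- unique(out$symbol[duplicated(out$symbol)])
      out <- out[!out$symbol %in% dup_syms, , drop = FALSE]
      warning(sprintf("%d symbol(s) with duplicate rows dropped entirely",
                      length(dup_syms)))
    }
    out <- out[order(match(out$symbol, symbol)), , drop = FALSE]
  }
  rownames(out) <- NULL

  structure(out,
            class = c("de_table", "data.frame"),
            provenance = list(source = src, sep = sep,
                              columns = c(symbol = col_symbol,
                                          log2fc = col_log2fc,
                                          padj = col_padj),
                              duplicate_policy = duplicate_policy),
            n_unparseable = n_unparseable,
            n_duplicates = n_dup)
}

#' Build a `de_table` from vectors
#'
#' Convenience constructor used by the simulator and in tests; applies the
#' same normalization and invariants as [parse_de_table()].
#'
#' @param symbol Character vector of gene symbols (uppercased, trimmed).
#' @param log2fc Numeric log2 fold changes.
#' @param padj Numeric BH-adjusted p-values in `[0,1]`, `NA` allowed.
#' @return A `de_table`.
#' @export
de_table <- function(symbol, log2fc, padj) {
  symbol <- toupper(trimws(as.character(symbol)))
  stopifnot(length(symbol) == length(log2fc),
            length(symbol) == length(padj),
            all(nzchar(symbol)))
  if (anyDuplicated(symbol)) stop_direnrich("duplicate symbols in de_table()")
  padj <- as.numeric(padj)
  if (any(!is.na(padj) & (padj < 0 | padj > 1))) {
    stop_direnrich("padj values must be in [0,1] or NA")
  }
  structure(data.frame(symbol = symbol, log2fc = as.numeric(log2fc),
                       padj = padj, stringsAsFactors = FALSE),
            class = c("de_table", "data.frame"),
            provenance = list(source = "<constructed>"))
}

#' Score and classify DE records
#'
#' Computes the composite ranking score \eqn{S = |log2FC| \times
#' (-log10\,max(padj, padj\_floor))} and calls each gene's direction:
#' `UP` if `padj < alpha` and `log2fc > 0`, `DOWN` if `padj < alpha` and
#' `log2fc < 0`, `UNTESTED` if `padj` is missing, `NS` otherwise (including
#' the degenerate `log2fc == 0` with significant padj, whose direction is
#' undefined). S is a prioritization heuristic, not a significance test.
#'
#' @param table A `de_table` (or any data.frame with `symbol`, `log2fc`,
#'   `padj`).
#' @param alpha Significance threshold on the adjusted p-value (strict `<`);
#'   default 0.05.
#' @param padj_floor Positive floor applied to `padj` before the log so that
#'   reported zeros keep S finite; default `1e-300`.
#' @return A `scored_table`: the input with columns `s` (non-negative, `NA`
#'   for UNTESTED) and `direction` (factor UP/DOWN/NS/UNTESTED).
#' @examples
#' de <- de_table("SLC16A12", 4.094, 5.670e-15)
#' score_and_classify(de)$s   # ~58.32
#' @export
score_and_classify <- function(table, alpha = 0.05, padj_floor = 1e-300) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
            is.numeric(padj_floor), padj_floor > 0)
  req <- c("symbol", "log2fc", "padj")
  if (!all(req %in% names(table))) {
    stop_direnrich("table must have columns %s", paste(req, collapse = ", "))
  }
  padj <- table$padj
  lfc <- table$log2fc
  s <- abs(lfc) * -log10(pmax(padj, padj_floor))
  direction <- rep("NS", nrow(table))
  direction[!is.na(padj) & padj < alpha & lfc > 0] <- "UP"
  direction[!is.na(padj) & padj < alpha & lfc < 0] <- "DOWN"
  direction[is.na(padj)] <- "UNTESTED"
  s[is.na(padj)] <- NA_real_

  out <- table
  out$s <- s
  out$direction <- factor(direction,
                          levels = c("UP", "DOWN", "NS", "UNTESTED"))
  class(out) <- unique(c("scored_table", class(as.data.frame(out))))
  attr(out, "alpha") <- alpha
  attr(out, "padj_floor") <- padj_floor
  out
}

#' Rank scored records by composite score
#'
#' Deterministic total order: descending `s`; ties broken by smaller `padj`,
#' then larger `|log2fc|`, then lexicographic symbol. `UNTESTED` records
#' (missing padj) sort last, alphabetically.
#'
#' @param records A `scored_table` from [score_and_classify()].
#' @return The records reordered; a `scored_table`.
#' @export
rank_by_score <- function(records) {
  if (!"s" %in% names(records)) {
    stop_direnrich("records are not scored; call score_and_classify() first")
  }
  # every key must be NA-free: order() would otherwise push any row with an
  # NA in any key to the end, breaking the symbol tiebreak. UNTESTED records
  # (NA s) carry neutral keys so they sort last, alphabetically.
  untested <- is.na(records$s)
  ord <- order(untested,
               -ifelse(untested, 0, records$s),
               ifelse(is.na(records$padj), Inf, records$padj),
               -ifelse(untested, 0, abs(records$log2fc)),
               records$symbol,
               method = "radix")
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Volcano-plot coordinates and labels
#'
#' Exports plot-ready coordinates (`x = log2fc`, `y = -log10 padj`), the
#' significance class of each gene, reference lines (horizontal at
#' `-log10(alpha)`, i.e. 1.301 for alpha 0.05; vertical at `log2fc = 0`),
#' and the top `k_labels` genes per direction under the [rank_by_score()]
#' ordering. Rendering is out of scope; only coordinates are produced.
#'
#' @inheritParams rank_by_score
#' @param alpha Significance threshold (strict `<`).
#' @param k_labels Number of labels per direction; default 15.
#' @return A list with `points` (symbol, x, y, class in
#'   `sig-up`/`sig-down`/`ns`), `labels` (character vector, up labels then
#'   down labels), `hline` and `vline`.
#' @export
volcano_coordinates <- function(records, alpha = 0.05, k_labels = 15L) {
  if (k_labels < 0) stop_direnrich("k_labels must be non-negative")
  if (!"s" %in% names(records)) records <- score_and_classify(records, alpha)
  floor_ <- attr(records, "padj_floor") %||% 1e-300
  cls <- c(UP = "sig-up", DOWN = "sig-down", NS = "ns", UNTESTED = "ns")
  points <- data.frame(
    symbol = records$symbol,
    x = records$log2fc,
    y = -log10(pmax(records$padj, floor_)),
    class = unname(cls[as.character(records$direction)]),
    stringsAsFactors = FALSE)
  ranked <- rank_by_score(records)
  top <- function(dir) {
    head(ranked$symbol[as.character(ranked$direction) == dir], k_labels)
  }
  list(points = points,
       labels = list(up = top("UP"), down = top("DOWN")),
       hline = -log10(alpha),
       vline = 0)
}
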