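#' Construct a gene set
#'
#' Symbols are uppercased, trimmed, deduplicated; empty entries are dropped.
#'
#' @param name Set name.
#' @param symbols Character vector of gene symbols.
#' @param tier Evidence tier, one of `functional`, `clip`, `validated_any`,
#'   `tf_targets`, `marker`, `custom`.
#' @param source Free-text provenance note.
#' @param regulator_direction Optional DE direction of the set's focal
#'   regulator (`"up"` or `"down"`); used by [run_enrichment()] under
#'   `direction = "auto"` (a down-regulated miRNA relieves repression, so its
#'   targets are tested against the UP partition, and vice versa).
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, symbols,
                     tier = c("custom", "functional", "clip", "validated_any",
                              "tf_targets", "marker"),
                     source = NA_character_,
                     regulator_direction = NULL) {
  tier <- match.arg(tier)
  if (!is.null(regulator_direction)) {
    regulator_direction <- match.arg(regulator_direction, c("up", "down"))
  }
  structure(
    list(name = as.character(name),
         tier = tier,
         symbols = unique(normalize_symbols(symbols)),
         source = source,
         regulator_direction = regulator_direction),
    class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' [%s]: %d symbol(s)\n",
              x$name, x$tier, length(x$symbols)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Blank gene fields are
#' skipped and duplicate genes within a line collapsed.
#'
#' @param path Path to a GMT file, or a character vector of GMT lines.
#' @param tier Evidence tier assigned to every set read.
#' @return Named list of `gene_set` objects in file order.
#' @export
read_gmt <- function(path, tier = "custom") {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop_direnrich("GMT line %d has %d field(s); need name, description, >=1 gene",
                     i, length(f))
    }
    sets[[i]] <- gene_set(f[1], f[-(1:2)], tier = tier, source = f[2])
  }
  setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets List of `gene_set` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, ifelse(is.na(s$source), "na", s$source), s$symbols),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-column symbol list
#'
#' One symbol per row (header optional via `header`); used for flat exports
#' converted from CSV/XLSX target downloads.
#'
#' @param path File path.
#' @param name,tier Passed to [gene_set()].
#' @param header Whether the first row is a header; default FALSE.
#' @return A `gene_set`.
#' @export
read_symbol_list <- function(path, name = basename(path), tier = "custom",
                             header = FALSE) {
  x <- readLines(path)
  if (header && length(x)) x <- x[-1]
  gene_set(name, x, tier = tier, source = path)
}

#' Read cell-type marker panels
#'
#' Two-column delimited table `cell_type<TAB>symbol` (header required).
#'
#' @param path File path (TSV or CSV).
#' @return Named list of `gene_set` objects with tier `"marker"`, one per
#'   cell type.
#' @export
read_marker_panels <- function(path) {
  dt <- data.table::fread(path, colClasses = "character", header = TRUE)
  if (ncol(dt) < 2L) stop_direnrich("marker table needs columns cell_type, symbol")
  ct <- trimws(dt[[1]])
  mapply(function(nm, sym) gene_set(nm, sym, tier = "marker", source = path),
         names(split(dt[[2]], ct)), split(dt[[2]], ct),
         SIMPLIFY = FALSE)
}

#' Harmonize a gene set against an alias map
#'
#' Replaces alias symbols by their canonical symbol, case-normalizes, and
#' collapses duplicates. An alias mapping to two different canonical symbols
#' is ambiguous: it is dropped and reported. With a `NULL` map only
#' case/whitespace normalization is performed (no network lookup is ever
#' attempted; supply a curated alias table for true HGNC harmonization).
#'
#' @param set A `gene_set`.
#' @param alias_map `NULL`, a named character vector (`alias = canonical`),
#'   or a two-column data.frame (alias, canonical).
#' @return List with `set` (harmonized `gene_set`) and `report` (renamed,
#'   collapsed, dropped_ambiguous character vectors).
#' @export
harmonize <- function(set, alias_map = NULL) {
  stopifnot(inherits(set, "gene_set"))
  syms <- set$symbols # already normalized by the constructor
  if (is.data.frame(alias_map)) {
    alias_map <- setNames(as.character(alias_map[[2]]),
                          as.character(alias_map[[1]]))
  }
  renamed <- character()
  dropped <- character()
  if (!is.null(alias_map) && length(alias_map)) {
    alias <- toupper(trimws(names(alias_map)))
    canon <- toupper(trimws(unname(alias_map)))
    # an alias listed with >1 distinct canonical target is ambiguous
    n_targets <- tapply(canon, alias, function(v) length(unique(v)))
    ambiguous <- names(n_targets)[n_targets > 1]
    lut <- setNames(canon, alias)[!alias %in% ambiguous]
    hit <- syms %in% ambiguous
    dropped <- syms[hit]
    syms <- syms[!hit]
    idx <- match(syms, names(lut))
    changed <- !is.na(idx) & lut[idx] != syms
    renamed <- syms[changed]
    syms[!is.na(idx)] <- unname(lut[idx[!is.na(idx)]])
  }
  n_before <- length(syms)
  syms <- unique(syms)
  out <- set
  out$symbols <- syms
  list(set = out,
       report = list(renamed = renamed,
                     collapsed = n_before - length(syms),
                     dropped_ambiguous = dropped))
}

#' Combine gene sets
#'
#' @param sets List of `gene_set` objects (at least one).
#' @param mode `"union"` or `"intersection"`.
#' @param name Name of the combined set.
#' @param tier Evidence tier of the result (e.g. `"validated_any"` for a
#'   functional-with-CLIP union).
#' @param regulator_direction Passed to [gene_set()].
#' @return A `gene_set`.
#' @export
combine_sets <- function(sets, mode = c("union", "intersection"),
                         name = NULL, tier = "custom",
                         regulator_direction = NULL) {
  mode <- match.arg(mode)
  if (length(sets) < 1L) stop_direnrich("combine_sets() needs at least one set")
  stopifnot(all(vapply(sets, inherits, TRUE, "gene_set")))
  syms <- lapply(sets, `[[`, "symbols")
  out <- Reduce(if (mode == "union") union else intersect, syms)
  nm <- name %||% paste(vapply(sets, `[[`, "", "name"),
                        collapse = if (mode == "union") "|" else "&")
  gene_set(nm, out, tier = tier, regulator_direction = regulator_direction)
}

#' Restrict a gene set to a background
#'
#' Intersects the set with the expressed-gene background it will be tested
#' against, reporting how many symbols were dropped.
#'
#' @param set A `gene_set`.
#' @param background Character vector of background symbols (or a `universe`).
#' @return List with `set` (restricted `gene_set`) and `dropped` (count).
#' @export
restrict_to_background <- function(set, background) {
  stopifnot(inherits(set, "gene_set"))
  if (inherits(background, "universe")) background <- background$background
  background <- normalize_symbols(background)
  out <- set
  out$symbols <- set$symbols[set$symbols %in% background]
  list(set = out, dropped = length(set$symbols) - length(out$symbols))
}

#' Per-regulator coverage of a gene subset (descriptive)
#'
#' For each regulon, counts how many of its targets fall in `subset`.
#' Purely descriptive (no p-values): mirrors listing regulators with multiple
#' targets inside an overlap subset for target-level transparency.
#'
#' @param subset Character vector of symbols (or a `gene_set`).
#' @param regulons List of `gene_set` objects (TF regulons).
#' @return data.frame (`regulator`, `n_regulon`, `overlap`) sorted by
#'   descending overlap, ties broken lexicographically.
#' @export
tf_coverage <- function(subset, regulons) {
  if (inherits(subset, "gene_set")) subset <- subset$symbols
  subset <- unique(normalize_symbols(subset))
  out <- data.frame(
    regulator = vapply(regulons, `[[`, "", "name"),
    n_regulon = vapply(regulons, function(s) length(s$symbols), 0L),
    overlap = vapply(regulons, function(s) sum(s$symbols %in% subset), 0L),
    stringsAsFactors = FALSE)
  out <- out[order(-out$overlap, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}
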