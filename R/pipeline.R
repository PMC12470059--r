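# leveled logging; warnings are also collected into the run manifest
pipeline_log <- function(level, fmt, ..., log_level = "info") {
  ranks <- c(debug = 0, info = 1, warning = 2, error = 3)
  if (ranks[[level]] >= ranks[[log_level]]) {
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
}

write_tsv <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", na = "NA")
  path
}

#' Run the full direction-aware enrichment pipeline
#'
#' Orchestrates every stage from a configuration: parse (or simulate) the DE
#' table, score and rank, build the core signature, construct the
#' expressed-gene universe, run family-wise enrichment over the configured
#' gene sets, and (when marker/strata inputs are present) the sensitivity
#' re-tests. All outputs are written under `out_dir` alongside a run
#' manifest (config echo, seed, package version, input checksums, collected
#' warnings) sufficient to reproduce the run.
#'
#' Recognized config keys: `de_table`, `col_symbol`/`col_log2fc`/`col_padj`,
#' `gmt`, `markers`, `strata`, `family.<id> = set1,set2,...`, `alpha`,
#' `core_size`, `direction` (up/down/auto), `term_min`, `term_max`,
#' `min_overlap`, `size_filter`, `seed`, `out_dir`, `simulate` (generate a
#' synthetic bundle first), `log_level`.
#'
#' @param config A `pipeline_config` from [read_pipeline_config()], a plain
#'   named list, or a path to a config file.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return Invisibly, a list with `ranked`, `core`, `universe`,
#'   `enrichment`, `sensitivity` (or NULL), and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  cfg <- modifyList(default_pipeline_config(), as.list(config))
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) {
    stop_direnrich("stage config: alpha must be in (0,1)")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_seen <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_direnrich("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  lvl <- cfg$log_level

  if (isTRUE(cfg$simulate)) {
    pipeline_log("info", "simulating input bundle (seed %d)", cfg$seed,
                 log_level = lvl)
    sc_args <- cfg[intersect(names(cfg),
                             names(formals(sim_config)))]
    sc <- do.call(sim_config, sc_args)
    bundle <- stage("simulate", {
      sim <- simulate_de_table(sc, seed = cfg$seed)
      u0 <- build_universe(score_and_classify(sim$table, cfg$alpha),
                           cfg$alpha)
      target <- plant_target_set(u0, sc$omega, sc$n_target,
                                 seed = cfg$seed + 1L)
      mk <- simulate_marker_panels(sc, u0, seed = cfg$seed + 2L)
      list(sim = sim, target = target, mk = mk)
    })
    cfg$de_table <- file.path(cfg$out_dir, "simulated_de.tsv")
    write_tsv(bundle$sim$table, cfg$de_table)
    write_tsv(bundle$sim$truth, file.path(cfg$out_dir, "simulated_truth.tsv"))
    cfg$gmt <- file.path(cfg$out_dir, "simulated_sets.gmt")
    write_gmt(list(bundle$target), cfg$gmt)
    cfg$markers <- file.path(cfg$out_dir, "simulated_markers.tsv")
    mdf <- do.call(rbind, lapply(bundle$mk$panels, function(p)
      data.frame(cell_type = p$name, symbol = p$symbols)))
    write_tsv(mdf, cfg$markers)
    cfg$strata <- file.path(cfg$out_dir, "simulated_strata.tsv")
    write_tsv(data.frame(symbol = names(bundle$mk$strata),
                         stratum = unname(bundle$mk$strata)), cfg$strata)
  }

  for (key in c("de_table", "gmt", "markers", "strata")) {
    if (!is.null(cfg[[key]]) && !all(file.exists(cfg[[key]]))) {
      stop_direnrich("config path for '%s' does not exist: %s", key,
                     paste(cfg[[key]][!file.exists(cfg[[key]])],
                           collapse = ", "))
    }
  }
  if (is.null(cfg$de_table)) stop_direnrich("config lacks 'de_table'")

  pipeline_log("info", "parsing DE table %s", cfg$de_table, log_level = lvl)
  de <- collect(stage("de_ingest",
    parse_de_table(cfg$de_table, cfg$col_symbol, cfg$col_log2fc,
                   cfg$col_padj)))
  scored <- stage("score", score_and_classify(de, cfg$alpha))
  ranked <- rank_by_score(scored)
  write_tsv(ranked, file.path(cfg$out_dir, "ranked.tsv"))

  core <- collect(stage("core", build_core(ranked, cfg$core_size, cfg$alpha)))
  write_tsv(core_as_table(core, ranked), file.path(cfg$out_dir, "core.tsv"))
  jsonlite::write_json(
    list(size = nrow(core$members), n_up = length(core$up),
         n_down = length(core$down)),
    file.path(cfg$out_dir, "core.json"), auto_unbox = TRUE)

  univ <- stage("universe", build_universe(scored, cfg$alpha))
  pipeline_log("info", "universe: M=%d K_up=%d K_down=%d", univ$M,
               univ$K_up, univ$K_down, log_level = lvl)

  enr <- sens <- NULL
  if (!is.null(cfg$gmt)) {
    sets <- stage("gene_sets",
                  unlist(lapply(cfg$gmt, read_gmt), recursive = FALSE))
    # planted simulator sets emulate targets of a down-regulated regulator
    if (isTRUE(cfg$simulate)) {
      sets <- lapply(sets, function(s) {
        s$regulator_direction <- "down"; s
      })
    }
    enr <- stage("enrichment", run_enrichment(
      univ, sets, direction = cfg$direction, families = cfg$families,
      term_min = cfg$term_min, term_max = cfg$term_max,
      min_overlap = cfg$min_overlap, size_filter = isTRUE(cfg$size_filter)))
    write_tsv(enr, file.path(cfg$out_dir, "enrichment.tsv"))
    jsonlite::write_json(enr, file.path(cfg$out_dir, "enrichment.json"),
                         dataframe = "rows", digits = NA, na = "null")

    variants <- list()
    if (!is.null(cfg$markers)) {
      panels <- stage("markers", read_marker_panels(cfg$markers))
      u_ex <- stage("sensitivity", exclude_markers(univ, panels))
      variants$marker_excluded <- run_enrichment(
        u_ex, sets, direction = cfg$direction, families = cfg$families,
        term_min = cfg$term_min, term_max = cfg$term_max,
        min_overlap = cfg$min_overlap, size_filter = isTRUE(cfg$size_filter))
    }
    if (!is.null(cfg$strata)) {
      smap <- data.table::fread(cfg$strata, colClasses = "character")
      strata <- stage("sensitivity", stratify(univ, as.data.frame(smap)))
      for (lb in names(strata)) {
        u_s <- strata[[lb]]
        if (isTRUE(attr(u_s, "untestable"))) next
        ok <- tryCatch(run_enrichment(
          u_s, sets, direction = cfg$direction, families = cfg$families,
          term_min = cfg$term_min, term_max = cfg$term_max,
          min_overlap = cfg$min_overlap,
          size_filter = isTRUE(cfg$size_filter)), error = function(e) NULL)
        if (!is.null(ok)) variants[[paste0("stratum_", lb)]] <- ok
      }
    }
    if (length(variants)) {
      sens <- collect(consistency_report(enr, variants))
      write_tsv(sens, file.path(cfg$out_dir, "sensitivity.tsv"))
      jsonlite::write_json(sens, file.path(cfg$out_dir, "sensitivity.json"),
                           dataframe = "rows", digits = NA, na = "null")
    }
  }

  inputs <- unlist(cfg[c("de_table", "gmt", "markers", "strata")])
  manifest <- list(
    package = "direnrich",
    version = as.character(utils::packageVersion("direnrich")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "families")],
    families = cfg$families,
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    universe = list(M = univ$M, K_up = univ$K_up, K_down = univ$K_down),
    warnings = warnings_seen)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(render_report(enr), file.path(cfg$out_dir, "report.txt"))

  invisible(list(ranked = ranked, core = core, universe = univ,
                 enrichment = enr, sensitivity = sens, manifest = manifest))
}
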