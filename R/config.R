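#' Read a pipeline configuration file
#'
#' Minimal TOML-like `key = value` format: one assignment per line, `#`
#' comments, optional quotes around strings, comma-separated lists, and
#' `true`/`false` booleans. Families are declared as
#' `family.<id> = set1, set2, ...`.
#'
#' @param path Path to the config file.
#' @return A named list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_direnrich("config file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    val <- gsub('^"|"$', "", val)
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (length(parts) && !any(is.na(num))) num
      else if (length(parts) == 1L && tolower(parts) %in% c("true", "false"))
        tolower(parts) == "true"
      else parts
    if (startsWith(key, "family.")) {
      fam <- sub("^family\\.", "", key)
      cfg$families[[fam]] <- as.character(parsed)
    } else {
      cfg[[key]] <- parsed
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

# defaults merged under user values
default_pipeline_config <- function() {
  list(alpha = 0.05, core_size = 80, direction = "up",
       term_min = 5, term_max = 500, min_overlap = 2, size_filter = TRUE,
       seed = 1, out_dir = ".", col_symbol = "symbol",
       col_log2fc = "log2fc", col_padj = "padj", simulate = FALSE,
       log_level = "info")
}
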