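#' Build a fixed-size, direction-preserving core signature
#'
#' Retains the top `size` genes with `padj < alpha`, ordered by the composite
#' score under the deterministic tie rule of [rank_by_score()] (smaller padj,
#' then larger |log2fc|, then symbol). Direction is preserved: the members
#' carry their UP/DOWN calls and are partitioned accordingly. No threshold on
#' S itself is applied — significance alone gates membership, S only orders.
#' If fewer than `size` genes are significant, all of them are returned with
#' a warning.
#'
#' @param records A `scored_table` (ranked or not; ranking is applied).
#' @param size Target signature size; default 80.
#' @param alpha Significance threshold (strict `<`); default 0.05.
#' @return A `core_signature`: list with `members` (scored records in rank
#'   order), `up` / `down` (symbol vectors), `size_requested`, `alpha`.
#' @examples
#' cfg <- sim_config(M = 500, seed = 7)
#' sim <- simulate_de_table(cfg)
#' core <- build_core(score_and_classify(sim$table), size = 20)
#' length(core$up) + length(core$down)  # 20
#' @export
build_core <- function(records, size = 80L, alpha = 0.05) {
  if (!is.numeric(size) || length(size) != 1L || size < 1) {
    stop_direnrich("size must be a positive integer")
  }
  size <- as.integer(size)
  if (!"s" %in% names(records)) records <- score_and_classify(records, alpha)
  ranked <- rank_by_score(records)
  sig <- ranked[!is.na(ranked$padj) & ranked$padj < alpha, , drop = FALSE]
  if (nrow(sig) < size) {
    warning(sprintf("only %d significant gene(s) available for a size-%d core",
                    nrow(sig), size))
  }
  members <- head(sig, size)
  rownames(members) <- NULL
  structure(
    list(members = members,
         up = members$symbol[as.character(members$direction) == "UP"],
         down = members$symbol[as.character(members$direction) == "DOWN"],
         size_requested = size,
         alpha = alpha),
    class = "core_signature")
}

#' Partition a core signature by direction
#'
#' @param core A `core_signature` from [build_core()].
#' @return List with `up` and `down` symbol vectors plus `n_up`, `n_down`.
#' @export
partition_directions <- function(core) {
  stopifnot(inherits(core, "core_signature"))
  list(up = core$up, down = core$down,
       n_up = length(core$up), n_down = length(core$down))
}

#' @export
print.core_signature <- function(x, ...) {
  cat(sprintf("core signature: %d gene(s) (requested %d, alpha %g): %d up, %d down\n",
              nrow(x$members), x$size_requested, x$alpha,
              length(x$up), length(x$down)))
  invisible(x)
}

#' Export a core signature as a flat table
#'
#' @param core A `core_signature`.
#' @param all_records Optional full `scored_table`; when given, every record
#'   is returned with an `in_core` flag, otherwise only members.
#' @return data.frame with columns of the scored records plus `in_core`.
#' @export
core_as_table <- function(core, all_records = NULL) {
  stopifnot(inherits(core, "core_signature"))
  if (is.null(all_records)) {
    out <- core$members
    out$in_core <- TRUE
    return(out)
  }
  out <- rank_by_score(all_records)
  out$in_core <- out$symbol %in% core$members$symbol
  out
}
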