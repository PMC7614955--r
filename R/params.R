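#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with its default, grouped by
#' stage. Values supplied as arguments override the defaults; validation is
#' strict so a typo in a key is an error, not a silent no-op.
#'
#' @param tm TM-scan parameters, see [tm_params()].
#' @param motif Motif-scan parameters: `match_score`, `threshold_frac`,
#'   `max_hits_per_kind`.
#' @param classify Classification parameters: `tolerance` (allowed
#'   per-stretch helix-count deviation).
#' @param align Alignment/distance parameters: `match`, `mismatch`, `gap`
#'   (per-residue, linear), `distance_cap` (ceiling for the Poisson-corrected
#'   distance as p approaches 1).
#' @param group Paralogue-group assignment parameters: `min_margin`
#'   (expected substitutions per site below which a query stays
#'   `UNASSIGNED`).
#' @param seed Integer seed for any stochastic step.
#' @return Validated named list of class `nth_params`.
#' @export
nth_params <- function(tm = tm_params(),
                       motif = list(match_score = 2, threshold_frac = 0.6,
                                    max_hits_per_kind = 1),
                       classify = list(tolerance = 2),
                       align = list(match = 1, mismatch = -1, gap = -2,
                                    distance_cap = 10),
                       group = list(min_margin = 0.02),
                       seed = 1L) {
  defaults <- list(
    motif = list(match_score = 2, threshold_frac = 0.6, max_hits_per_kind = 1),
    classify = list(tolerance = 2),
    align = list(match = 1, mismatch = -1, gap = -2, distance_cap = 10),
    group = list(min_margin = 0.02)
  )
  fill <- function(given, def, where) {
    unknown <- setdiff(names(given), names(def))
    if (length(unknown) > 0L) {
      abort(sprintf("Unknown %s parameter(s): %s.", where,
                    paste(unknown, collapse = ", ")))
    }
    utils::modifyList(def, given)
  }
  p <- list(
    tm = do.call(tm_params, as.list(tm)),
    motif = fill(motif, defaults$motif, "motif"),
    classify = fill(classify, defaults$classify, "classify"),
    align = fill(align, defaults$align, "align"),
    group = fill(group, defaults$group, "group"),
    seed = as.integer(seed)
  )
  stopifnot(p$classify$tolerance >= 0, p$align$distance_cap > 0,
            p$group$min_margin >= 0)
  class(p) <- c("nth_params", "list")
  p
}

#' Read a run configuration from a YAML file
#'
#' Loads a YAML file whose top-level keys are the argument names of
#' [nth_params()] (`tm`, `motif`, `classify`, `align`, `group`, `seed`) and
#' validates it. Unknown keys at any level are rejected.
#'
#' @param path Path to a YAML configuration file.
#' @return Validated `nth_params` object.
#' @export
read_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("tm", "motif", "classify", "align", "group", "seed")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown configuration key(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  do.call(nth_params, cfg)
}
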