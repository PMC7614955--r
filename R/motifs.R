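#' Packaged dinucleotide-binding motif library
#'
#' Position score matrices for the NAD(H)-binding domain (DOMAIN_I) and the
#' NADP(H)-binding domain (DOMAIN_III), built from short Rossmann-fold-style
#' consensus strings authored in this package (both carry the classical
#' glycine-rich G-x-G-x-x-G dinucleotide-binding fingerprint). Each matrix
#' scores `match_score` for the consensus residue at a position and 0 for any
#' other residue; `X` always scores 0. Acceptance thresholds default to 60%
#' of each motif's maximum score, which sits far above the score distribution
#' of unrelated sequence. These matrices are a desk-scale functional
#' stand-in for curated domain models (profile HMM search is deliberately out
#' of scope); externally produced annotations can be supplied through
#' [parse_external_annotations()] instead.
#'
#' @param match_score Score for the consensus residue at each position.
#' @param threshold_frac Acceptance threshold as a fraction of the maximum
#'   attainable score.
#' @return A list with one entry per domain kind, each holding `consensus`,
#'   `matrix` (positions x residues) and `threshold`.
#' @export
nth_motif_library <- function(match_score = 2, threshold_frac = 0.6) {
  consensus <- c(
    DOMAIN_I   = "EKVAITGSGQAGRNAAKELSKDGHEVTGIDRSENKLDEAKSLGIETLN",
    DOMAIN_III = "GKSEVTVIGAGQTGLSAAREASEMGNEVTVIEQSDRLLPSYDKDMSQN"
  )
  lapply(consensus, function(cons) {
    chars <- strsplit(cons, "", fixed = TRUE)[[1]]
    m <- matrix(0, nrow = length(chars), ncol = 21,
                dimnames = list(NULL, c(AA20, "X")))
    m[cbind(seq_along(chars), match(chars, colnames(m)))] <- match_score
    list(consensus = cons, matrix = m,
         threshold = threshold_frac * match_score * length(chars))
  })
}

#' Score a position matrix along a sequence
#'
#' Slides a position score matrix over the sequence and returns the summed
#' score at every alignment offset.
#'
#' @param sequence Amino-acid string.
#' @param matrix Position score matrix (rows = motif positions, columns named
#'   by residue, including `X`).
#' @return Tibble with `offset` (0-based) and `score`, one row per placement;
#'   zero rows (with a warning) when the motif is longer than the sequence.
#' @export
score_motif <- function(sequence, matrix) {
  chars <- check_sequence(sequence)
  L <- nrow(matrix)
  n <- length(chars)
  if (L > n) {
    warn("Motif longer than sequence; returning no placements.")
    return(tibble(offset = integer(), score = double()))
  }
  idx <- match(chars, colnames(matrix))
  offsets <- 0:(n - L)
  score <- vapply(offsets, function(o) {
    sum(matrix[cbind(seq_len(L), idx[o + seq_len(L)])])
  }, numeric(1))
  tibble(offset = offsets, score = score)
}

#' Locate NAD(H)- and NADP(H)-binding domains
#'
#' Scans the sequence with each motif in the library and reports
#' non-overlapping placements scoring at or above the library threshold.
#' Selection is greedy: best score first, ties broken by smaller start, a hit
#' overlapping an already accepted hit (of any kind) is skipped, and at most
#' `max_hits_per_kind` hits are kept per domain kind.
#'
#' @param sequence Amino-acid string.
#' @param library Motif library, see [nth_motif_library()].
#' @param max_hits_per_kind Cap on reported hits per domain kind.
#' @return Tibble with `kind` (`DOMAIN_I`/`DOMAIN_III`), `start`, `end`
#'   (0-based half-open) and `score`, sorted by `start`.
#' @export
find_domains <- function(sequence, library = nth_motif_library(),
                         max_hits_per_kind = 1) {
  stopifnot(all(c("DOMAIN_I", "DOMAIN_III") %in% names(library)))
  cand <- bind_rows(imap(library, function(entry, kind) {
    sc <- score_motif(sequence, entry$matrix)
    sc |>
      filter(.data$score >= entry$threshold) |>
      mutate(kind = kind, start = .data$offset,
             end = .data$offset + nrow(entry$matrix))
  }))
  if (nrow(cand) == 0L) {
    return(tibble(kind = character(), start = integer(), end = integer(),
                  score = double()))
  }
  cand <- arrange(cand, desc(.data$score), .data$start)
  taken <- cand[0, ]
  kind_count <- c(DOMAIN_I = 0L, DOMAIN_III = 0L)
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    if (kind_count[[row$kind]] >= max_hits_per_kind) next
    overlaps <- nrow(taken) > 0L &&
      any(row$start < taken$end & taken$start < row$end)
    if (overlaps) next
    taken <- bind_rows(taken, row)
    kind_count[[row$kind]] <- kind_count[[row$kind]] + 1L
  }
  taken |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    select("kind", "start", "end", "score") |>
    arrange(.data$start)
}

#' Parse externally produced domain and topology annotations
#'
#' Reads a canonical annotation table (for example converted from SMART/Pfam
#' domain analysis or DeepTMHMM topology output) and converts it to the
#' internal representation. Input coordinates are 1-based inclusive, as is
#' conventional for such predictors; internal coordinates are 0-based
#' half-open.
#'
#' @param table Data frame with columns `protein_id`, `feature_type` (one of
#'   `NAD_binding`, `NADP_binding`, `TMhelix`), `start`, `end`.
#' @return Tibble with `protein_id`, `element_type` (`DOMAIN_I`,
#'   `DOMAIN_III`, `TM_HELIX`), `start`, `end` (0-based half-open), sorted
#'   within protein.
#' @export
parse_external_annotations <- function(table) {
  table <- as_tibble(table)
  needed <- c("protein_id", "feature_type", "start", "end")
  if (!all(needed %in% names(table))) {
    abort(paste0("Annotation table must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (nrow(table) == 0L) {
    return(tibble(protein_id = character(), element_type = character(),
                  start = integer(), end = integer()))
  }
  type_map <- c(NAD_binding = "DOMAIN_I", NADP_binding = "DOMAIN_III",
                TMhelix = "TM_HELIX")
  unknown <- which(!table$feature_type %in% names(type_map))
  if (length(unknown) > 0L) {
    abort(sprintf("Unknown feature_type '%s' in annotation row(s) %s.",
                  table$feature_type[unknown[1]],
                  paste(unknown, collapse = ", ")))
  }
  bad <- which(table$end < table$start)
  if (length(bad) > 0L) {
    abort(sprintf("end < start in annotation row(s) %s.",
                  paste(bad, collapse = ", ")))
  }
  table |>
    mutate(element_type = unname(type_map[.data$feature_type]),
           start = as.integer(.data$start) - 1L,
           end = as.integer(.data$end)) |>
    select("protein_id", "element_type", "start", "end") |>
    arrange(.data$protein_id, .data$start)
}
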