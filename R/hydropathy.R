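#' Kyte-Doolittle hydropathy scale
#'
#' Named vector of per-residue hydropathy indices for the 20 canonical amino
#' acids. The unknown residue `X` scores 0 wherever the scale is applied.
#'
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' kyte_doolittle()[c("I", "R")]
kyte_doolittle <- function() {
  c(I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
    E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

#' Transmembrane-scan parameters
#'
#' Defaults for the sliding-window hydropathy scan and helix grouping.
#' `window` is the (odd) smoothing window in residues; residues whose
#' windowed mean hydropathy reaches `threshold` seed candidate helices.
#' Candidate runs separated by fewer than `min_loop_len` residues are merged,
#' runs longer than `max_helix_len` are split at their least hydrophobic
#' interior residue, and shorter runs are grown to `min_helix_len`.
#' Consecutive helices up to `max_gap` residues apart belong to the same
#' TM stretch.
#'
#' @param window Odd integer, sliding-window width (residues).
#' @param threshold Mean hydropathy required to call a residue membrane-like.
#' @param min_helix_len,max_helix_len Bounds on reported helix length.
#' @param min_loop_len Minimum soluble gap between distinct helices.
#' @param max_gap Maximum inter-helix gap within one TM stretch.
#' @return Named list of scan parameters.
#' @export
tm_params <- function(window = 19, threshold = 1.6, min_helix_len = 15,
                      max_helix_len = 30, min_loop_len = 4, max_gap = 80) {
  stopifnot(window >= 3, window %% 2 == 1, threshold > 0,
            min_helix_len > 0, max_helix_len >= 2 * min_helix_len,
            min_loop_len > 0, max_gap > 0)
  list(window = window, threshold = threshold, min_helix_len = min_helix_len,
       max_helix_len = max_helix_len, min_loop_len = min_loop_len,
       max_gap = max_gap)
}

check_sequence <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || nchar(sequence) == 0L) {
    abort("`sequence` must be a single non-empty amino-acid string.")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(AA20, "X"))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Non-canonical residue '%s' at position %d (0-based %d); only the 20 canonical amino acids and X are accepted.",
      chars[bad[1]], bad[1], bad[1] - 1L))
  }
  chars
}

#' Per-residue windowed hydropathy profile
#'
#' Computes the mean Kyte-Doolittle hydropathy over a centered window at each
#' residue. Windows are truncated at the termini, so the profile has exactly
#' one value per residue.
#'
#' @param sequence Amino-acid string (canonical alphabet plus `X`, which
#'   scores 0).
#' @param window Odd window width, at least 3.
#' @return Numeric vector, one value per residue.
#' @export
#' @examples
#' hydropathy_profile(strrep("I", 19), window = 19)[1]
hydropathy_profile <- function(sequence, window = 19) {
  chars <- check_sequence(sequence)
  n <- length(chars)
  stopifnot(window >= 3, window %% 2 == 1, window <= n)
  scale <- c(kyte_doolittle(), X = 0)
  vals <- unname(scale[chars])
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(vals))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Maximal runs of TRUE in a logical vector, as a two-column matrix of
# 1-based inclusive [start, end] indices.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# Split a run (1-based inclusive) longer than max_len at its least
# hydrophobic interior residue, constrained so both pieces keep at least
# min_len residues; leftmost minimum wins. Recursive.
split_run <- function(s, e, profile, min_len, max_len) {
  len <- e - s + 1L
  if (len <= max_len) return(cbind(s, e))
  cand <- seq.int(s + min_len, e - min_len)
  cut <- cand[which.min(profile[cand])]
  rbind(split_run(s, cut - 1L, profile, min_len, max_len),
        split_run(cut + 1L, e, profile, min_len, max_len))
}

#' Predict transmembrane helices by hydropathy scanning
#'
#' Calls maximal runs of residues whose windowed hydropathy reaches the
#' threshold, merges runs separated by less than `min_loop_len`, splits runs
#' exceeding `max_helix_len` at their least hydrophobic interior residue
#' (leftmost minimum on ties, applied recursively), and grows runs shorter
#' than `min_helix_len` symmetrically to the minimum length (never across a
#' neighbouring helix or the sequence ends). The result is deterministic for
#' fixed inputs.
#'
#' @param sequence Amino-acid string.
#' @param params Scan parameters from [tm_params()].
#' @return Tibble with columns `start`, `end` (0-based half-open) and
#'   `mean_hydropathy`, sorted and non-overlapping.
#' @export
#' @examples
#' seq <- paste0(strrep("E", 20), strrep("L", 21), strrep("E", 20))
#' predict_tm_helices(seq)
predict_tm_helices <- function(sequence, params = tm_params()) {
  profile <- hydropathy_profile(sequence, params$window)
  n <- length(profile)
  runs <- true_runs(profile >= params$threshold)
  if (nrow(runs) == 0L) {
    return(tibble(start = integer(), end = integer(),
                  mean_hydropathy = double()))
  }

  # merge runs whose separating loop is shorter than min_loop_len
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      gap <- runs[i, 1] - merged[nrow(merged), 2] - 1L
      if (gap < params$min_loop_len) {
        merged[nrow(merged), 2] <- runs[i, 2]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }

  # split over-long runs
  pieces <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    split_run(merged[i, 1], merged[i, 2], profile,
              params$min_helix_len, params$max_helix_len)
  }))

  # grow short runs to min_helix_len, bounded by neighbours and termini
  for (i in seq_len(nrow(pieces))) {
    deficit <- params$min_helix_len - (pieces[i, 2] - pieces[i, 1] + 1L)
    if (deficit <= 0L) next
    left_bound <- if (i == 1L) 1L else pieces[i - 1L, 2] + 1L
    right_bound <- if (i == nrow(pieces)) n else pieces[i + 1L, 1] - 1L
    add_left <- min((deficit + 1L) %/% 2L, pieces[i, 1] - left_bound)
    pieces[i, 1] <- pieces[i, 1] - add_left
    add_right <- min(deficit - add_left, right_bound - pieces[i, 2])
    pieces[i, 2] <- pieces[i, 2] + add_right
    still <- deficit - add_left - add_right
    if (still > 0L) {
      pieces[i, 1] <- pieces[i, 1] - min(still, pieces[i, 1] - left_bound)
    }
  }

  tibble(
    start = as.integer(pieces[, 1] - 1L),
    end = as.integer(pieces[, 2]),
    mean_hydropathy = map_dbl(seq_len(nrow(pieces)),
                              function(i) mean(profile[pieces[i, 1]:pieces[i, 2]]))
  )
}

#' Group transmembrane helices into stretches
#'
#' Consecutive helices belong to the same stretch when their gap is at most
#' `max_gap` residues and no `split_points` interval (typically a soluble
#' domain hit) lies wholly inside the gap.
#'
#' @param helices Tibble of helices (`start`, `end`, 0-based half-open),
#'   sorted and non-overlapping.
#' @param split_points Optional tibble/data frame of intervals (`start`,
#'   `end`) that force a stretch boundary when contained in an inter-helix
#'   gap.
#' @param max_gap Maximum within-stretch inter-helix gap (residues).
#' @return Tibble with one row per stretch: `stretch`, `start`, `end`,
#'   `n_helices`, and a list-column `helices` of the member helices.
#' @export
group_stretches <- function(helices, split_points = NULL, max_gap = 80) {
  if (nrow(helices) == 0L) {
    return(tibble(stretch = integer(), start = integer(), end = integer(),
                  n_helices = integer(), helices = list()))
  }
  if (is.unsorted(helices$start, strictly = TRUE) ||
      any(helices$start[-1] < helices$end[-nrow(helices)])) {
    abort("`helices` must be sorted by start and non-overlapping.")
  }
  sp <- if (is.null(split_points) || nrow(split_points) == 0L) {
    matrix(numeric(), ncol = 2)
  } else {
    o <- order(split_points$start)
    m <- cbind(split_points$start[o], split_points$end[o])
    if (any(m[-1, 1] < m[-nrow(m), 2])) abort("`split_points` must be non-overlapping.")
    m
  }

  stretch_id <- integer(nrow(helices))
  stretch_id[1] <- 1L
  for (i in seq_len(nrow(helices))[-1]) {
    gap_lo <- helices$end[i - 1L]      # half-open: gap is [gap_lo, gap_hi)
    gap_hi <- helices$start[i]
    gap <- gap_hi - gap_lo
    hit_inside <- nrow(sp) > 0L && any(sp[, 1] >= gap_lo & sp[, 2] <= gap_hi)
    new_stretch <- gap > max_gap || hit_inside
    stretch_id[i] <- stretch_id[i - 1L] + as.integer(new_stretch)
  }

  helices |>
    mutate(.stretch = stretch_id) |>
    group_by(.data$.stretch) |>
    summarise(helices = list(dplyr::pick("start", "end")),
              n_helices = n(),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    mutate(stretch = row_number()) |>
    select("stretch", "start", "end", "n_helices", "helices")
}
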