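aa_substitution_matrix <- function(match = 1, mismatch = -1) {
  letters21 <- c(AA20, "X")
  m <- matrix(mismatch, 21, 21, dimnames = list(letters21, letters21))
  diag(m) <- match
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

#' Pairwise distance between two protein sequences
#'
#' Globally aligns the two sequences (Needleman-Wunsch, linear gap penalty,
#' via `Biostrings::pairwiseAlignment()`) and computes either the
#' p-distance (mismatches over aligned gap-free columns) or its Poisson
#' correction `-log(1 - p)`, capped at `distance_cap` as p approaches 1.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @param mode `"p_distance"` or `"poisson"`.
#' @param match,mismatch,gap Alignment scores (gap is the per-residue linear
#'   penalty, negative).
#' @param distance_cap Ceiling for the Poisson distance.
#' @return Single non-negative distance.
#' @export
#' @examples
#' pairwise_distance("AAAA", "AAAT")
pairwise_distance <- function(seq_a, seq_b, mode = c("p_distance", "poisson"),
                              match = 1, mismatch = -1, gap = -2,
                              distance_cap = 10) {
  mode <- match.arg(mode)
  check_sequence(seq_a)
  check_sequence(seq_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = aa_substitution_matrix(match, mismatch),
    gapOpening = 0, gapExtension = -gap, type = "global")
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cols <- a != "-" & b != "-"
  if (!any(cols)) abort("Alignment has no gap-free columns.")
  p <- sum(a[cols] != b[cols]) / sum(cols)
  switch(mode,
         p_distance = p,
         poisson = if (p >= 1 - exp(-distance_cap)) distance_cap else -log(1 - p))
}

#' All-pairs distance matrix
#'
#' @param sequences Named character vector or tibble with `id` and
#'   `sequence` columns.
#' @param ... Passed to [pairwise_distance()].
#' @return Symmetric matrix with zero diagonal, labelled by sequence id.
#' @export
distance_matrix <- function(sequences, ...) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$id)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    abort("Sequences must carry unique names.")
  }
  n <- length(sequences)
  m <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- pairwise_distance(sequences[[i]], sequences[[j]], ...)
        m[i, j] <- d
        m[j, i] <- d
      }
    }
  }
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (through `ape::nj()`), with
#' negative branch lengths clamped to zero. On matrices that are exactly
#' additive for a tree, the generating topology is recovered.
#'
#' @param dist Symmetric distance matrix with labelled rows/columns, at
#'   least 3 taxa.
#' @return Unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3L) abort("Neighbor joining needs at least 3 taxa.")
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8)) ||
      any(diag(dist) != 0) || any(!is.finite(dist)) || any(dist < 0)) {
    abort("Distance matrix must be symmetric, finite, non-negative with zero diagonal.")
  }
  tree <- ape::nj(stats::as.dist(dist))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Root a tree on an outgroup's pendant edge
#'
#' Places the root at the midpoint of the edge leading to the outgroup leaf
#' (when branch lengths are present), so the root's children are the
#' outgroup and the ingroup clade.
#'
#' @param tree A `phylo` tree.
#' @param outgroup_label Leaf label to root on.
#' @return Rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_label) {
  if (!outgroup_label %in% tree$tip.label) {
    abort(sprintf("Outgroup '%s' is not a leaf of the tree.", outgroup_label))
  }
  tip <- which(tree$tip.label == outgroup_label)
  if (!is.null(tree$edge.length)) {
    pendant <- which(tree$edge[, 2] == tip)
    phytools::reroot(tree, node.number = tip,
                     position = tree$edge.length[pendant] / 2)
  } else {
    ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  }
}

#' Assign query sequences to paralogue groups
#'
#' Each query is assigned to the reference group (I or II) with the smaller
#' mean pairwise distance to its members; the margin is the absolute
#' difference of the two means. Queries whose margin falls below
#' `min_margin` stay `UNASSIGNED`.
#'
#' @param queries Named character vector (or tibble with `id`, `sequence`)
#'   of query sequences.
#' @param ref_group_I,ref_group_II Non-empty reference sequence sets for the
#'   two ancestral paralogue groups.
#' @param min_margin Minimum supporting margin (expected substitutions per
#'   site under the chosen distance mode).
#' @param mode Distance mode, see [pairwise_distance()].
#' @param ... Further arguments to [pairwise_distance()].
#' @return Tibble with `gene_id`, `group` (`GROUP_I`, `GROUP_II`,
#'   `UNASSIGNED`), `margin`, `mean_dist_I`, `mean_dist_II`.
#' @export
assign_paralog_groups <- function(queries, ref_group_I, ref_group_II,
                                  min_margin = 0.02, mode = "poisson", ...) {
  as_named <- function(x, what) {
    if (is.data.frame(x)) x <- setNames(x$sequence, x$id)
    x
  }
  queries <- as_named(queries)
  ref_group_I <- as_named(ref_group_I)
  ref_group_II <- as_named(ref_group_II)
  if (length(ref_group_I) == 0L || length(ref_group_II) == 0L) {
    abort("Both reference groups must be non-empty.")
  }
  if (length(queries) == 0L) {
    return(tibble(gene_id = character(), group = character(),
                  margin = double(), mean_dist_I = double(),
                  mean_dist_II = double()))
  }
  ids <- names(queries) %||% paste0("query_", seq_along(queries))
  purrr::map2(queries, ids, function(q, id) {
    d1 <- mean(map_dbl(ref_group_I, pairwise_distance, seq_b = q,
                       mode = mode, ...))
    d2 <- mean(map_dbl(ref_group_II, pairwise_distance, seq_b = q,
                       mode = mode, ...))
    margin <- abs(d1 - d2)
    group <- if (margin < min_margin) "UNASSIGNED"
             else if (d1 < d2) "GROUP_I" else "GROUP_II"
    tibble(gene_id = id, group = group, margin = margin,
           mean_dist_I = d1, mean_dist_II = d2)
  }) |> bind_rows()
}
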