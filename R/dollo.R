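#' Build a lineage-by-character presence/absence matrix
#'
#' Maps classified gene records onto the three isoform characters
#' (`alpha_beta`; `beta_alpha_I` and `beta_alpha_II` for the two ancestral
#' beta-alpha paralogue groups) and records, per lineage, whether at least
#' one gene realises each character. Duplicate genes within a
#' lineage/character are idempotent; a beta-alpha record with no paralogue
#' group is counted toward neither beta-alpha character (with a warning).
#'
#' @param gene_records Tibble with `lineage`, `gene_id`, `isoform`
#'   (`ALPHA_BETA`/`BETA_ALPHA`) and `paralog_group` (`GROUP_I`, `GROUP_II`
#'   or `NA`).
#' @param lineage_order Character vector fixing row order; must cover every
#'   lineage present in the records. Lineages with no records get all-false
#'   rows.
#' @return Tibble of class `presence_matrix` with columns `lineage`,
#'   `alpha_beta`, `beta_alpha_I`, `beta_alpha_II` (logical).
#' @export
build_presence_matrix <- function(gene_records,
                                  lineage_order = unique(gene_records$lineage)) {
  gene_records <- as_tibble(gene_records)
  stray <- setdiff(gene_records$lineage, lineage_order)
  if (length(stray) > 0L) {
    abort(sprintf("lineage_order does not cover: %s.",
                  paste(stray, collapse = ", ")))
  }
  bad_group <- gene_records$isoform == "ALPHA_BETA" &
    !is.na(gene_records$paralog_group)
  if (any(bad_group)) {
    abort("paralog_group must be NA for ALPHA_BETA records.")
  }
  orphan <- gene_records$isoform == "BETA_ALPHA" &
    is.na(gene_records$paralog_group)
  if (any(orphan)) {
    warn(sprintf(
      "%d BETA_ALPHA record(s) without a paralogue group counted toward neither beta-alpha character.",
      sum(orphan)))
  }
  char_of <- function(iso, grp) {
    dplyr::case_when(
      iso == "ALPHA_BETA" ~ "alpha_beta",
      iso == "BETA_ALPHA" & grp %in% "GROUP_I" ~ "beta_alpha_I",
      iso == "BETA_ALPHA" & grp %in% "GROUP_II" ~ "beta_alpha_II",
      TRUE ~ NA_character_
    )
  }
  mapped <- gene_records |>
    mutate(character = char_of(.data$isoform, .data$paralog_group)) |>
    filter(!is.na(.data$character))
  m <- tibble(lineage = lineage_order)
  for (ch in CHARACTERS) {
    m[[ch]] <- m$lineage %in% mapped$lineage[mapped$character == ch]
  }
  class(m) <- c("presence_matrix", class(m))
  m
}

check_tree_matrix <- function(tree, matrix) {
  extra_tips <- setdiff(tree$tip.label, matrix$lineage)
  extra_rows <- setdiff(matrix$lineage, tree$tip.label)
  if (length(extra_tips) > 0L || length(extra_rows) > 0L) {
    fmt <- function(x) if (length(x) == 0L) "none" else paste(x, collapse = ", ")
    abort(sprintf(
      "Tree leaves and matrix lineages differ (tree-only: %s; matrix-only: %s).",
      fmt(extra_tips), fmt(extra_rows)))
  }
}

# Tip labels below each edge child; nodes indexed as in ape.
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; ch <- post$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Minimal Dollo loss scenario for one character
#'
#' Under Dollo parsimony the character is gained once, at or above the root,
#' and can only be lost. The minimal explanation of an absence pattern on a
#' rooted tree places one loss on the edge above each maximal all-absent
#' subtree. Polytomies are allowed (each all-absent child of a
#' not-all-absent node counts one loss).
#'
#' A character absent from every tip carries no evidence of ancestral
#' presence: by default `root_present` is `FALSE` and 0 losses are reported
#' with flag `NEVER_OBSERVED`. Set `assume_ancestral_presence = TRUE` to
#' assert presence at the root instead, which yields a single loss on the
#' (virtual) root edge.
#'
#' @param tree Rooted `phylo` tree whose leaves are lineages.
#' @param matrix A `presence_matrix`, see [build_presence_matrix()].
#' @param character Character column to analyse.
#' @param assume_ancestral_presence Treat an all-absent character as
#'   ancestrally present.
#' @return List of class `dollo_scenario`: `character`, `root_present`,
#'   `n_losses`, `loss_edges` (tibble: `parent`, `node`, list-column `tips`
#'   of the lost clade), `flags`.
#' @export
dollo_losses <- function(tree, matrix, character,
                         assume_ancestral_presence = FALSE) {
  check_tree_matrix(tree, matrix)
  if (!character %in% names(matrix)) {
    abort(sprintf("Character '%s' is not a matrix column.", character))
  }
  present <- setNames(matrix[[character]], matrix$lineage)[tree$tip.label]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L

  empty_edges <- tibble(parent = integer(), node = integer(), tips = list())
  if (!any(present)) {
    if (assume_ancestral_presence) {
      scen <- list(character = character, root_present = TRUE,
                   n_losses = 1L,
                   loss_edges = tibble(parent = NA_integer_, node = root,
                                       tips = list(tree$tip.label)),
                   flags = "ROOT_EDGE_LOSS")
    } else {
      scen <- list(character = character, root_present = FALSE,
                   n_losses = 0L, loss_edges = empty_edges,
                   flags = "NEVER_OBSERVED")
    }
    class(scen) <- "dollo_scenario"
    return(scen)
  }

  # postorder visits every edge below a node before that node's own edge,
  # so all_absent[child] is final when edge (parent, child) is processed
  post <- ape::reorder.phylo(tree, "postorder")
  all_absent <- c(!present, rep(TRUE, tree$Nnode))
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1]; ch <- post$edge[k, 2]
    if (!all_absent[ch]) all_absent[p] <- FALSE
  }

  tips_below <- node_tip_sets(tree)
  is_loss <- all_absent[tree$edge[, 2]] & !all_absent[tree$edge[, 1]]
  loss_edges <- tibble(
    parent = tree$edge[is_loss, 1],
    node = tree$edge[is_loss, 2],
    tips = tips_below[tree$edge[is_loss, 2]]
  )
  scen <- list(character = character, root_present = TRUE,
               n_losses = nrow(loss_edges), loss_edges = loss_edges,
               flags = character())
  class(scen) <- "dollo_scenario"
  scen
}

#' @export
print.dollo_scenario <- function(x, ...) {
  cat("<dollo_scenario>", x$character, "\n")
  cat("  root present:", x$root_present, " losses:", x$n_losses, "\n")
  if (nrow(x$loss_edges) > 0L) {
    lost <- map_chr(x$loss_edges$tips, paste, collapse = "+")
    cat("  lost clades:", paste(lost, collapse = "; "), "\n")
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Brute-force minimal Dollo loss count (test oracle)
#'
#' Exhaustively searches subsets of tree edges (plus a virtual root edge,
#' so an all-absent pattern costs one loss) for the smallest set whose
#' subtree union makes exactly the observed tips absent under a single gain
#' at the root. Only feasible on small trees.
#'
#' @param tree Rooted `phylo` tree (at most 12 edges).
#' @param present_tips Character vector of tips carrying the character.
#' @return Minimal loss count (integer).
#' @export
brute_force_losses <- function(tree, present_tips) {
  n_edge <- nrow(tree$edge)
  if (n_edge > 12L) abort("brute_force_losses() is limited to trees with <= 12 edges.")
  tips <- tree$tip.label
  sets <- node_tip_sets(tree)
  mask_of <- function(tip_names) {
    sum(bitwShiftL(1L, match(tip_names, tips) - 1L))
  }
  target <- mask_of(setdiff(tips, present_tips))
  edge_masks <- c(map_dbl(tree$edge[, 2], function(nd) mask_of(sets[[nd]])),
                  mask_of(tips))  # virtual root edge last
  for (k in 0:length(edge_masks)) {
    if (k == 0L) {
      if (target == 0) return(0L)
      next
    }
    subsets <- combn(length(edge_masks), k)
    for (j in seq_len(ncol(subsets))) {
      covered <- 0
      for (e in subsets[, j]) covered <- bitwOr(covered, edge_masks[e])
      if (covered == target) return(k)
    }
  }
  abort("No loss-edge subset explains the pattern (should not happen).")
}

#' Count characters present at the root
#'
#' Applies [dollo_losses()] to each character in the subset and counts how
#' many are reconstructed as present in the most recent common ancestor.
#'
#' @inheritParams dollo_losses
#' @param character_subset Character columns to assess.
#' @return Integer count.
#' @export
root_paralog_count <- function(tree, matrix,
                               character_subset = CHARACTERS) {
  sum(map_int(character_subset, function(ch) {
    as.integer(dollo_losses(tree, matrix, ch)$root_present)
  }))
}

#' Rank candidate topologies by implied gene-loss counts
#'
#' Runs [dollo_losses()] for every character on every candidate topology
#' and ranks topologies by total implied losses (ascending; ties broken by
#' topology name). A topology requiring fewer independent losses offers the
#' more parsimonious account of the observed isoform distribution.
#'
#' @param matrix A `presence_matrix`.
#' @param topologies Named list of rooted `phylo` trees sharing the
#'   matrix's lineage set.
#' @param characters Character columns to score.
#' @return Tibble of class `topology_ranking`: `topology`, one loss-count
#'   column per character, `total_losses`, sorted ascending.
#' @export
compare_topologies <- function(matrix, topologies,
                               characters = intersect(CHARACTERS, names(matrix))) {
  if (is.null(names(topologies)) || any(names(topologies) == "")) {
    abort("`topologies` must be a fully named list of trees.")
  }
  rows <- imap(topologies, function(tree, name) {
    losses <- map_int(characters, function(ch) {
      dollo_losses(tree, matrix, ch)$n_losses
    })
    out <- tibble(topology = name)
    for (i in seq_along(characters)) out[[characters[i]]] <- losses[i]
    out$total_losses <- sum(losses)
    out
  })
  ranked <- bind_rows(rows) |>
    arrange(.data$total_losses, .data$topology)
  class(ranked) <- c("topology_ranking", class(ranked))
  ranked
}
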