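# Shared fixtures built in code.

quartet_tree <- function() ape::read.tree(text = "((A,B),(C,D));")

eight_leaf_tree <- function() {
  ape::read.tree(text = "(((A,B),(C,D)),((E,F),(G,H)));")
}

# presence_matrix over arbitrary tips with one character of interest
toy_matrix <- function(tips, present_tips) {
  m <- tibble::tibble(
    lineage = tips,
    alpha_beta = tips %in% present_tips,
    beta_alpha_I = FALSE,
    beta_alpha_II = FALSE
  )
  class(m) <- c("presence_matrix", class(m))
  m
}

# architecture with a given number of helices strictly between the domains,
# in alpha-beta orientation (domain I first)
arch_with_between <- function(n_between, order_ab = TRUE) {
  helix_span <- 40L
  d_len <- 100L
  helices <- tibble::tibble(
    start = d_len + 20L + (seq_len(n_between) - 1L) * helix_span,
    end = d_len + 20L + (seq_len(n_between) - 1L) * helix_span + 21L
  )
  if (n_between == 0L) helices <- helices[0, ]
  tail_start <- d_len + 40L + n_between * helix_span
  hits <- tibble::tibble(
    kind = if (order_ab) c("DOMAIN_I", "DOMAIN_III") else c("DOMAIN_III", "DOMAIN_I"),
    start = c(0L, tail_start),
    end = c(d_len, tail_start + d_len),
    score = c(96, 96)
  )
  stretches <- nthscan::group_stretches(helices, split_points = hits,
                                        max_gap = 10000)
  nthscan::assemble_architecture(hits, stretches, max_gap = 10000)
}
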