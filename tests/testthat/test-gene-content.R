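test_that("the presence matrix maps records to characters and is idempotent", {
  m <- build_presence_matrix(lineage_complements(), apicomplexan_lineages())
  expect_equal(m$lineage, apicomplexan_lineages())
  chrom <- m[m$lineage == "Chromerida", -1]
  expect_true(all(unlist(chrom)))
  piro <- m[m$lineage == "Piroplasmida", -1]
  expect_false(any(unlist(piro)))
  expect_equal(as.data.frame(m), as.data.frame(lineage_presence_matrix()))

  single <- build_presence_matrix(
    tibble::tibble(lineage = "L1", gene_id = "g1", isoform = "ALPHA_BETA",
                   paralog_group = NA_character_),
    lineage_order = c("L1", "L2"))
  expect_true(single$alpha_beta[1])
  expect_false(any(single$beta_alpha_I, single$beta_alpha_II,
                   unlist(single[2, -1])))

  dup <- build_presence_matrix(
    tibble::tibble(lineage = c("L1", "L1"), gene_id = c("g1", "g2"),
                   isoform = "BETA_ALPHA", paralog_group = "GROUP_I"),
    lineage_order = "L1")
  expect_equal(as.data.frame(dup), as.data.frame(build_presence_matrix(
    tibble::tibble(lineage = "L1", gene_id = "g1", isoform = "BETA_ALPHA",
                   paralog_group = "GROUP_I"), lineage_order = "L1")))
})

test_that("a beta-alpha record with no group counts toward neither character", {
  expect_warning(
    m <- build_presence_matrix(
      tibble::tibble(lineage = "L1", gene_id = "g1", isoform = "BETA_ALPHA",
                     paralog_group = NA_character_),
      lineage_order = "L1"),
    "neither")
  expect_false(any(m$beta_alpha_I, m$beta_alpha_II))
})

test_that("Dollo losses are counted on maximal absent subtrees", {
  tr <- quartet_tree()
  all_present <- toy_matrix(tr$tip.label, tr$tip.label)
  expect_equal(dollo_losses(tr, all_present, "alpha_beta")$n_losses, 0L)

  half <- toy_matrix(tr$tip.label, c("A", "B"))
  scen <- dollo_losses(tr, half, "alpha_beta")
  expect_equal(scen$n_losses, 1L)
  expect_setequal(scen$loss_edges$tips[[1]], c("C", "D"))
  expect_equal(scen$n_losses, brute_force_losses(tr, c("A", "B")))

  expect_error(dollo_losses(tr, toy_matrix(c("A", "B", "C", "E"),
                                           "A"), "alpha_beta"),
               "differ")
})

test_that("an all-absent character is not inferred present without assertion", {
  tr <- quartet_tree()
  none <- toy_matrix(tr$tip.label, character(0))
  scen <- dollo_losses(tr, none, "alpha_beta")
  expect_false(scen$root_present)
  expect_equal(scen$n_losses, 0L)
  expect_true("NEVER_OBSERVED" %in% scen$flags)
  asserted <- dollo_losses(tr, none, "alpha_beta",
                           assume_ancestral_presence = TRUE)
  expect_equal(asserted$n_losses, 1L)
  expect_equal(brute_force_losses(tr, character(0)), 1L)
})

test_that("dollo_losses matches the brute-force oracle across random small trees", {
  set.seed(101)
  n_cases <- 0
  for (i in 1:150) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- NULL
    pattern <- sample(c(TRUE, FALSE), n, replace = TRUE)
    m <- toy_matrix(tr$tip.label, tr$tip.label[pattern])
    d <- dollo_losses(tr, m, "alpha_beta", assume_ancestral_presence = TRUE)
    expect_equal(d$n_losses,
                 brute_force_losses(tr, tr$tip.label[pattern]),
                 info = paste("case", i))
    n_cases <- n_cases + 1
  }
  expect_equal(n_cases, 150)
})

test_that("a present tip appearing inside an all-absent clade never reduces the loss count", {
  set.seed(33)
  for (i in 1:30) {
    tr <- ape::rtree(6); tr$edge.length <- NULL
    pattern <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    present <- tr$tip.label[pattern]
    if (length(present) == 0 || all(pattern)) next
    base <- dollo_losses(tr, toy_matrix(tr$tip.label, present),
                         "alpha_beta", assume_ancestral_presence = TRUE)
    # revive one member of a lost clade of two or more tips: the remaining
    # absent members still need at least one loss of their own
    big_clades <- base$loss_edges$tips[lengths(base$loss_edges$tips) >= 2]
    if (length(big_clades) == 0) next
    revived <- c(present, big_clades[[1]][1])
    more <- dollo_losses(tr, toy_matrix(tr$tip.label, revived),
                         "alpha_beta", assume_ancestral_presence = TRUE)
    expect_gte(more$n_losses, base$n_losses)
  }
})

test_that("the packaged matrix implies one alpha-beta loss on the Mathur-style tree", {
  m <- lineage_presence_matrix()
  tops <- candidate_topologies()
  scen <- dollo_losses(tops$mathur, m, "alpha_beta")
  expect_true(scen$root_present)
  expect_equal(scen$n_losses, 1L)
  # the lost clade is everything after the Gregarinia/Marosporida divergence
  expect_setequal(scen$loss_edges$tips[[1]],
                  c("Nephromycida", "Cryptosporidia", "Sarcocystidae",
                    "Eimeriidae", "Haemosporida", "Piroplasmida"))
})

test_that("both beta-alpha paralogues are reconstructed at the common ancestor", {
  m <- lineage_presence_matrix()
  for (tree in candidate_topologies()) {
    expect_equal(root_paralog_count(tree, m,
                                    c("beta_alpha_I", "beta_alpha_II")), 2L)
  }
  tr <- quartet_tree()
  expect_equal(root_paralog_count(tr, toy_matrix(tr$tip.label, character(0)),
                                  "alpha_beta"), 0L)
  expect_equal(root_paralog_count(tr, toy_matrix(tr$tip.label, "A"),
                                  "alpha_beta"), 1L)
})

test_that("topology comparison ranks by total losses with name tie-breaks", {
  m <- lineage_presence_matrix()
  tops <- candidate_topologies()
  rk <- compare_topologies(m, tops)
  expect_equal(rk$topology[1], "mathur")
  expect_lt(rk$alpha_beta[1], min(rk$alpha_beta[-1]))
  expect_equal(rk$total_losses,
               rk$alpha_beta + rk$beta_alpha_I + rk$beta_alpha_II)
  # identical topologies under different names give identical rows
  twin <- compare_topologies(m, list(b_copy = tops$mathur,
                                     a_copy = tops$mathur))
  expect_equal(twin$total_losses[1], twin$total_losses[2])
  expect_equal(twin$topology, c("a_copy", "b_copy"))
})

test_that("simulated complements recover true loss structure", {
  tree8 <- eight_leaf_tree()
  n_inf <- c(); n_true <- c()
  for (rep in 1:120) {
    sim <- simulate_complement_evolution(tree8, loss_prob = 0.1, seed = rep)
    m <- build_presence_matrix(sim$gene_records, tree8$tip.label)
    for (ch in c("alpha_beta", "beta_alpha_I", "beta_alpha_II")) {
      scen <- dollo_losses(tree8, m, ch, assume_ancestral_presence = TRUE)
      true_edges <- sim$truth[sim$truth$character == ch, ]
      n_inf <- c(n_inf, scen$n_losses)
      n_true <- c(n_true, nrow(true_edges))
      # inference can only merge sibling losses, never overcount
      expect_lte(scen$n_losses, nrow(true_edges))
      # every inferred lost clade is a union of true lost clades
      lost_tips <- unlist(true_edges$tips)
      expect_equal(sort(as.character(unlist(scen$loss_edges$tips))),
                   sort(unique(as.character(lost_tips))))
    }
  }
  expect_lt(abs(mean(n_inf) - mean(n_true)), 0.1)
})
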