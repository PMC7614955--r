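test_that("architecture assembly orders elements and enforces single domains", {
  hits <- tibble::tibble(kind = c("DOMAIN_I", "DOMAIN_III"),
                         start = c(0L, 720L), end = c(180L, 900L),
                         score = c(90, 90))
  helices <- tibble::tibble(start = 200L + (0:13) * 36L,
                            end = 221L + (0:13) * 36L)
  stretches <- group_stretches(helices, split_points = hits, max_gap = 80)
  arch <- assemble_architecture(hits, stretches)
  expect_equal(arch$element, c("DOMAIN_I", "TM_STRETCH", "DOMAIN_III"))
  expect_equal(arch$n_helices[2], 14L)

  dup <- dplyr::bind_rows(hits, hits[1, ])
  expect_error(assemble_architecture(dup, stretches), "Two DOMAIN_I")

  lone <- assemble_architecture(hits[0, ], stretches)
  expect_equal(lone$element, "TM_STRETCH")
})

test_that("a stretch overlapping a domain is truncated at the domain boundary", {
  hits <- tibble::tibble(kind = "DOMAIN_I", start = 100L, end = 200L,
                         score = 90)
  helices <- tibble::tibble(start = c(60L, 120L, 220L),
                            end = c(81L, 141L, 241L))
  stretches <- group_stretches(helices, max_gap = 500)
  arch <- assemble_architecture(hits, stretches, max_gap = 500)
  hx <- dplyr::bind_rows(arch$helices[arch$element == "TM_STRETCH"])
  # the helix inside the domain is gone; the others untouched
  expect_equal(nrow(hx), 2L)
  expect_true(all(hx$end <= 100 | hx$start >= 200))
})

test_that("parity validity depends only on the helix count between the domains", {
  even <- arch_with_between(14)
  expect_equal(parity_check(even), list(status = "VALID", n_between = 14L))
  odd <- arch_with_between(13)
  expect_equal(parity_check(odd)$status, "PARITY_VIOLATION")
  adjacent <- arch_with_between(0, order_ab = FALSE)
  expect_equal(parity_check(adjacent), list(status = "VALID", n_between = 0L))
  no_d3 <- even[even$element != "DOMAIN_III", ]
  expect_error(parity_check(no_d3), "exactly one")
})

test_that("parity is invariant under stretch regrouping", {
  arch_wide <- arch_with_between(6)
  # regroup the same helices into many stretches by shrinking max_gap
  hx <- dplyr::bind_rows(arch_wide$helices[arch_wide$element == "TM_STRETCH"])
  hits <- tibble::tibble(
    kind = arch_wide$element[arch_wide$element != "TM_STRETCH"],
    start = arch_wide$start[arch_wide$element != "TM_STRETCH"],
    end = arch_wide$end[arch_wide$element != "TM_STRETCH"],
    score = 90)
  fine <- assemble_architecture(hits, group_stretches(hx, max_gap = 5),
                                max_gap = 5)
  expect_gt(sum(fine$element == "TM_STRETCH"), 1L)
  expect_equal(parity_check(fine)$n_between,
               parity_check(arch_wide)$n_between)
})

test_that("configuration label is decided by domain order alone", {
  x_ab <- make_isoform_sequence("ALPHA_BETA", seed = 31)
  call_ab <- nthscan:::classify_one_sequence(x_ab$record$sequence, nth_params())
  expect_equal(call_ab$label, "ALPHA_BETA")
  expect_length(call_ab$flags, 0)
  expect_equal(call_ab$stretch_sizes, 14L)

  x_ba <- make_isoform_sequence("BETA_ALPHA", seed = 31)
  call_ba <- nthscan:::classify_one_sequence(x_ba$record$sequence, nth_params())
  expect_equal(call_ba$label, "BETA_ALPHA")
  expect_length(call_ba$flags, 0)
  expect_equal(call_ba$stretch_sizes, c(9L, 4L))
})

test_that("missing domains yield AMBIGUOUS with the matching flag", {
  arch <- arch_with_between(4)
  d1_only <- arch[arch$element != "DOMAIN_III", ]
  call <- classify_isoform(d1_only)
  expect_equal(call$label, "AMBIGUOUS")
  expect_true("MISSING_DOMAIN_III" %in% call$flags)
  expect_false("MISSING_DOMAIN_I" %in% call$flags)
})

test_that("odd between-domain helix counts are INVALID with PARITY_VIOLATION", {
  call <- classify_isoform(arch_with_between(13))
  expect_equal(call$label, "INVALID")
  expect_true("PARITY_VIOLATION" %in% call$flags)
})

test_that("template departures are flagged without demoting the call", {
  # 10 helices between the domains in alpha-beta orientation: even (valid),
  # but 4 short of the 14-helix template at tolerance 2
  call <- classify_isoform(arch_with_between(10))
  expect_equal(call$label, "ALPHA_BETA")
  expect_true("TM_COUNT_DEVIATION" %in% call$flags)
  expect_equal(call$template_deviation, -4L)
})

test_that("mirrored architectures swap the configuration labels", {
  mirror_arch <- function(arch) {
    L <- max(arch$end) + 50L
    out <- arch |>
      dplyr::mutate(
        new_start = L - end, new_end = L - start,
        helices = lapply(helices, function(h) {
          if (is.null(h)) return(NULL)
          tibble::tibble(start = L - rev(h$end), end = L - rev(h$start))
        })
      ) |>
      dplyr::mutate(start = new_start, end = new_end) |>
      dplyr::select(-new_start, -new_end) |>
      dplyr::arrange(start)
    class(out) <- c("nth_architecture", class(out))
    out
  }
  for (n_between in c(2, 14)) {
    arch <- arch_with_between(n_between)
    expect_equal(classify_isoform(arch)$label, "ALPHA_BETA")
    expect_equal(classify_isoform(mirror_arch(arch))$label, "BETA_ALPHA")
  }
})

test_that("shuffling loop residues outside planted elements keeps the label", {
  x <- make_isoform_sequence("BETA_ALPHA", seed = 51)
  s <- strsplit(x$record$sequence, "")[[1]]
  planted <- rep(FALSE, length(s))
  for (i in seq_len(nrow(x$truth))) {
    planted[(x$truth$start[i] + 1):x$truth$end[i]] <- TRUE
  }
  set.seed(51)
  loop_idx <- which(!planted)
  s[loop_idx] <- s[sample(loop_idx)]
  call <- nthscan:::classify_one_sequence(paste(s, collapse = ""),
                                          nth_params())
  expect_equal(call$label, "BETA_ALPHA")
})

test_that("batch classification preserves order, aggregates lineages and survives errors", {
  recs <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_isoform_sequence("ALPHA_BETA", seed = 60 + i,
                          id = paste0("ab_", i), lineage = "LineageA")$record
  }), lapply(1:10, function(i) {
    make_isoform_sequence("BETA_ALPHA", seed = 80 + i,
                          id = paste0("ba_", i), lineage = "LineageB")$record
  }))
  res <- classify_batch(recs)
  expect_equal(res$calls$protein_id, recs$id)
  expect_equal(sum(res$calls$label == "ALPHA_BETA"), 10L)
  expect_equal(sum(res$calls$label == "BETA_ALPHA"), 10L)
  # summary is a recount of the per-record rows
  recount <- dplyr::count(res$calls, lineage, label, name = "n_proteins")
  expect_equal(as.data.frame(res$summary), as.data.frame(recount))
  g <- glance(res)
  expect_equal(g$n_alpha_beta, 10L)
  expect_equal(g$n_proteins, 20L)

  # an unparseable record becomes an ERROR row, others still classified
  recs_bad <- dplyr::bind_rows(
    tibble::tibble(id = "bad", genus = NA, lineage = "LineageA",
                   sequence = "QQ-ZZ"),
    recs[1, ])
  res_bad <- classify_batch(recs_bad)
  expect_equal(res_bad$calls$label, c("ERROR", "ALPHA_BETA"))

  empty <- classify_batch(recs[0, ])
  expect_equal(nrow(empty$calls), 0L)
})
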