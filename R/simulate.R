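HELIX_RESIDUES <- c("L", "I", "V", "F")
LOOP_RESIDUES <- c("E", "D", "K", "R", "S", "T", "N", "Q", "G", "P")

random_block <- function(n, pool) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

mutate_sequence <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(orig) {
      sample(setdiff(AA20, orig), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic NTH-like protein with planted architecture
#'
#' Realises an isoform template in sequence: hydrophilic loops drawn from
#' charged/polar residues, planted domain consensus segments from the motif
#' library, and hydrophobic helix blocks drawn from leucine/isoleucine/
#' valine/phenylalanine, concatenated in template order. The alpha-beta
#' layout is domain I, one stretch of helices, domain III; the beta-alpha
#' layout is an N-terminal stretch, domain III, domain I, C-terminal
#' stretch. Point mutations are then applied residue-wise at `mutation_rate`.
#' All randomness flows from `seed`, so output is bit-reproducible.
#'
#' The residue pools keep the hydropathy of helices and loops far from the
#' scan threshold, so classification tests probe pipeline logic rather than
#' scanner calibration.
#'
#' @param isoform `"ALPHA_BETA"` or `"BETA_ALPHA"`.
#' @param helix_counts Helices per stretch; defaults to the template of the
#'   chosen isoform (14, or 9 and 4).
#' @param helix_len,loop_len Helix block and loop lengths (residues).
#' @param spacer_len Loop length between consecutive stretches not separated
#'   by a domain (long enough to force a stretch split by `max_gap`).
#' @param mutation_rate Per-residue substitution probability in `[0, 1)`.
#' @param library Motif library supplying the domain consensus segments.
#' @param id,genus,lineage Metadata for the generated record.
#' @param seed Integer seed.
#' @return List with `record` (tibble row: `id`, `genus`, `lineage`,
#'   `sequence`) and `truth` (tibble of planted elements: `element`,
#'   `start`, `end`, 0-based half-open; `TM_HELIX` rows carry `stretch`).
#' @export
make_isoform_sequence <- function(isoform = c("ALPHA_BETA", "BETA_ALPHA"),
                                  helix_counts = NULL,
                                  helix_len = 21, loop_len = 25,
                                  spacer_len = 120, mutation_rate = 0,
                                  library = nth_motif_library(),
                                  id = "synthetic_1", genus = "Synthetica",
                                  lineage = "Synthetic", seed = 1L) {
  isoform <- match.arg(isoform)
  stopifnot(mutation_rate >= 0, mutation_rate < 1, helix_len >= 1,
            loop_len >= 1)
  helix_counts <- helix_counts %||% isoform_templates()[[isoform]]
  stopifnot(all(helix_counts >= 1))

  set.seed(seed)
  d1 <- library$DOMAIN_I$consensus
  d3 <- library$DOMAIN_III$consensus

  parts <- list()       # list of (kind, text, stretch)
  emit <- function(kind, text, stretch = NA_integer_) {
    parts[[length(parts) + 1L]] <<- list(kind = kind, text = text,
                                         stretch = stretch)
  }
  emit_stretch <- function(idx, n_helices) {
    for (h in seq_len(n_helices)) {
      if (h > 1L) emit("LOOP", random_block(loop_len, LOOP_RESIDUES))
      emit("TM_HELIX", random_block(helix_len, HELIX_RESIDUES), idx)
    }
  }
  loop <- function() emit("LOOP", random_block(loop_len, LOOP_RESIDUES))

  if (isoform == "ALPHA_BETA") {
    loop(); emit("DOMAIN_I", d1); loop()
    for (s in seq_along(helix_counts)) {
      if (s > 1L) emit("LOOP", random_block(spacer_len, LOOP_RESIDUES))
      emit_stretch(s, helix_counts[s])
    }
    loop(); emit("DOMAIN_III", d3); loop()
  } else {
    n_str <- length(helix_counts)
    loop(); emit_stretch(1L, helix_counts[1])
    loop(); emit("DOMAIN_III", d3); loop(); emit("DOMAIN_I", d1); loop()
    if (n_str > 1L) {
      for (s in seq.int(2L, n_str)) {
        if (s > 2L) emit("LOOP", random_block(spacer_len, LOOP_RESIDUES))
        emit_stretch(s, helix_counts[s])
      }
      loop()
    }
  }

  lens <- map_int(parts, function(p) nchar(p$text))
  ends <- cumsum(lens)
  starts <- ends - lens
  truth <- tibble(
    element = map_chr(parts, "kind"),
    start = as.integer(starts),
    end = as.integer(ends),
    stretch = map_int(parts, function(p) p$stretch %||% NA_integer_)
  ) |> filter(.data$element != "LOOP")

  sequence <- mutate_sequence(paste(map_chr(parts, "text"), collapse = ""),
                              mutation_rate)
  list(
    record = tibble(id = id, genus = genus, lineage = lineage,
                    sequence = sequence),
    truth = truth
  )
}

#' Simulate gene-complement evolution under Dollo loss
#'
#' Every character starts present at the root and is lost, independently per
#' character, on each edge with probability `loss_prob` while still present;
#' once lost it stays lost. Tips report their surviving characters as gene
#' records; the returned truth lists the edges on which each loss event
#' occurred.
#'
#' @param tree Rooted `phylo` tree whose leaves are lineages.
#' @param characters Characters present at the root.
#' @param loss_prob Per-edge, per-character loss probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `gene_records` (tibble: `lineage`, `gene_id`,
#'   `isoform`, `paralog_group`) and `truth` (tibble: `character`, `parent`,
#'   `node`, list-column `tips` of the clade lost by each event).
#' @export
simulate_complement_evolution <- function(tree,
                                          characters = CHARACTERS,
                                          loss_prob = 0.1, seed = 1L) {
  stopifnot(loss_prob >= 0, loss_prob <= 1,
            all(characters %in% CHARACTERS))
  set.seed(seed)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  # preorder: parents before children
  pre <- ape::reorder.phylo(tree, "cladewise")
  sets <- node_tip_sets(tree)

  records <- list(); truth <- list()
  for (ch in characters) {
    state <- rep(NA, n_tip + tree$Nnode)
    state[root] <- TRUE
    for (k in seq_len(nrow(pre$edge))) {
      p <- pre$edge[k, 1]; nd <- pre$edge[k, 2]
      lost_here <- state[p] && runif(1) < loss_prob
      state[nd] <- state[p] && !lost_here
      if (lost_here) {
        truth[[length(truth) + 1L]] <- tibble(
          character = ch, parent = p, node = nd, tips = list(sets[[nd]]))
      }
    }
    surviving <- tree$tip.label[state[seq_len(n_tip)]]
    if (length(surviving) > 0L) {
      iso <- if (ch == "alpha_beta") "ALPHA_BETA" else "BETA_ALPHA"
      grp <- switch(ch, alpha_beta = NA_character_,
                    beta_alpha_I = "GROUP_I", beta_alpha_II = "GROUP_II")
      records[[length(records) + 1L]] <- tibble(
        lineage = surviving,
        gene_id = paste0(tolower(substr(surviving, 1, 4)), "_", ch),
        isoform = iso, paralog_group = grp)
    }
  }
  list(
    gene_records = if (length(records)) bind_rows(records) else
      tibble(lineage = character(), gene_id = character(),
             isoform = character(), paralog_group = character()),
    truth = if (length(truth)) bind_rows(truth) else
      tibble(character = character(), parent = integer(), node = integer(),
             tips = list())
  )
}

#' Simulate diverged paralogue reference families
#'
#' Builds two reference families descending from a single ancestral
#' sequence: the ancestor is mutated at `divergence` to found group I and
#' group II lineages, each of which then speciates into `n_per_group`
#' sequences at `within_noise`. Used for paralogue-assignment recovery
#' tests and to produce packaged synthetic reference sets.
#'
#' @param n_per_group Sequences per group.
#' @param seq_len Ancestral sequence length.
#' @param divergence Per-residue substitution probability separating the two
#'   ancestral paralogues.
#' @param within_noise Per-residue substitution probability within a group.
#' @param seed Integer seed.
#' @return List with tibbles `group_I` and `group_II` (`id`, `sequence`).
#' @export
make_reference_families <- function(n_per_group = 4, seq_len = 200,
                                    divergence = 0.3, within_noise = 0.1,
                                    seed = 1L) {
  set.seed(seed)
  ancestor <- random_block(seq_len, AA20)
  anc <- list(GROUP_I = mutate_sequence(ancestor, divergence / 2),
              GROUP_II = mutate_sequence(ancestor, divergence / 2))
  out <- lapply(names(anc), function(g) {
    tibble(
      id = sprintf("%s_ref_%d", tolower(g), seq_len(n_per_group)),
      sequence = vapply(seq_len(n_per_group), function(i)
        mutate_sequence(anc[[g]], within_noise), character(1))
    )
  })
  names(out) <- c("group_I", "group_II")
  out
}
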