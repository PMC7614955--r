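#' Assemble a per-protein domain/TM architecture
#'
#' Merges soluble domain hits and transmembrane stretches into one ordered
#' element list. Where a TM stretch overlaps a domain hit, the stretch is
#' truncated at the domain boundary: member helices are clipped to the
#' sequence outside the domain, empty helices are dropped, and helices are
#' regrouped (a domain sitting inside a former gap splits the stretch).
#'
#' @param domain_hits Tibble from [find_domains()] (at most one hit per
#'   kind).
#' @param tm_stretches Tibble from [group_stretches()].
#' @param max_gap Maximum within-stretch inter-helix gap used when
#'   regrouping.
#' @return Tibble of class `nth_architecture` with columns `element`
#'   (`DOMAIN_I`, `DOMAIN_III` or `TM_STRETCH`), `start`, `end`,
#'   `n_helices` (`NA` for domains) and list-column `helices`.
#' @export
assemble_architecture <- function(domain_hits, tm_stretches, max_gap = 80) {
  for (k in c("DOMAIN_I", "DOMAIN_III")) {
    if (sum(domain_hits$kind == k) > 1L) {
      abort(sprintf(
        "Two %s hits supplied; restrict selection upstream (max_hits_per_kind).", k))
    }
  }
  helices <- if (nrow(tm_stretches) == 0L) {
    tibble(start = integer(), end = integer())
  } else {
    bind_rows(tm_stretches$helices) |> select("start", "end")
  }

  # clip helices against each domain interval
  if (nrow(domain_hits) > 0L && nrow(helices) > 0L) {
    pieces <- list()
    for (i in seq_len(nrow(helices))) {
      segs <- tibble(start = helices$start[i], end = helices$end[i])
      for (j in seq_len(nrow(domain_hits))) {
        ds <- domain_hits$start[j]; de <- domain_hits$end[j]
        segs <- bind_rows(lapply(seq_len(nrow(segs)), function(k) {
          s <- segs$start[k]; e <- segs$end[k]
          if (e <= ds || s >= de) return(tibble(start = s, end = e))
          out <- tibble(start = integer(), end = integer())
          if (s < ds) out <- bind_rows(out, tibble(start = s, end = ds))
          if (e > de) out <- bind_rows(out, tibble(start = de, end = e))
          out
        }))
      }
      pieces[[i]] <- segs
    }
    helices <- bind_rows(pieces) |>
      filter(.data$end > .data$start) |>
      arrange(.data$start)
  }

  stretches <- group_stretches(helices, split_points = domain_hits,
                               max_gap = max_gap)
  elements <- bind_rows(
    if (nrow(domain_hits) > 0L)
      tibble(element = domain_hits$kind, start = domain_hits$start,
             end = domain_hits$end, n_helices = NA_integer_,
             helices = rep(list(NULL), nrow(domain_hits))),
    if (nrow(stretches) > 0L)
      tibble(element = "TM_STRETCH", start = stretches$start,
             end = stretches$end, n_helices = stretches$n_helices,
             helices = stretches$helices)
  )
  if (is.null(elements)) {
    elements <- tibble(element = character(), start = integer(),
                       end = integer(), n_helices = integer(),
                       helices = list())
  }
  elements <- arrange(elements, .data$start)
  class(elements) <- c("nth_architecture", class(elements))
  elements
}

architecture_helices <- function(architecture) {
  rows <- architecture$helices[architecture$element == "TM_STRETCH"]
  if (length(rows) == 0L) return(tibble(start = integer(), end = integer()))
  bind_rows(rows) |> arrange(.data$start)
}

#' Membrane-sidedness parity check
#'
#' A proton-translocating transhydrogenase needs its NAD(H)- and
#' NADP(H)-binding domains on the same side of the membrane, so the number
#' of transmembrane helices strictly between the two domains must be even.
#' Works for either domain order.
#'
#' @param architecture An `nth_architecture` tibble containing both domains.
#' @return List with `status` (`"VALID"` or `"PARITY_VIOLATION"`) and
#'   `n_between`, the helix count strictly between the two domains.
#' @export
parity_check <- function(architecture) {
  d1 <- architecture |> filter(.data$element == "DOMAIN_I")
  d3 <- architecture |> filter(.data$element == "DOMAIN_III")
  if (nrow(d1) != 1L || nrow(d3) != 1L) {
    abort("parity_check() needs exactly one DOMAIN_I and one DOMAIN_III element.")
  }
  lo <- min(d1$end, d3$end)
  hi <- max(d1$start, d3$start)
  hx <- architecture_helices(architecture)
  n_between <- sum(hx$start >= lo & hx$end <= hi)
  list(status = if (n_between %% 2L == 0L) "VALID" else "PARITY_VIOLATION",
       n_between = as.integer(n_between))
}

#' Isoform architecture templates
#'
#' The two single-chain eukaryotic NTH configurations: the alpha-beta
#' isoform carries domain I, a single stretch of 14 TM helices, then domain
#' III; the beta-alpha isoform carries an N-terminal stretch of 9 helices,
#' domain III, domain I, and a C-terminal stretch of 4 helices.
#'
#' @return Named list of per-label expected stretch helix counts, in element
#'   order.
#' @export
isoform_templates <- function() {
  list(ALPHA_BETA = c(14L), BETA_ALPHA = c(9L, 4L))
}

#' Classify one architecture into an isoform call
#'
#' The configuration label is decided by domain order alone: `ALPHA_BETA`
#' when domain I starts before domain III, `BETA_ALPHA` when reversed.
#' A missing domain yields `AMBIGUOUS`; a failed parity check yields
#' `INVALID`. Departures of the observed stretch structure from the
#' template of the matching label beyond `tolerance` helices are reported as
#' quality flags (`TM_COUNT_DEVIATION`, `STRETCH_COUNT_DEVIATION`) without
#' demoting the call.
#'
#' @param architecture An `nth_architecture` tibble.
#' @param templates Per-label expected stretch sizes, see
#'   [isoform_templates()].
#' @param tolerance Allowed per-stretch helix-count deviation.
#' @return List of class `isoform_call`: `label`, `flags`, `stretch_sizes`,
#'   `template_deviation` (signed observed minus expected per compared
#'   stretch), `n_helices_between`.
#' @export
classify_isoform <- function(architecture, templates = isoform_templates(),
                             tolerance = 2) {
  stopifnot(all(c("ALPHA_BETA", "BETA_ALPHA") %in% names(templates)))
  d1 <- architecture |> filter(.data$element == "DOMAIN_I")
  d3 <- architecture |> filter(.data$element == "DOMAIN_III")
  sizes <- architecture$n_helices[architecture$element == "TM_STRETCH"]
  flags <- character()
  if (nrow(d1) == 0L) flags <- c(flags, "MISSING_DOMAIN_I")
  if (nrow(d3) == 0L) flags <- c(flags, "MISSING_DOMAIN_III")

  if (length(flags) > 0L) {
    call <- list(label = "AMBIGUOUS", flags = flags,
                 stretch_sizes = as.integer(sizes),
                 template_deviation = integer(),
                 n_helices_between = NA_integer_)
    class(call) <- "isoform_call"
    return(call)
  }

  parity <- parity_check(architecture)
  label <- if (d1$start < d3$start) "ALPHA_BETA" else "BETA_ALPHA"
  expected <- templates[[label]]
  deviation <- integer()
  if (length(sizes) != length(expected)) {
    flags <- c(flags, "STRETCH_COUNT_DEVIATION")
  }
  n_cmp <- min(length(sizes), length(expected))
  if (n_cmp > 0L) {
    deviation <- as.integer(sizes[seq_len(n_cmp)] - expected[seq_len(n_cmp)])
    if (any(abs(deviation) > tolerance)) {
      flags <- c(flags, "TM_COUNT_DEVIATION")
    }
  }
  if (parity$status == "PARITY_VIOLATION") {
    label <- "INVALID"
    flags <- c(flags, "PARITY_VIOLATION")
  }
  call <- list(label = label, flags = flags,
               stretch_sizes = as.integer(sizes),
               template_deviation = deviation,
               n_helices_between = parity$n_between)
  class(call) <- "isoform_call"
  call
}

#' @export
print.isoform_call <- function(x, ...) {
  cat("<isoform_call>", x$label, "\n")
  cat("  stretches:", if (length(x$stretch_sizes)) paste(x$stretch_sizes, collapse = "+") else "none", "\n")
  cat("  helices between domains:", x$n_helices_between, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

classify_one_sequence <- function(sequence, params) {
  library <- nth_motif_library(params$motif$match_score,
                               params$motif$threshold_frac)
  hits <- find_domains(sequence, library, params$motif$max_hits_per_kind)
  helices <- predict_tm_helices(sequence, params$tm)
  stretches <- group_stretches(helices, split_points = hits,
                               max_gap = params$tm$max_gap)
  arch <- assemble_architecture(hits, stretches, max_gap = params$tm$max_gap)
  classify_isoform(arch, tolerance = params$classify$tolerance)
}

#' Classify a batch of protein records
#'
#' Runs the full scan-and-classify pipeline (domain motif scan, hydropathy
#' TM scan, stretch grouping, architecture assembly, isoform call) on each
#' record. Per-record failures are recorded as `ERROR` rows; the pipeline
#' continues.
#'
#' @param records Tibble of protein records with columns `id`, `genus`,
#'   `lineage`, `sequence` (see [read_protein_fasta()]).
#' @param params Pipeline parameters, see [nth_params()].
#' @return Object of class `nth_classification`: a list with `calls` (one
#'   row per record, input order preserved: `protein_id`, `genus`,
#'   `lineage`, `label`, `flags`, `stretch_sizes`, `n_helices_between`) and
#'   `summary` (lineage x label counts). [generics::tidy()] returns the
#'   calls, [generics::glance()] the overall label counts.
#' @export
classify_batch <- function(records, params = nth_params()) {
  records <- as_tibble(records)
  calls <- map(seq_len(nrow(records)), function(i) {
    tryCatch(classify_one_sequence(records$sequence[i], params),
             error = function(e) {
               structure(list(label = "ERROR",
                              flags = conditionMessage(e),
                              stretch_sizes = integer(),
                              template_deviation = integer(),
                              n_helices_between = NA_integer_),
                         class = "isoform_call")
             })
  })
  call_tbl <- tibble(
    protein_id = records$id %||% character(),
    genus = records$genus %||% rep(NA_character_, nrow(records)),
    lineage = records$lineage %||% rep(NA_character_, nrow(records)),
    label = map_chr(calls, "label"),
    flags = map_chr(calls, function(x) paste(x$flags, collapse = ",")),
    stretch_sizes = map_chr(calls, function(x)
      paste(x$stretch_sizes, collapse = "+")),
    n_helices_between = map_int(calls, "n_helices_between")
  )
  if (nrow(records) == 0L) {
    call_tbl <- call_tbl[0, ]
  }
  summary_tbl <- call_tbl |>
    count(.data$lineage, .data$label, name = "n_proteins")
  out <- list(calls = call_tbl, summary = summary_tbl)
  class(out) <- "nth_classification"
  out
}

#' @export
print.nth_classification <- function(x, ...) {
  cat("<nth_classification>", nrow(x$calls), "proteins\n")
  print(x$summary)
  invisible(x)
}
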