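#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile geom_text
#'   facet_wrap labs scale_fill_brewer scale_fill_manual theme_minimal
#' @export
ggplot2::autoplot

#' Tidy a batch classification
#'
#' @param x An `nth_classification` from [classify_batch()].
#' @param ... Unused.
#' @return The per-protein call table.
#' @method tidy nth_classification
#' @export
tidy.nth_classification <- function(x, ...) x$calls

#' One-row summary of a batch classification
#'
#' @param x An `nth_classification`.
#' @param ... Unused.
#' @return One-row tibble with the number of proteins and per-label counts.
#' @method glance nth_classification
#' @export
glance.nth_classification <- function(x, ...) {
  counts <- table(factor(x$calls$label, levels = ISOFORM_LABELS))
  out <- tibble(n_proteins = nrow(x$calls))
  for (lbl in ISOFORM_LABELS) {
    out[[paste0("n_", tolower(lbl))]] <- as.integer(counts[[lbl]])
  }
  out
}

#' Plot per-lineage isoform calls
#'
#' @param object An `nth_classification`.
#' @param ... Unused.
#' @return A ggplot: stacked bars of call counts per lineage.
#' @method autoplot nth_classification
#' @export
autoplot.nth_classification <- function(object, ...) {
  object$summary |>
    ggplot(aes(x = .data$lineage, y = .data$n_proteins, fill = .data$label)) +
    geom_col() +
    labs(x = NULL, y = "proteins", fill = "isoform call") +
    theme_minimal()
}

#' Tidy a Dollo loss scenario
#'
#' @param x A `dollo_scenario` from [dollo_losses()].
#' @param ... Unused.
#' @return Tibble with one row per inferred loss edge (`character`,
#'   `parent`, `node`, `lost_clade`).
#' @method tidy dollo_scenario
#' @export
tidy.dollo_scenario <- function(x, ...) {
  if (nrow(x$loss_edges) == 0L) {
    return(tibble(character = character(), parent = integer(),
                  node = integer(), lost_clade = character()))
  }
  x$loss_edges |>
    mutate(character = x$character,
           lost_clade = map_chr(.data$tips, paste, collapse = "+")) |>
    select("character", "parent", "node", "lost_clade")
}

#' One-row summary of a Dollo loss scenario
#'
#' @param x A `dollo_scenario`.
#' @param ... Unused.
#' @return One-row tibble: `character`, `root_present`, `n_losses`,
#'   `flags`.
#' @method glance dollo_scenario
#' @export
glance.dollo_scenario <- function(x, ...) {
  tibble(character = x$character, root_present = x$root_present,
         n_losses = x$n_losses,
         flags = paste(x$flags, collapse = ","))
}

#' Tidy a topology ranking
#'
#' @param x A `topology_ranking` from [compare_topologies()].
#' @param ... Unused.
#' @return Long tibble: `topology`, `character`, `n_losses`.
#' @method tidy topology_ranking
#' @export
tidy.topology_ranking <- function(x, ...) {
  x |>
    as_tibble() |>
    tidyr::pivot_longer(cols = !c("topology", "total_losses"),
                        names_to = "character", values_to = "n_losses") |>
    select("topology", "character", "n_losses")
}

#' Plot a topology ranking
#'
#' @param object A `topology_ranking`.
#' @param ... Unused.
#' @return A ggplot: per-character loss counts stacked by topology,
#'   ordered by total losses.
#' @method autoplot topology_ranking
#' @export
autoplot.topology_ranking <- function(object, ...) {
  long <- tidy(object)
  long$topology <- factor(long$topology, levels = object$topology)
  ggplot(long, aes(x = .data$topology, y = .data$n_losses,
                   fill = .data$character)) +
    geom_col() +
    labs(x = NULL, y = "implied gene losses", fill = "character") +
    theme_minimal()
}

#' Plot a presence/absence matrix
#'
#' @param object A `presence_matrix`.
#' @param ... Unused.
#' @return A ggplot tile map of character presence per lineage.
#' @method autoplot presence_matrix
#' @export
autoplot.presence_matrix <- function(object, ...) {
  long <- object |>
    as_tibble() |>
    tidyr::pivot_longer(cols = !"lineage", names_to = "character",
                        values_to = "present")
  long$lineage <- factor(long$lineage, levels = rev(object$lineage))
  ggplot(long, aes(x = .data$character, y = .data$lineage,
                   fill = .data$present)) +
    geom_tile(colour = "grey80") +
    scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey95")) +
    labs(x = NULL, y = NULL, fill = "present") +
    theme_minimal()
}
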