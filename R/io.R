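#' Path to a packaged fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists available fixtures.
#' @return File path (or vector of file names).
#' @export
nth_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "nthscan")))
  }
  path <- system.file("extdata", file, package = "nthscan")
  if (path == "") abort(sprintf("No packaged fixture named '%s'.", file))
  path
}

#' Read protein records from FASTA
#'
#' Headers are parsed as whitespace-separated `id [genus] [lineage]`; an
#' optional metadata table keyed by `id` takes precedence over
#' header-derived fields. Wrapped sequence lines are concatenated and
#' case-normalised to upper.
#'
#' @param path FASTA file path.
#' @param metadata Optional data frame with `id` and any of `genus`,
#'   `lineage`.
#' @return Tibble with `id`, `genus`, `lineage`, `sequence`.
#' @export
read_protein_fasta <- function(path, metadata = NULL) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  if (file.size(path) == 0L) {
    warn(sprintf("FASTA file '%s' is empty.", path))
    return(tibble(id = character(), genus = character(),
                  lineage = character(), sequence = character()))
  }
  set <- Biostrings::readAAStringSet(path)
  fields <- stringr::str_split(names(set), "\\s+")
  ids <- map_chr(fields, 1)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate FASTA ids: %s.",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  records <- tibble(
    id = ids,
    genus = map_chr(fields, function(f) if (length(f) >= 2) f[2] else NA_character_),
    lineage = map_chr(fields, function(f) if (length(f) >= 3) f[3] else NA_character_),
    sequence = unname(toupper(as.character(set)))
  )
  if (!is.null(metadata)) {
    metadata <- as_tibble(metadata)
    for (col in intersect(c("genus", "lineage"), names(metadata))) {
      idx <- match(records$id, metadata$id)
      override <- metadata[[col]][idx]
      records[[col]] <- ifelse(is.na(override), records[[col]], override)
    }
  }
  records
}

#' Write protein records to FASTA
#'
#' Inverse of [read_protein_fasta()]: headers are `id genus lineage`
#' (omitting trailing missing fields), sequences wrapped at 60 columns.
#'
#' @param records Tibble with `id`, `sequence` and optionally `genus`,
#'   `lineage`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  header <- map_chr(seq_len(nrow(records)), function(i) {
    parts <- c(records$id[i],
               if ("genus" %in% names(records)) records$genus[i],
               if ("lineage" %in% names(records)) records$lineage[i])
    # a missing middle field would shift parsing, so stop at the first NA
    if (anyNA(parts)) parts <- parts[seq_len(which(is.na(parts))[1] - 1L)]
    paste(parts, collapse = " ")
  })
  set <- Biostrings::AAStringSet(setNames(records$sequence, header))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read and write newick trees
#'
#' Thin wrappers around `ape` that keep polytomies, tolerate quoted labels
#' and absent branch lengths, and report unbalanced parentheses with the
#' character offset of the imbalance.
#'
#' @param path File path (for `read_newick`) or output path.
#' @param tree A `phylo` tree.
#' @return `read_newick()` a `phylo` tree; `write_newick()` the path,
#'   invisibly.
#' @export
read_newick <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(text))) {
    ch <- substr(text, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("Unbalanced ')' at character offset %d.", i))
      }
    }
  }
  if (depth != 0L) {
    abort(sprintf("Unbalanced '(': %d unclosed at end of input.", depth))
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) abort(sprintf("Could not parse newick in '%s'.", path))
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read and write presence/absence matrices as TSV
#'
#' Machine format: a `lineage` column plus one `1`/`0` column per
#' character.
#'
#' @param path TSV path.
#' @param matrix A `presence_matrix`.
#' @return `read_presence_matrix()` a `presence_matrix` tibble;
#'   `write_presence_matrix()` the path, invisibly.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as_tibble(df)
  for (col in setdiff(names(m), "lineage")) m[[col]] <- m[[col]] == 1
  class(m) <- c("presence_matrix", class(m))
  m
}

#' @rdname read_presence_matrix
#' @export
write_presence_matrix <- function(matrix, path) {
  out <- as.data.frame(matrix)
  for (col in setdiff(names(out), "lineage")) {
    out[[col]] <- as.integer(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Human-readable rendering of a presence matrix
#'
#' Renders presence as a check mark and absence as blank, mirroring the
#' conventional printed layout of gene-content tables.
#'
#' @param matrix A `presence_matrix`.
#' @return Tibble of strings.
#' @export
format_presence_matrix <- function(matrix) {
  out <- as_tibble(as.data.frame(matrix))
  for (col in setdiff(names(out), "lineage")) {
    out[[col]] <- ifelse(out[[col]], "√", "")
  }
  out
}

#' Export architecture elements as TSV
#'
#' Writes helices, stretches or domain hits in the shared element layout
#' (`protein_id`, `element_type`, `start`, `end`; 0-based half-open).
#'
#' @param elements Tibble with an element-type column and `start`, `end`.
#' @param protein_id Protein identifier recycled across rows.
#' @param path Output path.
#' @param element_type Column name holding the element type (`"kind"` for
#'   domain hits, `"element"` for architectures); helices default to
#'   `TM_HELIX`.
#' @return The path, invisibly.
#' @export
write_elements_tsv <- function(elements, protein_id, path,
                               element_type = NULL) {
  type <- if (!is.null(element_type)) {
    elements[[element_type]]
  } else if ("kind" %in% names(elements)) {
    elements$kind
  } else if ("element" %in% names(elements)) {
    elements$element
  } else {
    rep("TM_HELIX", nrow(elements))
  }
  out <- data.frame(protein_id = protein_id, element_type = type,
                    start = elements$start, end = elements$end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
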