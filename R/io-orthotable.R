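#' Read an orthogroup membership table
#'
#' Reads the OrthoFinder `Orthogroups.tsv` dialect: a header row of taxon
#' names (first column the orthogroup id), one row per orthogroup, cells
#' holding comma+space separated protein id lists. Empty cells mean the taxon
#' has no member in that orthogroup (the taxon is still part of the table's
#' taxon universe).
#'
#' @param path Path to an Orthogroups-style TSV.
#' @return A long tibble with columns `og_id`, `taxon`, `protein_id` (one row
#'   per member protein; taxa with empty cells contribute no rows) carrying
#'   the full taxon universe in attribute `"taxa"` (see [og_taxa()]).
#' @export
read_orthotable <- function(path) {
  if (!file.exists(path)) abort(sprintf("orthotable not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) abort("orthotable is empty")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  n_col <- length(header)
  if (n_col < 2L) abort("orthotable needs an id column plus >=1 taxon column")
  taxa <- header[-1L]
  rows <- cells[-1L]
  # trailing empty cells are dropped by strsplit; pad, but flag short rows
  # only when the raw line lacks the right number of tab separators
  n_tabs <- lengths(regmatches(lines[-1L], gregexpr("\t", lines[-1L], fixed = TRUE)))
  ragged <- which(n_tabs != (n_col - 1L))
  if (length(ragged)) {
    abort(sprintf("ragged row(s) in orthotable (expected %d columns): row %s",
                  n_col, paste(ragged + 1L, collapse = ", ")))
  }
  rows <- lapply(rows, function(r) c(r, rep("", n_col - length(r))))
  og_ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(og_ids)) abort("duplicate orthogroup id(s)")
  long <- purrr::map_dfr(seq_along(rows), function(i) {
    prot <- strsplit(rows[[i]][-1L], ", ", fixed = TRUE)
    tibble(
      og_id = og_ids[i],
      taxon = rep(taxa, lengths(prot)),
      protein_id = unlist(prot) %||% character()
    )
  })
  long <- dplyr::filter(long, nzchar(.data$protein_id))
  dup <- long %>%
    dplyr::count(.data$og_id, .data$protein_id) %>%
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("protein id(s) repeated within an orthogroup: %s",
                  paste(dup$protein_id, collapse = ", ")))
  }
  attr(long, "taxa") <- taxa
  long
}

#' Taxon universe of an orthotable
#'
#' @param og_table A tibble from [read_orthotable()] or [gen_orthogroups()].
#' @return Character vector of all taxa in the table, including taxa absent
#'   from every row that still appeared in the source header.
#' @export
og_taxa <- function(og_table) {
  attr(og_table, "taxa") %||% sort(unique(og_table$taxon))
}

#' Write an orthotable in the Orthogroups.tsv dialect
#'
#' Inverse of [read_orthotable()]; round-trips exactly.
#'
#' @inheritParams og_taxa
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthotable <- function(og_table, path) {
  taxa <- og_taxa(og_table)
  ogs <- unique(og_table$og_id)
  wide <- vapply(ogs, function(og) {
    sub <- og_table[og_table$og_id == og, ]
    vapply(taxa, function(tx) paste(sub$protein_id[sub$taxon == tx],
                                    collapse = ", "), "")
  }, character(length(taxa)))
  wide <- matrix(wide, nrow = length(taxa))  # guard 1-taxon edge case
  lines <- c(paste(c("Orthogroup", taxa), collapse = "\t"),
             vapply(seq_along(ogs), function(i) {
               paste(c(ogs[i], wide[, i]), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
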