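#' Per-orthogroup paralogy and representation statistics
#'
#' For each orthogroup: the number of species with at least one member
#' protein, the number of distinct phyla among those species, and the
#' single-copy fraction — the proportion of member proteins contributed by
#' taxa that have exactly one protein in the group. A group of `{t1:[p1],
#' t2:[p2], t3:[p3,p4]}` therefore has `n_species = 3` and
#' `single_copy_fraction = 2/4`.
#'
#' @param og_table Long orthotable tibble (`og_id`, `taxon`, `protein_id`),
#'   as from [read_orthotable()] or [gen_orthogroups()].
#' @param phylum_map Tibble mapping `taxon` to `phylum`; every taxon with a
#'   member protein must be mapped.
#' @return Tibble with columns `og_id`, `n_species`, `n_phyla`,
#'   `single_copy_fraction`, one row per orthogroup.
#' @export
og_stats <- function(og_table, phylum_map) {
  stopifnot(all(c("taxon", "phylum") %in% names(phylum_map)))
  missing <- setdiff(unique(og_table$taxon), phylum_map$taxon)
  if (length(missing)) {
    abort(sprintf("taxa missing from phylum_map: %s",
                  paste(missing, collapse = ", ")))
  }
  og_table %>%
    dplyr::count(.data$og_id, .data$taxon, name = "n_prot") %>%
    left_join(phylum_map, by = "taxon") %>%
    group_by(.data$og_id) %>%
    summarise(
      n_species = dplyr::n(),
      n_phyla = dplyr::n_distinct(.data$phylum),
      single_copy_fraction = sum(.data$n_prot[.data$n_prot == 1L]) /
        sum(.data$n_prot),
      .groups = "drop"
    )
}

#' Filter orthogroups for supermatrix construction
#'
#' Keeps an orthogroup iff `single_copy_fraction > min_single_copy`
#' (strictly), `n_phyla >= min_phyla` and `n_species >= min_species`.
#' Rejected groups carry the first failed criterion, checked in that order.
#' A group at exactly the single-copy threshold is rejected.
#'
#' @inheritParams og_stats
#' @param min_single_copy Strict lower bound on the single-copy fraction.
#' @param min_phyla,min_species Inclusive minima on phylum and species
#'   representation.
#' @return The [og_stats()] tibble with added columns `keep` (logical) and
#'   `reason` (`NA` for kept groups; otherwise `"single_copy"`, `"phyla"` or
#'   `"species"`).
#' @export
filter_ogs <- function(og_table, phylum_map, min_single_copy = 0.80,
                       min_phyla = 4L, min_species = 10L) {
  og_stats(og_table, phylum_map) %>%
    mutate(
      reason = case_when(
        .data$single_copy_fraction <= min_single_copy ~ "single_copy",
        .data$n_phyla < min_phyla ~ "phyla",
        .data$n_species < min_species ~ "species",
        TRUE ~ NA_character_
      ),
      keep = is.na(.data$reason)
    )
}

#' Remove multi-copy taxa from filtered orthogroups
#'
#' Drops, within each orthogroup, every taxon contributing more than one
#' protein, so that the result is strictly single-copy (idempotent). Groups
#' whose species count falls below `min_species` after pruning are kept but
#' flagged.
#'
#' @inheritParams og_stats
#' @param min_species Species count below which a pruned group is flagged.
#' @return The pruned long tibble, with attributes `"removed"` (tibble
#'   `og_id`, `taxon` of dropped taxa) and `"flagged"` (character vector of
#'   og ids whose pruned species count is below `min_species`).
#' @export
prune_multicopy <- function(og_table, min_species = 10L) {
  counts <- og_table %>% dplyr::count(.data$og_id, .data$taxon, name = "n_prot")
  multi <- counts %>% dplyr::filter(.data$n_prot > 1L)
  pruned <- og_table %>%
    dplyr::anti_join(multi, by = c("og_id", "taxon"))
  left <- pruned %>% group_by(.data$og_id) %>%
    summarise(n_species = dplyr::n_distinct(.data$taxon), .groups = "drop")
  flagged <- left$og_id[left$n_species < min_species]
  if (length(flagged)) {
    warn(sprintf("%d orthogroup(s) fell below %d species after pruning",
                 length(flagged), min_species))
  }
  attr(pruned, "removed") <- as_tibble(multi[c("og_id", "taxon")])
  attr(pruned, "flagged") <- flagged
  attr(pruned, "taxa") <- og_taxa(og_table)
  pruned
}

#' Concatenate per-orthogroup alignments into a partitioned supermatrix
#'
#' Blocks are ordered lexicographically by orthogroup id; a taxon absent from
#' an orthogroup receives an all-gap (`-`) block. Row lengths equal the sum
#' of block lengths by construction.
#'
#' @param alignments Tibble with columns `og_id`, `taxon`, `seq`; within an
#'   orthogroup all sequences must have equal (aligned) length.
#' @param taxon_universe Character vector of all row taxa; defaults to the
#'   taxa present in `alignments`.
#' @return A `supermatrix` object: list with `sequences` (tibble `taxon`,
#'   `seq`, in `taxon_universe` order), `blocks` (tibble `name`, `start`,
#'   `end`, 1-based inclusive) and `occupancy` (tibble `taxon`,
#'   `occupancy` = non-gap fraction).
#' @export
concatenate_supermatrix <- function(alignments, taxon_universe = NULL) {
  stopifnot(all(c("og_id", "taxon", "seq") %in% names(alignments)))
  if (nrow(alignments) == 0L) abort("no alignments supplied")
  taxon_universe <- taxon_universe %||% sort(unique(alignments$taxon))
  extra <- setdiff(alignments$taxon, taxon_universe)
  if (length(extra)) {
    abort(sprintf("taxa outside taxon_universe: %s", paste(extra, collapse = ", ")))
  }
  ogs <- sort(unique(alignments$og_id))
  lens <- integer(length(ogs))
  rows <- setNames(rep(list(character()), length(taxon_universe)), taxon_universe)
  for (i in seq_along(ogs)) {
    sub <- alignments[alignments$og_id == ogs[i], ]
    if (anyDuplicated(sub$taxon)) {
      abort(sprintf("taxon repeated in alignment of %s (prune first?)", ogs[i]))
    }
    len <- unique(nchar(sub$seq))
    if (length(len) != 1L) {
      abort(sprintf("ragged alignment in orthogroup %s", ogs[i]))
    }
    lens[i] <- len
    gap <- strrep("-", len)
    block <- setNames(rep(gap, length(taxon_universe)), taxon_universe)
    block[sub$taxon] <- sub$seq
    for (tx in taxon_universe) rows[[tx]] <- c(rows[[tx]], block[[tx]])
  }
  seqs <- vapply(rows, paste, "", collapse = "")
  ends <- cumsum(lens)
  blocks <- tibble(name = ogs, start = c(1L, head(ends, -1L) + 1L), end = ends)
  occupancy <- tibble(
    taxon = taxon_universe,
    occupancy = 1 - stringr::str_count(seqs, stringr::fixed("-")) / sum(lens)
  )
  structure(
    list(sequences = tibble(taxon = taxon_universe, seq = unname(seqs)),
         blocks = blocks, occupancy = occupancy),
    class = "supermatrix"
  )
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("<supermatrix> %d taxa x %d sites in %d blocks (mean occupancy %.3f)\n",
              nrow(x$sequences), sum(x$blocks$end - x$blocks$start + 1L),
              nrow(x$blocks), mean(x$occupancy$occupancy)))
  invisible(x)
}

#' @rdname concatenate_supermatrix
#' @param x A `supermatrix` object.
#' @param ... Unused.
#' @export
tidy.supermatrix <- function(x, ...) {
  x$blocks
}

#' @rdname concatenate_supermatrix
#' @export
glance.supermatrix <- function(x, ...) {
  tibble(
    n_taxa = nrow(x$sequences),
    n_blocks = nrow(x$blocks),
    total_length = sum(x$blocks$end - x$blocks$start + 1L),
    mean_occupancy = mean(x$occupancy$occupancy)
  )
}

#' Write a supermatrix to FASTA plus partition file
#'
#' @param sm A `supermatrix` object.
#' @param fasta_path,partition_path Output paths (either may be `NULL` to
#'   skip).
#' @param model Model placeholder for [write_partitions()].
#' @return `sm`, invisibly.
#' @export
write_supermatrix <- function(sm, fasta_path = NULL, partition_path = NULL,
                              model = "AUTO") {
  if (!is.null(fasta_path)) {
    write_fasta(rename(sm$sequences, id = "taxon"), fasta_path)
  }
  if (!is.null(partition_path)) {
    write_partitions(sm$blocks, partition_path, model = model)
  }
  invisible(sm)
}
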