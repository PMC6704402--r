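#' Read gene models from GFF3
#'
#' Reads `gene`, `mRNA`, `exon` and `three_prime_UTR` features via
#' [rtracklayer::import()] and flattens them to one row per gene. GFF3's
#' 1-based inclusive coordinates are converted to the package-internal
#' 0-based half-open convention on read (and back on write), losslessly.
#' Exons parented to an mRNA are resolved through the mRNA to its gene.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with one row per gene: `gene_id`, `contig`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (gene span, 0-based half-open),
#'   `utr3_start`, `utr3_end` (`NA` when no 3' UTR is annotated) and `exons`,
#'   a list-column of tibbles with sorted, non-overlapping `start`/`end`
#'   intervals.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) abort(sprintf("GFF3 not found: %s", path))
  gr <- rtracklayer::import(path)
  df <- as_tibble(as.data.frame(gr))
  need <- c("type", "ID", "Parent")
  for (col in setdiff(need, names(df))) df[[col]] <- NA_character_
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0L || all(is.na(p))) NA_character_ else as.character(p[[1L]])
  }, "")
  genes <- df[df$type == "gene", ]
  if (nrow(genes) == 0L) abort("no gene features in GFF3")
  mrna_parent <- setNames(df$Parent[df$type == "mRNA"], df$ID[df$type == "mRNA"])
  to_gene <- function(parent) {
    ifelse(parent %in% names(mrna_parent), unname(mrna_parent[parent]), parent)
  }
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    kids <- df[!is.na(df$Parent) & to_gene(df$Parent) == g$ID, ]
    ex <- kids[kids$type == "exon", ]
    ex <- ex[order(ex$start), ]
    exons <- tibble(start = ex$start - 1L, end = ex$end)
    if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)])) {
      abort(sprintf("overlapping exons in gene %s", g$ID))
    }
    utr <- kids[kids$type == "three_prime_UTR", ]
    tibble(
      gene_id = g$ID, contig = as.character(g$seqnames),
      strand = as.character(g$strand),
      start = g$start - 1L, end = g$end,
      utr3_start = if (nrow(utr)) min(utr$start) - 1L else NA_integer_,
      utr3_end = if (nrow(utr)) max(utr$end) else NA_integer_,
      exons = list(exons)
    )
  })
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gff_genes()].
#'
#' @param genes Tibble as returned by [read_gff_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff_genes <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    fmt <- function(type, s, e, attrs) {
      sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$contig, "glaucokit", type, s + 1L, e, g$strand, attrs)
    }
    lines <- c(lines, fmt("gene", g$start, g$end, sprintf("ID=%s", g$gene_id)))
    ex <- g$exons[[1L]]
    if (!is.null(ex) && nrow(ex)) {
      lines <- c(lines, vapply(seq_len(nrow(ex)), function(j) {
        fmt("exon", ex$start[j], ex$end[j],
            sprintf("ID=%s.exon%d;Parent=%s", g$gene_id, j, g$gene_id))
      }, ""))
    }
    if (!is.na(g$utr3_start)) {
      lines <- c(lines, fmt("three_prime_UTR", g$utr3_start, g$utr3_end,
                            sprintf("ID=%s.utr3;Parent=%s", g$gene_id, g$gene_id)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a genes-by-samples count matrix TSV
#'
#' @param path TSV with gene ids in the first column and one column per
#'   sample.
#' @return Tibble with column `gene` followed by integer sample columns.
#' @rdname counts_io
#' @export
read_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1L] <- "gene"
  x
}

#' @param counts Tibble as returned by [read_counts()].
#' @rdname counts_io
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}
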