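#' Six-frame ORF detection on a transcript
#'
#' Scans all six reading frames of a nucleotide sequence for maximal open
#' reading frames of at least `min_aa` residues, reporting every hit in
#' forward-strand coordinates (0-based half-open). Two definitions are
#' offered: `atg_to_stop` (the default) anchors each ORF at the first ATG
#' after the previous in-frame stop and runs to the next stop;
#' `stop_to_stop` reports the whole stop-free stretch. ORFs truncated by the
#' sequence boundary (no terminal stop) are reported with `truncated = TRUE`.
#' The standard genetic code is used; codons containing `N` count as neither
#' start nor stop.
#'
#' `aa_len` excludes the stop codon, so a complete hit spans
#' `3 * (aa_len + 1)` nucleotides (a 300-aa ORF occupies >= 900 nt) and a
#' truncated hit spans `3 * aa_len`.
#'
#' @param seq A single nucleotide sequence (character scalar) or a one-row
#'   tibble with `id`/`seq` columns as from [read_fasta()].
#' @param min_aa Minimum peptide length in residues.
#' @param mode ORF definition, `"atg_to_stop"` or `"stop_to_stop"`.
#' @param id Sequence id used in the output when `seq` is a bare string.
#' @return Tibble with columns `seq_id`, `strand`, `frame` (0/1/2 on its own
#'   strand), `start`, `end` (forward coordinates), `aa_len`, `truncated`.
#' @export
#' @examples
#' find_orfs("ATGAAATAA", min_aa = 2)
find_orfs <- function(seq, min_aa = 300L, mode = c("atg_to_stop", "stop_to_stop"),
                      id = "seq") {
  mode <- match.arg(mode)
  min_aa <- check_scalar_count(min_aa, "min_aa", min = 1)
  if (is.data.frame(seq)) {
    stopifnot(all(c("id", "seq") %in% names(seq)))
    return(purrr::map_dfr(seq_len(nrow(seq)), function(i) {
      find_orfs(seq$seq[i], min_aa = min_aa, mode = mode, id = seq$id[i])
    }))
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L == 0L) abort("empty sequence")
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      n_codon <- (L - frame) %/% 3L
      if (n_codon < 1L) next
      starts_nt <- frame + 3L * (seq_len(n_codon) - 1L)  # 0-based on strand
      codons <- substring(s, starts_nt + 1L, starts_nt + 3L)
      is_stop <- codons %in% stop_codons
      is_atg <- codons == "ATG"
      seg_id <- cumsum(c(TRUE, is_stop[-n_codon]))  # segment = run ending at a stop
      for (sg in split(seq_len(n_codon), seg_id)) {
        stop_here <- is_stop[sg[length(sg)]]
        body <- if (stop_here) sg[-length(sg)] else sg
        if (!length(body)) next
        first <- if (mode == "atg_to_stop") {
          atg <- which(is_atg[body])
          if (!length(atg)) next
          body[atg[1L]]
        } else {
          body[1L]
        }
        aa_len <- body[length(body)] - first + 1L
        if (aa_len < min_aa) next
        nt0 <- starts_nt[first]
        nt1 <- starts_nt[body[length(body)]] + 3L + (if (stop_here) 3L else 0L)
        if (strand == "+") {
          st <- nt0; en <- nt1
        } else {
          st <- L - nt1; en <- L - nt0
        }
        out[[length(out) + 1L]] <- tibble(
          seq_id = id, strand = strand, frame = frame,
          start = st, end = en, aa_len = aa_len, truncated = !stop_here
        )
      }
    }
  }
  if (!length(out)) {
    return(tibble(seq_id = character(), strand = character(), frame = integer(),
                  start = integer(), end = integer(), aa_len = integer(),
                  truncated = logical()))
  }
  bind_rows(out) %>% arrange(.data$strand, .data$frame, .data$start)
}

#' Detect opposite-strand overlapping ORF pairs
#'
#' Pairs every plus-strand hit with every minus-strand hit from the same
#' transcript whose forward-coordinate intervals overlap by at least
#' `min_overlap` nucleotides. A pair is `complete` when one interval contains
#' the other, `partial` otherwise. A transcript is called bidirectional when
#' it has at least one pair.
#'
#' @param orfs ORF tibble from [find_orfs()] (may hold several transcripts).
#' @param min_overlap Minimum nucleotide overlap.
#' @return Tibble with one row per pair: `seq_id`, plus/minus coordinates and
#'   peptide lengths, `overlap_nt`, `overlap_class`.
#' @export
detect_bidirectional_pairs <- function(orfs, min_overlap = 1L) {
  min_overlap <- check_scalar_count(min_overlap, "min_overlap", min = 1)
  empty <- tibble(seq_id = character(),
                  plus_start = integer(), plus_end = integer(), plus_aa = integer(),
                  minus_start = integer(), minus_end = integer(), minus_aa = integer(),
                  overlap_nt = integer(), overlap_class = character())
  if (nrow(orfs) == 0L) return(empty)
  plus <- orfs %>% filter(.data$strand == "+") %>%
    select("seq_id", plus_start = "start", plus_end = "end", plus_aa = "aa_len")
  minus <- orfs %>% filter(.data$strand == "-") %>%
    select("seq_id", minus_start = "start", minus_end = "end", minus_aa = "aa_len")
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(empty)
  pairs <- dplyr::inner_join(plus, minus, by = "seq_id",
                             relationship = "many-to-many") %>%
    mutate(overlap_nt = pmin(.data$plus_end, .data$minus_end) -
             pmax(.data$plus_start, .data$minus_start)) %>%
    filter(.data$overlap_nt >= min_overlap) %>%
    mutate(overlap_class = dplyr::if_else(
      (.data$plus_start <= .data$minus_start & .data$minus_end <= .data$plus_end) |
        (.data$minus_start <= .data$plus_start & .data$plus_end <= .data$minus_end),
      "complete", "partial"))
  pairs
}

#' Stranded-coverage transcription support for a bidirectional pair
#'
#' Given per-base stranded read coverage over the transcript, computes the
#' fraction of each ORF span covered at depth `>= min_depth` on its own
#' strand. Pairs whose minus-strand ORF has covered fraction below
#' `unsupported_below` are labelled `unsupported_minus`: long antisense ORFs
#' with no stranded read support are translation artefacts, not transcribed
#' genes.
#'
#' @param pair One row of [detect_bidirectional_pairs()] output.
#' @param plus_cov,minus_cov Integer vectors of per-base coverage, length
#'   equal to the transcript length.
#' @param min_depth Depth at or above which a base counts as covered.
#' @param unsupported_below Threshold on the minus fraction for the
#'   `unsupported_minus` label.
#' @return One-row tibble: `seq_id`, `plus_cov_fraction`,
#'   `minus_cov_fraction`, `support` (`"both"` or `"unsupported_minus"`).
#' @export
strand_support <- function(pair, plus_cov, minus_cov, min_depth = 1L,
                           unsupported_below = 0.1) {
  stopifnot(nrow(pair) == 1L)
  if (length(plus_cov) != length(minus_cov)) {
    abort("plus/minus coverage arrays differ in length")
  }
  L <- length(plus_cov)
  if (pair$plus_end > L || pair$minus_end > L) {
    abort("coverage array shorter than ORF span")
  }
  frac <- function(cov, s, e) mean(cov[(s + 1L):e] >= min_depth)
  pf <- frac(plus_cov, pair$plus_start, pair$plus_end)
  mf <- frac(minus_cov, pair$minus_start, pair$minus_end)
  tibble(
    seq_id = pair$seq_id,
    plus_cov_fraction = pf,
    minus_cov_fraction = mf,
    support = dplyr::if_else(mf < unsupported_below, "unsupported_minus", "both")
  )
}

#' Convergent 3'-UTR overlap between two gene models
#'
#' Reports an overlap when two genes on the same contig lie on opposite
#' strands in convergent orientation (3' ends facing each other) and their
#' annotated 3'-UTR intervals overlap by at least `min_overlap` nucleotides.
#' When a gene lacks a 3' UTR and `utr_fallback_nt > 0`, the terminal
#' `utr_fallback_nt` bases of the gene span stand in for the UTR.
#'
#' @param a,b One-row gene-model tibbles (columns `gene_id`, `contig`,
#'   `strand`, `start`, `end`, `utr3_start`, `utr3_end`; coordinates 0-based
#'   half-open as from [read_gff_genes()]).
#' @param min_overlap Minimum overlap in nucleotides.
#' @param utr_fallback_nt Width of the gene-terminus window used when a 3'
#'   UTR is not annotated; `0` means genes without UTRs are skipped.
#' @return A one-row tibble (`gene_a`, `gene_b`, `overlap_start`,
#'   `overlap_end`, `overlap_nt`) or a zero-row tibble when the pair is not
#'   a convergent overlapping pair.
#' @export
utr_overlap <- function(a, b, min_overlap = 1L, utr_fallback_nt = 0L) {
  no <- tibble(gene_a = character(), gene_b = character(),
               overlap_start = integer(), overlap_end = integer(),
               overlap_nt = integer())
  if (a$contig != b$contig) return(no)
  if (a$strand == b$strand) return(no)
  p <- if (a$strand == "+") a else b
  m <- if (a$strand == "+") b else a
  # convergent: plus gene upstream (left) of minus gene, tails meeting inside
  if (!(p$start < m$start && p$end < m$end)) return(no)
  utr_iv <- function(g) {
    if (!is.na(g$utr3_start)) return(c(g$utr3_start, g$utr3_end))
    if (utr_fallback_nt <= 0L) return(NULL)
    if (g$strand == "+") c(max(g$start, g$end - utr_fallback_nt), g$end)
    else c(g$start, min(g$end, g$start + utr_fallback_nt))
  }
  ip <- utr_iv(p); im <- utr_iv(m)
  if (is.null(ip) || is.null(im)) return(no)
  s <- max(ip[1L], im[1L]); e <- min(ip[2L], im[2L])
  if (e - s < min_overlap) return(no)
  tibble(gene_a = a$gene_id, gene_b = b$gene_id,
         overlap_start = as.integer(s), overlap_end = as.integer(e),
         overlap_nt = as.integer(e - s))
}
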