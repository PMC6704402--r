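# longest stop-free stretch (nt) over the three reverse-strand frames
max_minus_stopfree_nt <- function(seq) {
  s <- revcomp(seq)
  L <- nchar(s)
  best <- 0L
  for (frame in 0:2) {
    n_codon <- (L - frame) %/% 3L
    if (n_codon < 1L) next
    starts <- frame + 3L * (seq_len(n_codon) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    run <- rle(!(codons %in% stop_codons))
    open <- run$lengths[run$values]
    if (length(open)) best <- max(best, 3L * max(open))
  }
  best
}

#' Simulate transcripts with planted bidirectional overlapping ORFs
#'
#' Positive transcripts carry a forward ORF and a fully contained
#' reverse-strand ORF, both of at least `min_aa` residues. The overlap
#' region is built from codons that are stop-free on both strands in the
#' aligned frame, so the reverse-complemented interior reads as an open
#' frame by construction; the reverse ORF's own start and stop codons are
#' embedded in reverse complement inside the forward ORF. Negative
#' transcripts carry only a forward ORF; candidate negatives whose minus
#' strand happens to hold a stop-free stretch long enough for a `min_aa`
#' ORF are rejected and resampled, so the truth labels are exact.
#'
#' @inheritParams gen_orthogroups
#' @param n_pos,n_neg Numbers of positive (bidirectional) and negative
#'   transcripts.
#' @param min_aa Minimum ORF length in residues (a 300-aa ORF spans at
#'   least 900 nt).
#' @param pad_codons Forward-only codons flanking the dual-coding core
#'   inside the forward ORF.
#' @param flank_range UTR-like random flank length range (nt).
#' @param max_attempts Rejection-sampling budget per negative transcript.
#' @return List with `seqs` (tibble `id`, `seq`) and `truth` (tibble `id`,
#'   `is_bidirectional`, and for positives the planted forward/reverse ORF
#'   intervals in forward 0-based half-open coordinates).
#' @export
gen_bidir_transcripts <- function(seed, n_pos = 10L, n_neg = 10L,
                                  min_aa = 300L, pad_codons = 5L,
                                  flank_range = c(50L, 150L),
                                  max_attempts = 10000L) {
  min_aa <- check_scalar_count(min_aa, "min_aa", 1)
  withr::with_seed(seed, {
    rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")
    flank <- function() rand_nt(sample(flank_range[1L]:flank_range[2L], 1L))
    make_pos <- function(id) {
      minus_orf <- paste(c("ATG", sample(DUAL_SAFE_CODONS, min_aa - 1L,
                                         replace = TRUE), "TAA"), collapse = "")
      x <- revcomp(minus_orf)
      d1 <- paste(sample(DUAL_SAFE_CODONS, pad_codons, replace = TRUE), collapse = "")
      d2 <- paste(sample(DUAL_SAFE_CODONS, pad_codons, replace = TRUE), collapse = "")
      orf <- paste0("ATG", d1, x, d2, "TAA")
      f5 <- flank(); f3 <- flank()
      seq <- paste0(f5, orf, f3)
      ps <- nchar(f5)
      ms <- ps + 3L + nchar(d1)
      tibble(id = id, seq = seq, is_bidirectional = TRUE,
             plus_start = ps, plus_end = ps + nchar(orf),
             minus_start = ms, minus_end = ms + nchar(x))
    }
    make_neg <- function(id) {
      for (attempt in seq_len(max_attempts)) {
        body <- paste(sample(NONSTOP_CODONS, min_aa + sample(0:50, 1L),
                             replace = TRUE), collapse = "")
        seq <- paste0(flank(), "ATG", body, "TAA", flank())
        if (max_minus_stopfree_nt(seq) < 3L * min_aa) {
          return(tibble(id = id, seq = seq, is_bidirectional = FALSE,
                        plus_start = NA_integer_, plus_end = NA_integer_,
                        minus_start = NA_integer_, minus_end = NA_integer_))
        }
      }
      abort("rejection budget exhausted building a negative transcript; try a shorter min_aa")
    }
    pos <- purrr::map_dfr(seq_len(n_pos), function(i) make_pos(sprintf("pos_%03d", i)))
    neg <- purrr::map_dfr(seq_len(n_neg), function(i) make_neg(sprintf("neg_%03d", i)))
    all <- bind_rows(pos, neg)
    list(seqs = select(all, id = "id", seq = "seq"),
         truth = select(all, -"seq"))
  })
}
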