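test_that("find_orfs handles the minimal hand cases", {
  hits <- find_orfs("ATGAAATAA", min_aa = 2)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 0L)
  expect_equal(hits$end, 9L)
  expect_equal(hits$aa_len, 2L)
  expect_false(hits$truncated)
  # the minus strand of ATGAAATAA (TTATTTCAT) holds no ATG...stop of >= 2 aa
  expect_equal(sum(hits$strand == "-"), 0L)
  # conversely the reverse-complemented sequence carries the ORF on minus
  rc_hits <- find_orfs("TTATTTCAT", min_aa = 2)
  expect_equal(rc_hits$strand, "-")
  expect_equal(rc_hits$aa_len, 2L)
  expect_error(find_orfs("", min_aa = 1), "empty")
})

test_that("complete spans are 3*(aa+1) nt and truncated spans 3*aa nt", {
  hits <- find_orfs("ATGAAATAA", min_aa = 2)
  expect_equal(hits$end - hits$start, 3L * (hits$aa_len + 1L))
  trunc <- find_orfs("ATGAAAAAA", min_aa = 2)   # no stop before the boundary
  trunc <- trunc[trunc$strand == "+" & trunc$frame == 0, ]
  expect_true(trunc$truncated)
  expect_equal(trunc$end - trunc$start, 3L * trunc$aa_len)
})

test_that("find_orfs matches a brute-force position-by-position scan", {
  withr::with_seed(99, {
    for (i in 1:20) {
      s <- random_dna(600)
      for (mode in c("atg_to_stop", "stop_to_stop")) {
        got <- find_orfs(s, min_aa = 20, mode = mode)
        want <- brute_orfs(s, min_aa = 20, mode = mode)
        expect_equal(nrow(got), nrow(want))
        if (nrow(got)) {
          expect_equal(got$start, want$start)
          expect_equal(got$end, want$end)
          expect_equal(got$aa_len, want$aa_len)
          expect_equal(got$truncated, want$truncated)
        }
      }
    }
  })
})

test_that("strand symmetry: scanning the reverse complement swaps strands", {
  withr::with_seed(123, {
    for (i in 1:10) {
      s <- random_dna(500)
      L <- nchar(s)
      fwd <- find_orfs(s, min_aa = 15)
      rev <- find_orfs(brute_revcomp(s), min_aa = 15)
      reflected <- tibble::tibble(
        strand = ifelse(rev$strand == "+", "-", "+"),
        start = L - rev$end, end = L - rev$start, aa_len = rev$aa_len
      )
      expect_equal(
        dplyr::arrange(reflected, strand, start),
        dplyr::arrange(fwd[c("strand", "start", "end", "aa_len")], strand, start)
      )
    }
  })
})

test_that("raising min_aa never adds hits", {
  withr::with_seed(5, s <- random_dna(2000))
  lo <- find_orfs(s, min_aa = 10)
  hi <- find_orfs(s, min_aa = 30)
  key <- function(d) paste(d$strand, d$frame, d$start, d$end)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("pair detection applies interval arithmetic and containment", {
  orfs <- tibble::tibble(
    seq_id = "tx", strand = c("+", "-"), frame = 0L,
    start = c(0L, 300L), end = c(900L, 1200L), aa_len = c(299L, 299L),
    truncated = FALSE
  )
  p <- detect_bidirectional_pairs(orfs)
  expect_equal(p$overlap_nt, 600L)
  expect_equal(p$overlap_class, "partial")

  orfs$start <- c(0L, 150L); orfs$end <- c(1200L, 1050L)
  p2 <- detect_bidirectional_pairs(orfs)
  expect_equal(p2$overlap_class, "complete")

  # same-strand hits never pair; disjoint intervals never pair
  orfs$strand <- c("+", "+")
  expect_equal(nrow(detect_bidirectional_pairs(orfs)), 0L)
  orfs$strand <- c("+", "-"); orfs$start <- c(0L, 500L); orfs$end <- c(300L, 900L)
  expect_equal(nrow(detect_bidirectional_pairs(orfs)), 0L)
})

test_that("planted bidirectional transcripts are recovered exactly", {
  sim <- gen_bidir_transcripts(seed = 17, n_pos = 8, n_neg = 8, min_aa = 300)
  orfs <- find_orfs(sim$seqs, min_aa = 300)
  pairs <- detect_bidirectional_pairs(orfs)
  called_pos <- unique(pairs$seq_id)
  truth_pos <- sim$truth$id[sim$truth$is_bidirectional]
  expect_setequal(called_pos, truth_pos)
  # the planted reverse ORF interval lies inside a detected minus hit
  for (id in truth_pos) {
    tr <- sim$truth[sim$truth$id == id, ]
    hit <- pairs[pairs$seq_id == id, ]
    expect_true(any(hit$minus_start <= tr$minus_start &
                    tr$minus_end <= hit$minus_end))
  }
})

test_that("transcript reversal with strand relabeling conserves the pair count", {
  sim <- gen_bidir_transcripts(seed = 23, n_pos = 3, n_neg = 3, min_aa = 100)
  for (i in seq_len(nrow(sim$seqs))) {
    s <- sim$seqs$seq[i]
    n1 <- nrow(detect_bidirectional_pairs(find_orfs(s, min_aa = 100)))
    n2 <- nrow(detect_bidirectional_pairs(find_orfs(brute_revcomp(s), min_aa = 100)))
    expect_equal(n1, n2)
  }
})

test_that("strand support flags antisense ORFs without stranded coverage", {
  pair <- tibble::tibble(seq_id = "tx", plus_start = 10L, plus_end = 40L,
                         plus_aa = 9L, minus_start = 20L, minus_end = 50L,
                         minus_aa = 9L, overlap_nt = 20L,
                         overlap_class = "partial")
  L <- 60L
  sup <- strand_support(pair, plus_cov = rep(5L, L), minus_cov = rep(0L, L))
  expect_equal(sup$minus_cov_fraction, 0)
  expect_equal(sup$support, "unsupported_minus")
  sup2 <- strand_support(pair, plus_cov = rep(5L, L), minus_cov = rep(5L, L))
  expect_equal(sup2$plus_cov_fraction, 1)
  expect_equal(sup2$minus_cov_fraction, 1)
  expect_equal(sup2$support, "both")
  # fraction equals a direct per-base count on random coverage
  withr::with_seed(2, cov <- rpois(L, 1))
  sup3 <- strand_support(pair, plus_cov = cov, minus_cov = cov)
  expect_equal(sup3$minus_cov_fraction,
               sum(cov[21:50] >= 1) / 30)
  expect_error(strand_support(pair, rep(1, 10), rep(1, 9)), "length")
})

test_that("utr_overlap requires convergent opposite-strand gene pairs", {
  gp <- tibble::tibble(gene_id = "gA", contig = "tig", strand = "+",
                       start = 0L, end = 3000L,
                       utr3_start = 2800L, utr3_end = 3000L)
  gm <- tibble::tibble(gene_id = "gB", contig = "tig", strand = "-",
                       start = 2900L, end = 6000L,
                       utr3_start = 2900L, utr3_end = 3100L)
  ov <- utr_overlap(gp, gm)
  expect_equal(ov$overlap_nt, 100L)
  expect_equal(ov$overlap_start, 2900L)

  # divergent orientation (minus gene upstream): no report
  gm2 <- dplyr::mutate(gm, start = 0L, end = 2000L,
                       utr3_start = 0L, utr3_end = 200L)
  gp2 <- dplyr::mutate(gp, start = 1900L, end = 5000L,
                       utr3_start = 4800L, utr3_end = 5000L)
  expect_equal(nrow(utr_overlap(gp2, gm2)), 0L)

  # same strand: no report
  gm3 <- dplyr::mutate(gm, strand = "+")
  expect_equal(nrow(utr_overlap(gp, gm3)), 0L)

  # different contig: no report
  gm4 <- dplyr::mutate(gm, contig = "other")
  expect_equal(nrow(utr_overlap(gp, gm4)), 0L)

  # UTR-less genes use the gene-terminus fallback only when enabled
  gm5 <- dplyr::mutate(gm, utr3_start = NA_integer_, utr3_end = NA_integer_)
  expect_equal(nrow(utr_overlap(gp, gm5)), 0L)
  ov5 <- utr_overlap(gp, gm5, utr_fallback_nt = 200L)
  expect_equal(ov5$overlap_nt, 100L)
})
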