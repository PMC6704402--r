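counts3 <- tibble::tibble(gene = c("g1", "g2", "g3"),
                          s1 = c(10, 30, 50), s2 = c(20, 60, 100))

test_that("size factors follow the median-of-ratios hand computation", {
  sf <- size_factors(counts3)
  expect_equal(sf$size_factor, c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  # identical columns: all factors 1
  eq <- tibble::tibble(gene = c("a", "b"), s1 = c(5, 9), s2 = c(5, 9))
  expect_equal(size_factors(eq)$size_factor, c(1, 1))
  # scale equivariance: doubling one sample's counts doubles its factor
  # relative to the others (the geometric-mean reference rescales too)
  doubled <- dplyr::mutate(counts3, s2 = s2 * 2)
  sfd <- size_factors(doubled)
  expect_equal(sfd$size_factor[2] / sfd$size_factor[1],
               2 * sf$size_factor[2] / sf$size_factor[1])
  zero <- tibble::tibble(gene = c("a", "b"), s1 = c(0, 5), s2 = c(5, 0))
  expect_error(size_factors(zero), "nonzero")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  tc <- gen_timecourse_counts(seed = 14, n_de = 50, n_flat = 200)
  m <- as.matrix(tc$counts[-1])
  rownames(m) <- tc$counts$gene
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  sf <- size_factors(tc$counts)
  expect_equal(sf$size_factor, unname(ref), tolerance = 1e-8)
})

test_that("the DE rule combines the 1.5 log2FC contrast with annotation", {
  # planted means (10, 40, 10, 10, 10, 10): log2(41/11) = 1.898 >= 1.5
  TIMEPOINTS_TEST <- c("1ALO", "8ALO", "14ALO", "1AD", "5AD", "7AD")
  # flat genes dominate so every median-of-ratios factor is exactly 1 and
  # the normalized means equal the planted ones
  mk_gene <- function(g, means) {
    tibble::tibble(gene = g,
                   !!!setNames(as.list(rep(means, each = 3)),
                               paste0(rep(TIMEPOINTS_TEST, each = 3), "_r", 1:3)))
  }
  counts <- dplyr::bind_rows(
    mk_gene("g1", c(10, 40, 10, 10, 10, 10)),
    mk_gene("gflat", rep(10, 6)),
    mk_gene("gflat2", rep(25, 6)),
    mk_gene("gflat3", rep(80, 6)),
    mk_gene("gflat4", rep(130, 6))
  )
  samples <- tibble::tibble(
    sample = paste0(rep(TIMEPOINTS_TEST, each = 3), "_r", 1:3),
    timepoint = rep(TIMEPOINTS_TEST, each = 3),
    replicate = rep(1:3, 6)
  )
  ann <- tibble::tibble(gene = counts$gene, has_annotation = TRUE)
  de <- de_genes(counts, samples, ann)
  g1 <- de[de$gene == "g1", ]
  expect_equal(g1$max_abs_log2fc, log2(41 / 11), tolerance = 1e-6)
  expect_equal(g1$fc_timepoint, "8ALO")
  expect_true(g1$is_de)
  expect_false(de$is_de[de$gene == "gflat"])

  # the annotation requirement vetoes an otherwise qualifying gene
  ann2 <- dplyr::mutate(ann, has_annotation = gene != "g1")
  de2 <- de_genes(counts, samples, ann2)
  expect_false(de2$is_de[de2$gene == "g1"])
  expect_gte(de2$max_abs_log2fc[de2$gene == "g1"], 1.5)

  # a missing timepoint is an error
  expect_error(de_genes(counts, samples[samples$timepoint != "5AD", ],
                        ann), "5AD")
})

test_that("DE calling is invariant to replicate column order", {
  tc <- gen_timecourse_counts(seed = 26, n_de = 20, n_flat = 30)
  de1 <- de_genes(tc$counts, tc$samples, tc$annotations)
  perm <- withr::with_seed(3, sample(2:19))
  counts2 <- tc$counts[c(1, perm)]
  de2 <- de_genes(counts2, tc$samples, tc$annotations)
  expect_equal(de1, de2)
})

test_that("the log transform hits its fixed points and stabilizes variance", {
  counts <- tibble::tibble(gene = c("a", "b"), s1 = c(0, 7), s2 = c(0, 7))
  f1 <- tibble::tibble(sample = c("s1", "s2"), size_factor = c(1, 1))
  tr <- vst_transform(counts, f1)
  expect_equal(tr$s1, c(0, 3))
  # on NB counts, the transformed variance grows sub-linearly with the mean
  withr::with_seed(31, {
    tiers <- c(10, 100, 1000)
    raw_var <- sapply(tiers, function(mu) var(rnbinom(2000, mu = mu, size = 50)))
    tr_var <- sapply(tiers, function(mu) var(log2(rnbinom(2000, mu = mu, size = 50) + 1)))
  })
  expect_true(all(diff(raw_var) > 0))
  expect_lt(tr_var[3] / tr_var[1], raw_var[3] / raw_var[1])
})

test_that("profile clustering recovers planted shapes and handles duplicates", {
  tc <- gen_timecourse_counts(seed = 33, n_de = 100, n_flat = 50, n_patterns = 2)
  de_set <- tc$truth$gene[tc$truth$is_de]
  cl <- cluster_profiles(vst_transform(tc$counts), tc$samples,
                         genes = de_set, k = 2)
  truth <- tc$truth$pattern[match(cl$gene, tc$truth$gene)]
  # two planted shapes, low noise: perfect agreement up to label switching
  expect_equal(mclust::adjustedRandIndex(cl$cluster, truth), 1)

  # a single profile duplicated: everything in one cluster at any cut height
  dup <- tc$counts[tc$counts$gene == de_set[1], ]
  dups <- dplyr::bind_rows(lapply(1:10, function(i) {
    dplyr::mutate(dup, gene = paste0("dup", i))
  }))
  cl2 <- cluster_profiles(dups, tc$samples, h = 0.5)
  expect_equal(length(unique(cl2$cluster)), 1L)

  expect_error(cluster_profiles(dups, tc$samples, k = 50), "more clusters")
  expect_error(cluster_profiles(dups, tc$samples), "exactly one")
  p <- plot_cluster_profiles(cl)
  expect_s3_class(p, "ggplot")
})

test_that("clustering does not depend on input row order", {
  tc <- gen_timecourse_counts(seed = 37, n_de = 40, n_flat = 10, n_patterns = 4)
  tr <- vst_transform(tc$counts)
  cl1 <- cluster_profiles(tr, tc$samples, k = 4)
  shuffled <- withr::with_seed(9, tr[sample.int(nrow(tr)), ])
  cl2 <- cluster_profiles(shuffled, tc$samples, k = 4)
  expect_identical(cl1, cl2)
})

test_that("peak phase takes the earliest maximum and flags flat profiles", {
  means <- tibble::tibble(
    gene = c("pcna_like", "cycb_like", "flat", "early"),
    `1ALO` = c(1, 1, 5, 9), `8ALO` = c(9, 2, 5, 5), `14ALO` = c(3, 9, 5, 4),
    `1AD` = c(1, 1, 5, 3), `5AD` = c(1, 1, 5, 2), `7AD` = c(1, 1, 5, 1)
  )
  pk <- peak_phase(means)
  expect_equal(as.character(pk$peak),
               c("8ALO", "14ALO", "1ALO", "1ALO"))
  expect_true(pk$flat[pk$gene == "flat"])
  expect_false(pk$declining_from_start[pk$gene == "flat"])
  expect_true(pk$declining_from_start[pk$gene == "early"])
  # ties break to the earliest timepoint
  tie <- tibble::tibble(gene = "t", `1ALO` = 1, `8ALO` = 7, `14ALO` = 7,
                        `1AD` = 1, `5AD` = 1, `7AD` = 1)
  expect_equal(as.character(peak_phase(tie)$peak), "8ALO")
})
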