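#' Median-of-ratios size factors
#'
#' Per-sample normalization constants computed with the median-of-ratios
#' formula: for each gene present in every sample, the ratio of its count to
#' its across-sample geometric mean; a sample's factor is the median ratio.
#' Factors are scale-equivariant (doubling one sample's counts doubles its
#' factor) and are not renormalized.
#'
#' @param counts Tibble with a `gene` column followed by one integer column
#'   per sample.
#' @return Tibble with columns `sample`, `size_factor`.
#' @export
#' @examples
#' size_factors(tibble::tibble(gene = c("g1", "g2", "g3"),
#'                             s1 = c(10, 30, 50), s2 = c(20, 60, 100)))
size_factors <- function(counts) {
  m <- counts_matrix(counts)
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    abort("no gene has nonzero counts in all samples; cannot form the geometric-mean reference")
  }
  lm <- log(m[all_pos, , drop = FALSE])
  loggeo <- rowMeans(lm)
  sf <- apply(lm, 2L, function(col) exp(median(col - loggeo)))
  tibble(sample = colnames(m), size_factor = unname(sf))
}

counts_matrix <- function(counts) {
  stopifnot("gene" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "gene")])
  rownames(m) <- counts$gene
  storage.mode(m) <- "double"
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

validate_samples <- function(samples, sample_names) {
  stopifnot(all(c("sample", "timepoint") %in% names(samples)))
  missing_tp <- setdiff(TIMEPOINTS, samples$timepoint)
  if (length(missing_tp)) {
    abort(sprintf("missing timepoint(s): %s", paste(missing_tp, collapse = ", ")))
  }
  missing_s <- setdiff(sample_names, samples$sample)
  if (length(missing_s)) {
    abort(sprintf("sample(s) not in sample sheet: %s",
                  paste(missing_s, collapse = ", ")))
  }
  samples
}

#' Replicate-mean expression per timepoint
#'
#' @param counts Tibble (`gene` + sample columns) of counts or transformed
#'   values.
#' @param samples Sample sheet tibble with columns `sample`, `timepoint`
#'   (levels `1ALO`, `8ALO`, `14ALO`, `1AD`, `5AD`, `7AD`) and optionally
#'   `replicate`.
#' @return Tibble `gene` plus one column per timepoint, in diel order.
#' @export
timepoint_means <- function(counts, samples) {
  m <- counts_matrix(counts)
  validate_samples(samples, colnames(m))
  tp <- setNames(samples$timepoint, samples$sample)[colnames(m)]
  means <- vapply(TIMEPOINTS, function(t) {
    rowMeans(m[, tp == t, drop = FALSE])
  }, numeric(nrow(m)))
  means <- matrix(means, nrow = nrow(m),
                  dimnames = list(counts$gene, TIMEPOINTS))
  dplyr::bind_cols(tibble(gene = counts$gene), as_tibble(means))
}

#' Call differentially expressed genes in the light/dark time course
#'
#' A gene is differentially expressed when (i) the absolute log2 fold change
#' between the first timepoint (1ALO) and any other timepoint is at least
#' `fc_threshold`, and (ii) the gene carries a functional annotation (a
#' proxy for a database hit). Fold changes are computed on
#' size-factor-normalized, replicate-averaged counts with a pseudocount of 1.
#'
#' @param counts Raw count tibble (`gene` + sample columns).
#' @param samples Sample sheet (see [timepoint_means()]).
#' @param annotations Tibble with columns `gene`, `has_annotation`; genes
#'   absent from it count as unannotated.
#' @param fc_threshold Log2 fold-change threshold (default 1.5).
#' @param pseudocount Added to normalized means before the log ratio.
#' @return Tibble: `gene`, the six normalized timepoint means, `max_abs_log2fc`,
#'   `fc_timepoint` (where the maximum is reached), `has_annotation`, `is_de`.
#' @export
de_genes <- function(counts, samples, annotations = NULL, fc_threshold = 1.5,
                     pseudocount = 1) {
  sf <- size_factors(counts)
  m <- counts_matrix(counts)
  norm <- sweep(m, 2L, setNames(sf$size_factor, sf$sample)[colnames(m)], "/")
  norm_tbl <- dplyr::bind_cols(tibble(gene = counts$gene), as_tibble(norm))
  means <- timepoint_means(norm_tbl, samples)
  mm <- as.matrix(means[TIMEPOINTS])
  lfc <- log2(sweep(mm[, -1L, drop = FALSE] + pseudocount, 1L,
                    mm[, "1ALO"] + pseudocount, "/"))
  max_i <- apply(abs(lfc), 1L, which.max)
  ann <- if (is.null(annotations)) {
    rep(TRUE, nrow(means))
  } else {
    stopifnot(all(c("gene", "has_annotation") %in% names(annotations)))
    a <- setNames(annotations$has_annotation, annotations$gene)[means$gene]
    !is.na(a) & a
  }
  means %>%
    mutate(
      max_abs_log2fc = apply(abs(lfc), 1L, max),
      fc_timepoint = colnames(lfc)[max_i],
      has_annotation = ann,
      is_de = .data$max_abs_log2fc >= fc_threshold & ann
    )
}

#' Variance-stabilizing log transform
#'
#' `log2(count / size_factor + 1)` — a monotone, dispersion-free
#' approximation to a model-based variance-stabilizing transform, adequate
#' for profile clustering where only relative shapes matter.
#'
#' @inheritParams de_genes
#' @param factors Output of [size_factors()]; computed when `NULL`.
#' @return Tibble of the same shape as `counts` with transformed values.
#' @export
vst_transform <- function(counts, factors = NULL) {
  factors <- factors %||% size_factors(counts)
  m <- counts_matrix(counts)
  tr <- log2(sweep(m, 2L, setNames(factors$size_factor, factors$sample)[colnames(m)],
                   "/") + 1)
  dplyr::bind_cols(tibble(gene = counts$gene), as_tibble(tr))
}

#' Agglomerative clustering of expression profiles
#'
#' Average-linkage hierarchical clustering of per-gene z-scored timepoint
#' mean profiles (Euclidean distance), cut at `k` clusters or height `h`.
#' Genes are processed in lexicographic id order so the result does not
#' depend on input row order. Constant profiles get a zero z-profile.
#'
#' @param transformed Transformed expression tibble (see [vst_transform()]).
#' @param samples Sample sheet.
#' @param genes Optional character vector restricting clustering to a gene
#'   set (typically the DE set).
#' @param k Number of clusters (mutually exclusive with `h`).
#' @param h Dendrogram cut height.
#' @return Tibble `gene`, `cluster` (integer), with attribute `"profiles"`:
#'   a tibble of per-cluster mean z-profiles (`cluster`, `timepoint`,
#'   `mean_z`).
#' @export
cluster_profiles <- function(transformed, samples, genes = NULL, k = NULL,
                             h = NULL) {
  if (is.null(k) == is.null(h)) abort("supply exactly one of `k` or `h`")
  if (!is.null(genes)) {
    transformed <- transformed[transformed$gene %in% genes, , drop = FALSE]
  }
  if (nrow(transformed) < 2L) abort("need at least 2 genes to cluster")
  if (!is.null(k) && k > nrow(transformed)) {
    abort("more clusters requested than genes")
  }
  transformed <- arrange(transformed, .data$gene)
  means <- timepoint_means(transformed, samples)
  mm <- as.matrix(means[TIMEPOINTS])
  rownames(mm) <- means$gene
  z <- t(apply(mm, 1L, function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  hc <- hclust(dist(z), method = "average")
  cl <- if (!is.null(k)) cutree(hc, k = k) else cutree(hc, h = h)
  out <- tibble(gene = means$gene, cluster = unname(cl))
  prof <- as_tibble(z) %>%
    mutate(cluster = unname(cl)) %>%
    tidyr::pivot_longer(-"cluster", names_to = "timepoint",
                        values_to = "z") %>%
    group_by(.data$cluster, .data$timepoint) %>%
    summarise(mean_z = mean(.data$z), .groups = "drop") %>%
    mutate(timepoint = factor(.data$timepoint, levels = TIMEPOINTS)) %>%
    arrange(.data$cluster, .data$timepoint)
  attr(out, "profiles") <- prof
  out
}

#' Peak phase of a diel expression profile
#'
#' The timepoint at which the profile is maximal, ties broken to the
#' earliest timepoint in diel order. A profile maximal at 1ALO is flagged
#' `declining_from_start` (genes induced within the first hour of light that
#' decline thereafter); constant profiles are flagged `flat`.
#'
#' @param means Tibble with a `gene` column and one column per timepoint
#'   (as from [timepoint_means()]).
#' @return Tibble `gene`, `peak` (factor in diel order),
#'   `declining_from_start`, `flat`.
#' @export
peak_phase <- function(means) {
  stopifnot(all(TIMEPOINTS %in% names(means)))
  mm <- as.matrix(means[TIMEPOINTS])
  idx <- apply(mm, 1L, which.max)  # which.max breaks ties to the first
  tibble(
    gene = means$gene,
    peak = factor(TIMEPOINTS[idx], levels = TIMEPOINTS),
    declining_from_start = idx == 1L & apply(mm, 1L, function(x) any(x != x[1L])),
    flat = apply(mm, 1L, function(x) all(x == x[1L]))
  )
}

#' Plot per-cluster mean expression profiles
#'
#' @param clusters Output of [cluster_profiles()].
#' @return A ggplot object: one line per cluster over the six timepoints.
#' @export
plot_cluster_profiles <- function(clusters) {
  prof <- attr(clusters, "profiles")
  if (is.null(prof)) abort("`clusters` lacks a profiles attribute")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$timepoint, y = .data$mean_z,
                                     group = .data$cluster)) +
    ggplot2::geom_line(color = "grey30") +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "timepoint", y = "mean z-scored expression") +
    ggplot2::theme_minimal()
}
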