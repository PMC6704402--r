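# build n distinct diel expression patterns as log2 offsets from the 1ALO
# baseline; patterns are maximin-separated in z-profile space so planted
# cluster labels are recoverable, and each pattern's peak timepoint leads
# the runner-up by >= peak_margin log2 units so the planted peak phase is
# well defined
make_patterns <- function(n_patterns, fold_change, min_sep = 1.5,
                          peak_margin = 0.5, budget = 5000L) {
  zscore <- function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  pats <- matrix(NA_real_, n_patterns, 6L)
  zs <- matrix(NA_real_, n_patterns, 6L)
  sep <- min_sep
  k <- 1L
  tries <- 0L
  while (k <= n_patterns) {
    v <- c(0, runif(5L, -1, 1))
    delta <- fold_change * v / max(abs(v))
    z <- zscore(delta)
    top2 <- sort(delta, decreasing = TRUE)[1:2]
    ok <- (top2[1L] - top2[2L]) >= peak_margin &&
      (k == 1L ||
       min(sqrt(rowSums(sweep(zs[seq_len(k - 1L), , drop = FALSE], 2L, z)^2))) >= sep)
    if (ok) {
      pats[k, ] <- delta
      zs[k, ] <- z
      k <- k + 1L
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > budget) {
        sep <- sep * 0.9  # relax separation rather than fail outright
        tries <- 0L
      }
    }
  }
  colnames(pats) <- TIMEPOINTS
  pats
}

#' Simulate a 6-timepoint light/dark expression count matrix
#'
#' Counts follow a negative binomial with per-sample library size factors:
#' `count ~ NB(mean = base * 2^delta[timepoint] * size_factor, dispersion)`.
#' Differentially expressed genes follow one of `n_patterns` planted diel
#' patterns whose extreme timepoint differs from the 1ALO baseline by
#' exactly `fold_change` in log2; flat genes are planted negatives. Three
#' replicates per timepoint, eighteen samples in all.
#'
#' @inheritParams gen_orthogroups
#' @param n_de,n_flat Numbers of differentially expressed and flat genes.
#' @param fold_change Planted |log2 fold change| between 1ALO and the
#'   pattern's extreme timepoint.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be > 0.
#' @param n_patterns Number of distinct planted diel patterns.
#' @param base_mean_log_mu,base_mean_log_sd Log-normal parameters of
#'   per-gene baseline means.
#' @param min_base_mean Baseline means are truncated below this value
#'   (profiles of weakly expressed genes are not recoverable from counts at
#'   any threshold).
#' @param lib_size_factors Planted per-sample size factors (length 18);
#'   default spans a 2-fold range with geometric mean 1.
#' @return List: `counts` (tibble `gene` + 18 sample columns), `samples`
#'   (sample sheet), `annotations` (all genes annotated), `truth` (tibble
#'   `gene`, `is_de`, `pattern`, `peak`, `planted_log2fc`, `base_mean`),
#'   `patterns` (matrix of planted log2 offsets), `size_factors` (planted).
#' @export
gen_timecourse_counts <- function(seed, n_de = 200L, n_flat = 800L,
                                  fold_change = 2.0, dispersion = 0.02,
                                  n_patterns = 8L,
                                  base_mean_log_mu = log(100),
                                  base_mean_log_sd = 1,
                                  min_base_mean = 10,
                                  lib_size_factors = NULL) {
  if (dispersion <= 0) abort("dispersion must be > 0")
  if (fold_change <= 0) abort("fold_change must be > 0")
  n_de <- check_scalar_count(n_de, "n_de", 0)
  n_flat <- check_scalar_count(n_flat, "n_flat", 0)
  sf <- lib_size_factors %||% 2^seq(-0.5, 0.5, length.out = 18L)
  if (length(sf) != 18L || any(sf <= 0)) {
    abort("lib_size_factors must be 18 positive values")
  }
  samples <- tibble(
    sample = paste0(rep(TIMEPOINTS, each = 3L), "_r", rep(1:3, 6L)),
    timepoint = rep(TIMEPOINTS, each = 3L),
    replicate = rep(1:3, 6L)
  )
  withr::with_seed(seed, {
    pats <- make_patterns(n_patterns, fold_change)
    n <- n_de + n_flat
    genes <- sprintf("g%05d", seq_len(n))
    is_de <- c(rep(TRUE, n_de), rep(FALSE, n_flat))
    pattern <- ifelse(is_de, rep_len(seq_len(n_patterns), n), NA_integer_)
    base <- pmax(min_base_mean, rlnorm(n, base_mean_log_mu, base_mean_log_sd))
    delta <- matrix(0, n, 6L, dimnames = list(genes, TIMEPOINTS))
    delta[is_de, ] <- pats[pattern[is_de], , drop = FALSE]
    mu <- base * 2^delta   # genes x timepoints
    tp_of_sample <- match(samples$timepoint, TIMEPOINTS)
    counts_mat <- vapply(seq_len(18L), function(j) {
      rnbinom(n, mu = mu[, tp_of_sample[j]] * sf[j], size = 1 / dispersion)
    }, numeric(n))
    colnames(counts_mat) <- samples$sample
    counts <- dplyr::bind_cols(tibble(gene = genes), as_tibble(counts_mat))
    truth <- tibble(
      gene = genes, is_de = is_de, pattern = pattern,
      peak = factor(TIMEPOINTS[apply(mu, 1L, which.max)], levels = TIMEPOINTS),
      planted_log2fc = ifelse(is_de,
                              apply(delta, 1L, function(d) d[which.max(abs(d))]),
                              0),
      base_mean = base
    )
    list(counts = counts, samples = samples,
         annotations = tibble(gene = genes, has_annotation = TRUE),
         truth = truth, patterns = pats,
         size_factors = tibble(sample = samples$sample, size_factor = sf))
  })
}
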