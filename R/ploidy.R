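#' Filter variant calls for the allele-frequency diagnostic
#'
#' Applies the variant-caller style filters used before ploidy inference:
#' minimum total coverage, minimum alternate-read count, and (only when a
#' quality value is present) minimum site quality.
#'
#' @param variants Variant tibble ([read_vcf()] / [gen_variant_set()]).
#' @param min_coverage Minimum read coverage (default 10).
#' @param min_alt_count Minimum alternate observation count (default 3).
#' @param min_quality Minimum phred-scaled site quality, applied only to
#'   records whose `quality` is non-missing (default 20).
#' @return The filtered tibble.
#' @export
filter_variants <- function(variants, min_coverage = 10L, min_alt_count = 3L,
                            min_quality = 20) {
  validate_variants(variants)
  qual <- if ("quality" %in% names(variants)) variants$quality else NA_real_
  keep <- variants$coverage >= min_coverage &
    variants$alt_count >= min_alt_count &
    (is.na(qual) | qual >= min_quality)
  variants[keep, , drop = FALSE]
}

#' Fraction of variants inside an allele-frequency band
#'
#' The alternate-allele frequency of each site is `alt_count / coverage`;
#' the band is closed (`[lo, hi]` inclusive). A depleted 30-70% band —
#' relative to the diploid expectation — is the signature of a haploid
#' assembly whose variants are dominated by sequencing error and fixed
#' differences rather than heterozygosity.
#'
#' @param variants Variant tibble (typically after [filter_variants()]).
#' @param lo,hi Band bounds on the frequency scale.
#' @return One-row tibble: `n_total`, `n_in_band`, `band_fraction`.
#' @export
band_fraction <- function(variants, lo = 0.30, hi = 0.70) {
  if (nrow(variants) == 0L) abort("no variants after filtering")
  f <- variants$alt_count / variants$coverage
  n_in <- sum(f >= lo & f <= hi)
  tibble(n_total = nrow(variants), n_in_band = n_in,
         band_fraction = n_in / nrow(variants))
}

#' Exact diploid expectation for the band fraction
#'
#' Under the diploid null every variant site is heterozygous, so the
#' alternate read count at a site of coverage `c` is `Binomial(c, 1/2)`. The
#' expected fraction of sites inside the band is the mean over the observed
#' coverages of `P(lo <= X/c <= hi)`, computed exactly from the binomial
#' mass function. At coverage 10 and band \[0.3, 0.7\] this is
#' `P(3 <= X <= 7) = 0.890625`.
#'
#' @param coverages Integer vector of per-site coverages (each >= 1).
#' @param lo,hi Band bounds.
#' @return Expected band fraction in \[0, 1\].
#' @export
expected_diploid_band <- function(coverages, lo = 0.30, hi = 0.70) {
  stopifnot(all(coverages >= 1))
  per_cov <- function(c) {
    k_lo <- ceiling(lo * c)
    k_hi <- floor(hi * c)
    if (k_hi < k_lo) return(0)
    sum(dbinom(k_lo:k_hi, size = c, prob = 0.5))
  }
  u <- unique(coverages)
  p <- vapply(u, per_cov, 0)
  mean(p[match(coverages, u)])
}

#' Allele-frequency-band ploidy call
#'
#' Compares the observed band fraction with the exact diploid expectation
#' over the same sites and calls ploidy from their ratio: below
#' `haploid_below` the heterozygous SNP class is essentially missing and the
#' genome is called haploid; at or above `diploid_above` the observed
#' spectrum matches the diploid null; in between the call is ambiguous.
#' All inputs to the decision are carried in the report.
#'
#' @param variants Variant tibble (raw; filtering is applied here).
#' @param lo,hi Frequency band (default 0.30-0.70).
#' @param min_coverage,min_alt_count,min_quality Passed to
#'   [filter_variants()].
#' @param haploid_below,diploid_above Decision thresholds on the
#'   observed/expected ratio.
#' @return A `ploidy_report` object (also a list): `n_total`, `n_in_band`,
#'   `band_fraction`, `expected_diploid_band`, `ratio`, `call`, plus the
#'   band and thresholds used. Use [tidy()]/[glance()] for tabular views.
#' @export
ploidy_call <- function(variants, lo = 0.30, hi = 0.70,
                        min_coverage = 10L, min_alt_count = 3L,
                        min_quality = 20,
                        haploid_below = 0.5, diploid_above = 0.75) {
  kept <- filter_variants(variants, min_coverage, min_alt_count, min_quality)
  bf <- band_fraction(kept, lo = lo, hi = hi)
  expd <- expected_diploid_band(kept$coverage, lo = lo, hi = hi)
  ratio <- bf$band_fraction / expd
  call <- if (ratio < haploid_below) "haploid"
          else if (ratio >= diploid_above) "diploid"
          else "ambiguous"
  structure(
    list(n_total = bf$n_total, n_in_band = bf$n_in_band,
         band_fraction = bf$band_fraction,
         expected_diploid_band = expd, ratio = ratio, call = call,
         band = c(lo = lo, hi = hi),
         thresholds = c(haploid_below = haploid_below,
                        diploid_above = diploid_above)),
    class = "ploidy_report"
  )
}

#' @export
print.ploidy_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<ploidy_report> call: %s\n",
    "  %d / %d variants (%.1f%%) at frequency %.0f-%.0f%%\n",
    "  diploid expectation %.1f%%; observed/expected ratio %.3f\n"),
    x$call, x$n_in_band, x$n_total, 100 * x$band_fraction,
    100 * x$band["lo"], 100 * x$band["hi"],
    100 * x$expected_diploid_band, x$ratio))
  invisible(x)
}

#' @rdname ploidy_call
#' @param x A `ploidy_report`.
#' @param ... Unused.
#' @export
glance.ploidy_report <- function(x, ...) {
  tibble(n_total = x$n_total, n_in_band = x$n_in_band,
         band_fraction = x$band_fraction,
         expected_diploid_band = x$expected_diploid_band,
         ratio = x$ratio, call = x$call)
}

#' @rdname ploidy_call
#' @export
tidy.ploidy_report <- function(x, ...) {
  tibble(
    statistic = c("n_total", "n_in_band", "band_fraction",
                  "expected_diploid_band", "ratio"),
    value = c(x$n_total, x$n_in_band, x$band_fraction,
              x$expected_diploid_band, x$ratio)
  )
}

#' Allele-frequency spectrum plot
#'
#' Histogram of alternate-allele frequencies (bin width 0.02) with the
#' diagnostic band shaded; a haploid callset shows an empty band, a diploid
#' one a central mode at 0.5.
#'
#' @param variants Variant tibble (pre-filtered as desired).
#' @param lo,hi Band to shade.
#' @param binwidth Histogram bin width on the frequency scale.
#' @return A ggplot object.
#' @export
plot_allele_spectrum <- function(variants, lo = 0.30, hi = 0.70,
                                 binwidth = 0.02) {
  df <- tibble(freq = variants$alt_count / variants$coverage)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq)) +
    ggplot2::annotate("rect", xmin = lo, xmax = hi, ymin = -Inf, ymax = Inf,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30") +
    ggplot2::labs(x = "alternate allele frequency", y = "variants") +
    ggplot2::theme_minimal()
}
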