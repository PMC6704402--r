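#' Simulate an orthogroup table with planted filter outcomes
#'
#' Generates an OrthoFinder-style membership table in which each orthogroup
#' is planted either to pass all three supermatrix filter criteria
#' (single-copy fraction strictly above `min_single_copy`, at least
#' `min_phyla` phyla, at least `min_species` species) or to fail exactly one
#' designated criterion. Taxa are assigned to phyla round-robin; multi-copy
#' taxa contribute two proteins. The truth table is exact by construction,
#' so it is a perfect oracle for [filter_ogs()].
#'
#' @param seed Integer seed; the same configuration always yields identical
#'   output.
#' @param n_ogs Number of orthogroups.
#' @param pass_fraction Fraction of orthogroups planted to pass (rounded).
#' @param n_taxa,n_phyla Size of the taxon pool and number of phylum labels.
#' @param paralog_rate Per-taxon probability of being multi-copy in passing
#'   groups (capped so the group still passes). With `paralog_rate = 0`
#'   every group is fully single-copy and no group is planted to fail the
#'   paralogy criterion.
#' @param min_single_copy,min_phyla,min_species The filter thresholds the
#'   truth labels refer to.
#' @return List with `table` (long orthotable tibble), `truth` (tibble
#'   `og_id`, `pass`, `fail_criterion`, `n_species`, `n_phyla`,
#'   `single_copy_fraction`) and `phylum_map` (tibble `taxon`, `phylum`).
#' @export
gen_orthogroups <- function(seed, n_ogs = 100L, pass_fraction = 0.4,
                            n_taxa = 40L, n_phyla = 8L, paralog_rate = 0.15,
                            min_single_copy = 0.80, min_phyla = 4L,
                            min_species = 10L) {
  n_ogs <- check_scalar_count(n_ogs, "n_ogs", 1)
  n_taxa <- check_scalar_count(n_taxa, "n_taxa", 1)
  n_phyla <- check_scalar_count(n_phyla, "n_phyla", 1)
  if (n_phyla > n_taxa) abort("more phyla than taxa")
  if (n_taxa < min_species) abort("n_taxa below min_species: no passing OG is constructible")
  if (n_phyla < min_phyla) abort("n_phyla below min_phyla: no passing OG is constructible")
  stopifnot(pass_fraction >= 0, pass_fraction <= 1,
            paralog_rate >= 0, paralog_rate <= 1)
  taxa <- sprintf("t%03d", seq_len(n_taxa))
  phyla <- sprintf("phylum%02d", ((seq_len(n_taxa) - 1L) %% n_phyla) + 1L)
  phylum_map <- tibble(taxon = taxa, phylum = phyla)
  # worst-case taxon pool when only min_phyla - 1 phyla may be used
  phyla_fail_pool <- sum(sort(table(phyla))[seq_len(max(min_phyla - 1L, 1L))])
  fail_types <- c(if (paralog_rate > 0) "single_copy", "phyla", "species")
  if ("phyla" %in% fail_types && phyla_fail_pool < min_species) {
    fail_types <- setdiff(fail_types, "phyla")
  }
  withr::with_seed(seed, {
    n_pass <- round(pass_fraction * n_ogs)
    status <- sample(c(rep("pass", n_pass),
                       rep(fail_types, length.out = n_ogs - n_pass)))
    pick_taxa <- function(s, phyla_pool = unique(phyla)) {
      # guarantee >= min(min_phyla, |pool|) phyla, then fill at random
      first <- vapply(sample(phyla_pool, min(min_phyla, length(phyla_pool), s)),
                      function(ph) sample(rep(taxa[phyla == ph], 2L), 1L), "")
      rest <- setdiff(taxa[phyla %in% phyla_pool], first)
      c(first, sample(rest, s - length(first)))
    }
    rows <- vector("list", n_ogs)
    truth <- vector("list", n_ogs)
    for (i in seq_len(n_ogs)) {
      og <- sprintf("OG%04d", i)
      st <- status[i]
      if (st == "pass") {
        s <- sample(min_species:n_taxa, 1L)
        tx <- pick_taxa(s)
        m_max <- floor((s - 1L) / 9L)   # largest m with (s-m)/(s+m) > 0.8
        m <- min(rbinom(1L, s, paralog_rate), m_max)
      } else if (st == "single_copy") {
        s <- sample(min_species:n_taxa, 1L)
        tx <- pick_taxa(s)
        m <- ceiling(s / 9)             # forces fraction <= 0.8
      } else if (st == "phyla") {
        pool <- sample(unique(phyla), min_phyla - 1L)
        avail <- taxa[phyla %in% pool]
        s_range <- min_species:length(avail)
        s <- s_range[sample.int(length(s_range), 1L)]
        tx <- sample(avail, s)
        m <- min(rbinom(1L, s, paralog_rate), floor((s - 1L) / 9L))
      } else { # species
        s <- sample(min_phyla:(min_species - 1L), 1L)
        tx <- pick_taxa(s)
        m <- min(rbinom(1L, s, paralog_rate), floor((s - 1L) / 9L))
      }
      multi <- if (m > 0) sample(tx, m) else character()
      n_copy <- ifelse(tx %in% multi, 2L, 1L)
      rows[[i]] <- tibble(
        og_id = og,
        taxon = rep(tx, n_copy),
        protein_id = unlist(lapply(seq_along(tx), function(j) {
          sprintf("%s_%s_p%d", og, tx[j], seq_len(n_copy[j]))
        }))
      )
      frac <- (s - m) / (s + m)
      truth[[i]] <- tibble(
        og_id = og,
        pass = st == "pass",
        fail_criterion = if (st == "pass") NA_character_ else st,
        n_species = s,
        n_phyla = dplyr::n_distinct(phyla[match(tx, taxa)]),
        single_copy_fraction = frac
      )
    }
    table <- bind_rows(rows)
    attr(table, "taxa") <- taxa
    list(table = table, truth = bind_rows(truth), phylum_map = phylum_map)
  })
}

#' Simulate gapless per-orthogroup "alignments" for supermatrix tests
#'
#' Random equal-length amino-acid blocks per orthogroup for the taxa present
#' in `og_table` (one sequence per taxon; multi-copy taxa must be pruned
#' first). Not evolutionary sequences — just structurally valid aligned
#' input for [concatenate_supermatrix()].
#'
#' @inheritParams gen_orthogroups
#' @param og_table Long orthotable (single-copy; see [prune_multicopy()]).
#' @param len_range Integer range of per-orthogroup alignment lengths.
#' @return Tibble `og_id`, `taxon`, `seq`.
#' @export
gen_og_alignments <- function(seed, og_table, len_range = c(50L, 200L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  withr::with_seed(seed, {
    members <- distinct(og_table, .data$og_id, .data$taxon)
    lens <- tibble(og_id = unique(members$og_id),
                   len = sample(len_range[1L]:len_range[2L],
                                dplyr::n_distinct(members$og_id), replace = TRUE))
    members %>%
      left_join(lens, by = "og_id") %>%
      mutate(seq = vapply(.data$len, function(l) {
        paste(sample(aa, l, replace = TRUE), collapse = "")
      }, "")) %>%
      select("og_id", "taxon", "seq")
  })
}

#' Simulate a variant set under a haploid or diploid model
#'
#' Diploid mode treats every site as heterozygous: the alternate read count
#' is `Binomial(coverage, 0.5)`, putting about 89% of coverage-10 sites in
#' the 30-70% frequency band. Haploid mode mixes error-driven sites
#' (`Binomial(coverage, error_rate)`) with a fraction of fixed differences
#' at frequency near 1 (`coverage - Binomial(coverage, error_rate)`),
#' depleting the central band — the spectrum a haploid assembly yields.
#'
#' @inheritParams gen_orthogroups
#' @param n Number of variant records.
#' @param ploidy 1 or 2.
#' @param coverage Mean (or fixed) per-site read coverage.
#' @param coverage_dist `"fixed"` or `"poisson"` (truncated at 1).
#' @param error_rate Per-read error probability (must be < 0.5).
#' @param fixed_fraction Haploid mode: fraction of sites that are fixed
#'   differences rather than errors.
#' @param contig Contig name written on every record.
#' @return Variant tibble (`contig`, `pos`, `ref`, `alt`, `coverage`,
#'   `alt_count`, `quality` = `NA`).
#' @export
gen_variant_set <- function(seed, n = 10000L, ploidy = 2L, coverage = 10L,
                            coverage_dist = c("fixed", "poisson"),
                            error_rate = 0.01, fixed_fraction = 0.5,
                            contig = "tig00000001") {
  coverage_dist <- match.arg(coverage_dist)
  n <- check_scalar_count(n, "n", 1)
  if (!ploidy %in% c(1L, 2L)) abort("ploidy must be 1 or 2")
  if (error_rate >= 0.5) abort("error_rate must be < 0.5")
  if (coverage < 1) abort("coverage must be >= 1")
  withr::with_seed(seed, {
    cov <- switch(coverage_dist,
      fixed = rep(as.integer(coverage), n),
      poisson = pmax(1L, stats::rpois(n, coverage))
    )
    alt <- if (ploidy == 2L) {
      rbinom(n, cov, 0.5)
    } else {
      fixed <- runif(n) < fixed_fraction
      err <- rbinom(n, cov, error_rate)
      ifelse(fixed, cov - err, err)
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt_base <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
    alt_n <- as.integer(alt)
    tibble(
      contig = contig,
      pos = sort(sample.int(n * 50L, n)),
      ref = ref, alt = unname(alt_base),
      coverage = cov, alt_count = alt_n,
      quality = NA_real_
    )
  })
}
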