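phylum_map4 <- tibble::tibble(
  taxon = c("t1", "t2", "t3", "t4"),
  phylum = c("P1", "P2", "P3", "P4")
)

og_row <- function(og, ...) {
  members <- list(...)
  tibble::tibble(
    og_id = og,
    taxon = rep(names(members), lengths(members)),
    protein_id = unlist(members)
  )
}

test_that("og_stats counts species, phyla and the single-copy fraction", {
  og <- og_row("OG1", t1 = "p1", t2 = "p2", t3 = c("p3", "p4"))
  s <- og_stats(og, phylum_map4)
  expect_equal(s$n_species, 3L)
  expect_equal(s$n_phyla, 3L)
  expect_equal(s$single_copy_fraction, 0.5)

  all_single <- og_row("OG2", t1 = "a", t2 = "b", t3 = "c")
  expect_equal(og_stats(all_single, phylum_map4)$single_copy_fraction, 1.0)

  # 20 proteins, 16 from single-copy taxa: fraction exactly 0.80
  og20 <- tibble::tibble(
    og_id = "OG3",
    taxon = c(sprintf("t%d", 1:16), rep("u1", 2), rep("u2", 2)),
    protein_id = sprintf("p%d", 1:20)
  )
  pm <- tibble::tibble(taxon = unique(og20$taxon),
                       phylum = paste0("P", seq_along(unique(og20$taxon))))
  expect_equal(og_stats(og20, pm)$single_copy_fraction, 0.80)

  expect_error(og_stats(og_row("OGx", zz = "p"), phylum_map4), "zz")
})

test_that("filter_ogs applies strict > on paralogy and inclusive phylum/species minima", {
  # exactly 0.80 single-copy: rejected under the strict threshold
  og <- tibble::tibble(
    og_id = "OGb",
    taxon = c(sprintf("t%d", 1:16), rep("u1", 2), rep("u2", 2)),
    protein_id = sprintf("p%d", 1:20)
  )
  pm <- tibble::tibble(taxon = unique(og$taxon),
                       phylum = paste0("P", c(1:4, rep(4, length(unique(og$taxon)) - 4))))
  res <- filter_ogs(og, pm)
  expect_false(res$keep)
  expect_equal(res$reason, "single_copy")

  # 12 species, 5 phyla, fraction 11/13 > 0.8 -> kept
  og2 <- tibble::tibble(
    og_id = "OGk",
    taxon = c(sprintf("t%d", 1:11), rep("t12", 2)),
    protein_id = sprintf("q%d", 1:13)
  )
  pm2 <- tibble::tibble(taxon = sprintf("t%d", 1:12),
                        phylum = paste0("P", rep(1:5, length.out = 12)))
  res2 <- filter_ogs(og2, pm2)
  expect_true(res2$keep)
  expect_true(is.na(res2$reason))
})

test_that("filtering is monotone in every threshold", {
  sim <- gen_orthogroups(seed = 21, n_ogs = 80)
  base_kept <- dplyr::filter(filter_ogs(sim$table, sim$phylum_map), keep)$og_id
  looser <- dplyr::filter(
    filter_ogs(sim$table, sim$phylum_map, min_single_copy = 0.5,
               min_phyla = 2, min_species = 5), keep)$og_id
  tighter <- dplyr::filter(
    filter_ogs(sim$table, sim$phylum_map, min_single_copy = 0.9,
               min_phyla = 6, min_species = 15), keep)$og_id
  expect_true(all(base_kept %in% looser))
  expect_true(all(tighter %in% base_kept))
})

test_that("prune_multicopy removes multi-copy taxa, is idempotent, flags shrinkage", {
  og <- og_row("OG1", t1 = "p1", t2 = c("p2", "p3"))
  expect_warning(pr <- prune_multicopy(og), "below 10 species")
  expect_equal(unique(pr$taxon), "t1")
  expect_equal(attr(pr, "removed")$taxon, "t2")
  expect_equal(attr(pr, "flagged"), "OG1")
  expect_warning(pr2 <- prune_multicopy(pr), "below")
  expect_equal(tibble::as_tibble(pr2), tibble::as_tibble(pr),
               ignore_attr = TRUE)  # the report attributes describe each call

  sim <- gen_orthogroups(seed = 13, n_ogs = 40)
  kept <- dplyr::filter(filter_ogs(sim$table, sim$phylum_map), keep)$og_id
  sub <- sim$table[sim$table$og_id %in% kept, ]
  pruned <- suppressWarnings(prune_multicopy(sub))
  stats <- og_stats(pruned, sim$phylum_map)
  expect_true(all(stats$single_copy_fraction == 1))
})

test_that("supermatrix concatenation gap-fills, conserves length, and reports occupancy", {
  aln <- tibble::tibble(
    og_id = c(rep("OG1", 4), rep("OG2", 5)),
    taxon = c("t1", "t2", "t3", "t4", "t1", "t2", "t3", "t4", "t5"),
    seq = c(strrep("A", 100), strrep("C", 100), strrep("D", 100), strrep("E", 100),
            strrep("F", 50), strrep("G", 50), strrep("H", 50), strrep("I", 50),
            strrep("K", 50))
  )
  sm <- concatenate_supermatrix(aln, taxon_universe = sprintf("t%d", 1:5))
  expect_true(all(nchar(sm$sequences$seq) == 150L))
  t5 <- sm$sequences$seq[sm$sequences$taxon == "t5"]
  expect_equal(substr(t5, 1, 100), strrep("-", 100))
  expect_equal(substr(t5, 101, 150), strrep("K", 50))
  expect_equal(sm$blocks$start, c(1L, 101L))
  expect_equal(sm$blocks$end, c(100L, 150L))
  occ <- sm$occupancy$occupancy
  expect_true(all(occ >= 0 & occ <= 1))
  expect_equal(occ[sm$occupancy$taxon == "t5"], 50 / 150)
  expect_equal(sum(sm$blocks$end - sm$blocks$start + 1L), 150L)
  g <- glance(sm)
  expect_equal(g$total_length, 150L)

  # single OG: supermatrix is that alignment with one block
  sm1 <- concatenate_supermatrix(aln[aln$og_id == "OG1", ])
  expect_equal(nrow(sm1$blocks), 1L)
  expect_equal(sm1$sequences$seq[1], strrep("A", 100))

  ragged <- aln
  ragged$seq[1] <- "SHORT"
  expect_error(concatenate_supermatrix(ragged), "ragged alignment.*OG1")
})

test_that("block order canonicalization makes output independent of input order", {
  sim <- gen_orthogroups(seed = 31, n_ogs = 25)
  kept <- dplyr::filter(filter_ogs(sim$table, sim$phylum_map), keep)$og_id
  pruned <- suppressWarnings(prune_multicopy(sim$table[sim$table$og_id %in% kept, ]))
  aln <- gen_og_alignments(seed = 32, pruned)
  sm1 <- concatenate_supermatrix(aln, og_taxa(sim$table))
  shuffled <- withr::with_seed(1, aln[sample.int(nrow(aln)), ])
  sm2 <- concatenate_supermatrix(shuffled, og_taxa(sim$table))
  expect_identical(sm1$sequences, sm2$sequences)
  expect_identical(sm1$blocks, sm2$blocks)

  f1 <- withr::local_tempfile(fileext = ".fa")
  p1 <- withr::local_tempfile(fileext = ".part")
  write_supermatrix(sm1, f1, p1)
  expect_equal(nrow(read_fasta(f1)), length(og_taxa(sim$table)))
  parts <- read_partitions(p1)
  expect_equal(parts$name, sm1$blocks$name)
  expect_equal(parts$end, sm1$blocks$end)
})
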