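#' Simulate a gene tree with a planted chlamydial HGT signal
#'
#' Builds a support-labeled newick tree in which an Archaeplastida recipient
#' clade of chosen lineage composition sits sister to a chlamydial clade,
#' with the chosen bootstrap support on the recipient clade's edge. Decoy
#' bacterial and eukaryotic taxa are attached on a long branch elsewhere so
#' that midpoint rooting never breaks the planted clade. Categories:
#'
#' * `all_archaeplastida` — glaucophyte, red and green leaves in the clade;
#' * `green_shared` — glaucophyte + green only;
#' * `red_shared` — glaucophyte + red only;
#' * `glaucophyte_specific` — >= 2 glaucophytes only, gene flagged as
#'   intron-containing;
#' * `other` — a pattern that must not be called a chlamydial HGT class:
#'   either a glaucophyte pair without introns, a glaucophyte clade sister
#'   to non-chlamydial bacteria, or a single glaucophyte leaf.
#'
#' @inheritParams gen_orthogroups
#' @param category Planted sharing category (see above).
#' @param support Bootstrap support planted on the recipient clade's edge.
#' @param n_glauco,n_rhodo,n_virid,n_chlam Leaf counts per lineage (rhodo /
#'   virid counts are ignored where the category excludes the lineage).
#' @param n_decoy Number of decoy (`other_bacteria` / `other_eukaryote`)
#'   leaves.
#' @param tree_id Identifier used in the truth row.
#' @return List with `tree` (`phylo`), `lineage_map` (tibble `leaf`,
#'   `lineage`) and `truth` (one-row tibble: `tree_id`, `category`,
#'   `support`, `donor`, `n_glauco`, `has_introns`).
#' @export
gen_hgt_tree <- function(seed, category = c("all_archaeplastida", "green_shared",
                                            "red_shared", "glaucophyte_specific",
                                            "other"),
                         support = 98, n_glauco = 2L, n_rhodo = 2L,
                         n_virid = 2L, n_chlam = 3L, n_decoy = 4L,
                         tree_id = "tree") {
  category <- match.arg(category)
  if (support < 0 || support > 100) abort("support must be in [0, 100]")
  if (n_glauco < 1L) abort("need at least one glaucophyte leaf")
  if (category == "all_archaeplastida" && (n_rhodo < 1L || n_virid < 1L)) {
    abort("all_archaeplastida requires red and green leaves")
  }
  if (category == "green_shared" && n_virid < 1L) {
    abort("green_shared requires green leaves")
  }
  if (category == "red_shared" && n_rhodo < 1L) {
    abort("red_shared requires red leaves")
  }
  if (category == "glaucophyte_specific" && n_glauco < 2L) {
    abort("glaucophyte_specific requires >= 2 glaucophyte species")
  }
  if (n_chlam < 1L || n_decoy < 2L) {
    abort("need >= 1 chlamydial and >= 2 decoy leaves")
  }
  withr::with_seed(seed, {
    other_subtype <- sample(c("no_introns", "bacterial_donor", "single_glauco"), 1L)
    rec <- switch(category,
      all_archaeplastida = c(rep("Glaucophyta", n_glauco),
                             rep("Rhodophyta", n_rhodo),
                             rep("Viridiplantae", n_virid)),
      green_shared = c(rep("Glaucophyta", n_glauco), rep("Viridiplantae", n_virid)),
      red_shared = c(rep("Glaucophyta", n_glauco), rep("Rhodophyta", n_rhodo)),
      glaucophyte_specific = rep("Glaucophyta", n_glauco),
      other = switch(other_subtype,
        no_introns = rep("Glaucophyta", max(2L, n_glauco)),
        bacterial_donor = rep("Glaucophyta", max(2L, n_glauco)),
        single_glauco = "Glaucophyta")
    )
    has_introns <- switch(category,
      glaucophyte_specific = TRUE,
      other = other_subtype == "single_glauco",  # introns alone must not rescue it
      sample(c(TRUE, FALSE), 1L))
    donor_lineage <- if (category == "other" && other_subtype == "bacterial_donor") {
      "other_bacteria"
    } else {
      "Chlamydiae"
    }
    mk <- function(lins) {
      counts <- table(lins)
      unlist(lapply(names(counts), function(l) {
        sprintf("%s_%d", l, seq_len(counts[[l]]))
      }))
    }
    rec_tips <- mk(rec)
    don_tips <- sprintf("%s_don%d", donor_lineage, seq_len(n_chlam))
    decoy_lin <- sample(c("other_bacteria", "other_eukaryote"), n_decoy,
                        replace = TRUE)
    decoy_tips <- sprintf("%s_x%d", decoy_lin, seq_along(decoy_lin))
    bl <- function(n) stats::runif(n, 0.05, 0.2)
    leafstr <- function(tips) paste(sprintf("%s:%.4f", tips, bl(length(tips))),
                                    collapse = ",")
    rec_str <- if (length(rec_tips) > 1L) {
      sprintf("(%s)%g:%.4f", leafstr(rec_tips), support, bl(1))
    } else {
      sprintf("%s:%.4f", rec_tips, bl(1))
    }
    don_str <- sprintf("(%s)%d:%.4f", leafstr(don_tips),
                       sample(85:100, 1L), bl(1))
    core <- sprintf("(%s,%s)%d:%.4f", rec_str, don_str, sample(70:100, 1L), bl(1))
    decoys <- sprintf("(%s)%d:%.4f", leafstr(decoy_tips), sample(50:90, 1L), 3.0)
    tree <- parse_newick(sprintf("(%s,%s);", core, decoys))
    lineage_map <- tibble(
      leaf = c(rec_tips, don_tips, decoy_tips),
      lineage = c(rec, rep(donor_lineage, n_chlam), decoy_lin)
    )
    truth <- tibble(
      tree_id = tree_id, category = category,
      support = if (length(rec_tips) > 1L) support else NA_real_,
      donor = donor_lineage, n_glauco = sum(rec == "Glaucophyta"),
      has_introns = has_introns
    )
    list(tree = tree, lineage_map = lineage_map, truth = truth)
  })
}

#' Simulate a batch of planted HGT gene trees
#'
#' @inheritParams gen_hgt_tree
#' @param categories Character vector of planted categories, one per tree
#'   (e.g. `rep(c("all_archaeplastida", "glaucophyte_specific"), c(17, 10))`).
#' @param supports Numeric vector recycled over trees.
#' @return List with `trees` (named list of `phylo`), `lineage_map` (one
#'   tibble covering every tree, with a `tree_id` column) and `truth`
#'   (tibble, one row per tree).
#' @export
gen_hgt_batch <- function(seed, categories, supports = 98) {
  supports <- rep(supports, length.out = length(categories))
  ids <- sprintf("tree%03d", seq_along(categories))
  sims <- lapply(seq_along(categories), function(i) {
    gen_hgt_tree(seed = as.integer((as.numeric(seed) * 1009 + i) %% 2147483647),
                 category = categories[i], support = supports[i],
                 tree_id = ids[i])
  })
  trees <- setNames(lapply(sims, `[[`, "tree"), ids)
  lineage_map <- purrr::map_dfr(sims, "lineage_map") %>%
    distinct(.data$leaf, .data$lineage)
  list(trees = trees, lineage_map = lineage_map,
       truth = purrr::map_dfr(sims, "truth"))
}
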