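#' Bipartition (unrooted) monophyly test
#'
#' Tests whether some edge of the tree separates exactly `leaf_set` from the
#' remaining leaves — the rooting-independent notion of monophyly — and
#' returns the support attached to that edge. Singleton sets and the full
#' leaf set are trivially monophyletic (support absent).
#'
#' @param tree A `phylo` tree with supports as internal node labels.
#' @param leaf_set Character vector of leaf names.
#' @return A list with `monophyletic` (logical) and `support` (numeric or
#'   `NA` when the defining edge is unlabeled or the test fails).
#' @export
#' @examples
#' check_monophyly(parse_newick("((A,B)95,(C,D)80);"), c("A", "B"))
check_monophyly <- function(tree, leaf_set) {
  if (!length(leaf_set)) abort("leaf_set is empty")
  unknown <- setdiff(leaf_set, tree$tip.label)
  if (length(unknown)) {
    abort(sprintf("unknown leaf name(s): %s", paste(unknown, collapse = ", ")))
  }
  n_tip <- length(tree$tip.label)
  idx <- sort(match(leaf_set, tree$tip.label))
  if (length(idx) %in% c(1L, n_tip)) {
    return(list(monophyletic = TRUE, support = NA_real_))
  }
  pp <- ape::prop.part(tree)
  sup <- support_values(tree)
  comp <- sort(setdiff(seq_len(n_tip), idx))
  for (i in seq_along(pp)) {
    part <- pp[[i]]
    if (identical(sort(part), idx) || identical(sort(part), comp)) {
      return(list(monophyletic = TRUE, support = sup[i]))
    }
  }
  list(monophyletic = FALSE, support = NA_real_)
}

#' Classify a bootstrap support value
#'
#' @param support_value Numeric support in \[0, 100\] or `NA`.
#' @param well_min Minimum support for `well_supported`.
#' @param weak_min Minimum support for `weakly_supported`.
#' @return `"well_supported"`, `"weakly_supported"` or `"none"`.
#' @export
classify_support <- function(support_value, well_min = 90, weak_min = 60) {
  dplyr::case_when(
    is.na(support_value) ~ "none",
    support_value >= well_min ~ "well_supported",
    support_value >= weak_min ~ "weakly_supported",
    TRUE ~ "none"
  )
}

validate_lineage_map <- function(tree, lineage_map) {
  stopifnot(all(c("leaf", "lineage") %in% names(lineage_map)))
  missing <- setdiff(tree$tip.label, lineage_map$leaf)
  if (length(missing)) {
    abort(sprintf("leaves missing from lineage_map: %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(lineage_map$lineage), LINEAGES)
  if (length(bad)) {
    abort(sprintf("unknown lineage label(s): %s", paste(bad, collapse = ", ")))
  }
  setNames(lineage_map$lineage, lineage_map$leaf)
}

clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Minimal clade spanning the recipient leaves, and its sister group
#'
#' Midpoint-roots the tree (deterministic, no outgroup needed; unit branch
#' lengths are assumed when none are present) and finds the smallest clade
#' containing every leaf whose lineage is in `recipient_lineages`. Reports
#' the clade's members, any non-recipient intruders inside it, the sister
#' group's lineage composition and the support of the edge subtending the
#' clade.
#'
#' @param tree A `phylo` support tree.
#' @param lineage_map Tibble with columns `leaf`, `lineage` covering every
#'   leaf; lineages are one of `Chlamydiae`, `Glaucophyta`, `Rhodophyta`,
#'   `Viridiplantae`, `other_bacteria`, `other_eukaryote`.
#' @param recipient_lineages Lineages defining the recipient group
#'   (default: the three Archaeplastida lineages).
#' @return List: `clade_tips`, `intruders`, `sister_tips`,
#'   `sister_lineages`, `support`, `spans_root` (`TRUE` when the recipients
#'   straddle every deep edge so no proper spanning clade exists).
#' @export
recipient_clade <- function(tree, lineage_map,
                            recipient_lineages = ARCHAEPLASTIDA) {
  lin <- validate_lineage_map(tree, lineage_map)
  rec <- tree$tip.label[lin[tree$tip.label] %in% recipient_lineages]
  if (!length(rec)) abort("no recipient leaves in tree")
  rt <- tree
  if (is.null(rt$edge.length)) rt$edge.length <- rep(1, nrow(rt$edge))
  rt <- phangorn::midpoint(rt, node.labels = "support")
  n_tip <- length(rt$tip.label)
  node <- if (length(rec) == 1L) match(rec, rt$tip.label) else
    ape::getMRCA(rt, rec)
  root <- n_tip + 1L
  if (node == root) {
    return(list(clade_tips = rt$tip.label,
                intruders = setdiff(rt$tip.label, rec),
                sister_tips = character(), sister_lineages = character(),
                support = NA_real_, spans_root = TRUE, tree_rooted = rt))
  }
  ct <- clade_tips(rt, node)
  parent <- rt$edge[rt$edge[, 2L] == node, 1L]
  sibs <- setdiff(rt$edge[rt$edge[, 1L] == parent, 2L], node)
  sister <- unlist(lapply(sibs, clade_tips, tree = rt))
  sup <- if (node > n_tip) support_values(rt)[node - n_tip] else NA_real_
  list(clade_tips = ct, intruders = setdiff(ct, rec),
       sister_tips = sister,
       sister_lineages = unname(lin[sister]),
       support = sup, spans_root = FALSE, tree_rooted = rt)
}

# nested-placement check: is there an ancestor of the recipient clade all of
# whose additional leaves are chlamydial?
nested_in_chlamydiae <- function(rt, clade, lin) {
  n_tip <- length(rt$tip.label)
  node <- if (length(clade) == 1L) match(clade, rt$tip.label) else
    ape::getMRCA(rt, clade)
  root <- n_tip + 1L
  while (node != root) {
    node <- rt$edge[rt$edge[, 2L] == node, 1L]
    extra <- setdiff(clade_tips(rt, node), clade)
    if (!length(extra)) next
    if (all(lin[extra] == "Chlamydiae")) return(TRUE)
    return(FALSE)
  }
  FALSE
}

#' Lineage-sharing category of a chlamydial HGT candidate
#'
#' Applies the sharing rubric to the lineages found inside the recipient
#' clade: glaucophytes plus both red and green algae is an
#' all-Archaeplastida transfer; glaucophytes plus only green
#' (`green_shared`) or only red (`red_shared`) algae indicate transfers
#' shared with one lineage; a purely glaucophyte clade qualifies as
#' `glaucophyte_specific` only when it holds at least 2 glaucophyte species
#' forming a monophyletic clade in a gene containing introns; anything else
#' is `other`.
#'
#' @inheritParams recipient_clade
#' @param has_introns Logical: does the recipient gene contain spliceosomal
#'   introns (a per-gene flag derived upstream from the gene models)?
#' @return A single string, one of `all_archaeplastida`, `green_shared`,
#'   `red_shared`, `glaucophyte_specific`, `other`.
#' @export
sharing_category <- function(tree, lineage_map, has_introns = FALSE,
                             recipient_lineages = ARCHAEPLASTIDA) {
  lin <- validate_lineage_map(tree, lineage_map)
  rc <- recipient_clade(tree, lineage_map, recipient_lineages)
  sharing_from_clade(tree, rc, lin, has_introns)
}

sharing_from_clade <- function(tree, rc, lin, has_introns) {
  inside <- sort(unique(unname(lin[rc$clade_tips])))
  glauco <- rc$clade_tips[lin[rc$clade_tips] == "Glaucophyta"]
  if (setequal(inside, c("Glaucophyta", "Rhodophyta", "Viridiplantae"))) {
    "all_archaeplastida"
  } else if (setequal(inside, c("Glaucophyta", "Viridiplantae"))) {
    "green_shared"
  } else if (setequal(inside, c("Glaucophyta", "Rhodophyta"))) {
    "red_shared"
  } else if (identical(inside, "Glaucophyta")) {
    mono <- length(glauco) >= 2L &&
      check_monophyly(tree, glauco)$monophyletic && isTRUE(has_introns)
    if (mono) "glaucophyte_specific" else "other"
  } else {
    "other"
  }
}

#' Classify one gene tree for chlamydial HGT
#'
#' Deterministic composition of the clade, donor, support and sharing rules:
#' finds the recipient (Archaeplastida) clade, reads the donor from its
#' sister group (or from a nested placement inside a chlamydial clade),
#' classes the subtending support, and applies the lineage-sharing rubric.
#' The full audit trail (sister composition, intruders, placement) is kept
#' in the returned row.
#'
#' @inheritParams sharing_category
#' @param tree_id Identifier carried into the output.
#' @param well_min,weak_min Support-class thresholds (see
#'   [classify_support()]).
#' @return One-row tibble: `tree_id`, `donor` (`"Chlamydiae"`, another
#'   lineage, or `"none"`), `placement` (`"sister"`, `"nested"` or `NA`),
#'   `support_value`, `support_class`, `sharing`, `glauco_monophyletic`,
#'   `n_glauco_species`, `has_introns`, `n_intruders`, `sister_composition`.
#' @export
classify_tree <- function(tree, lineage_map, has_introns = FALSE,
                          tree_id = "tree", well_min = 90, weak_min = 60,
                          recipient_lineages = ARCHAEPLASTIDA) {
  lin <- validate_lineage_map(tree, lineage_map)
  rc <- recipient_clade(tree, lineage_map, recipient_lineages)
  glauco <- rc$clade_tips[lin[rc$clade_tips] == "Glaucophyta"]
  glauco_mono <- length(glauco) >= 1L &&
    check_monophyly(tree, glauco)$monophyletic
  donor <- "none"; placement <- NA_character_
  if (!rc$spans_root && length(rc$sister_lineages)) {
    sis <- unique(rc$sister_lineages)
    if (identical(sis, "Chlamydiae")) {
      donor <- "Chlamydiae"; placement <- "sister"
    } else if (nested_in_chlamydiae(rc$tree_rooted, rc$clade_tips, lin)) {
      donor <- "Chlamydiae"; placement <- "nested"
    } else if (length(sis) == 1L) {
      donor <- sis; placement <- "sister"
    }
  }
  sharing <- if (identical(donor, "Chlamydiae")) {
    sharing_from_clade(tree, rc, lin, has_introns)
  } else {
    "other"
  }
  tibble(
    tree_id = tree_id,
    donor = donor,
    placement = placement,
    support_value = rc$support,
    support_class = classify_support(rc$support, well_min, weak_min),
    sharing = sharing,
    glauco_monophyletic = glauco_mono,
    n_glauco_species = length(glauco),
    has_introns = isTRUE(has_introns),
    n_intruders = length(rc$intruders),
    sister_composition = paste(sort(unique(rc$sister_lineages)), collapse = "+")
  )
}

#' Classify a batch of gene trees
#'
#' @param trees A named list of `phylo` trees (or a `multiPhylo`).
#' @param lineage_map Tibble `leaf`, `lineage` covering every leaf of every
#'   tree.
#' @param introns Either a single logical recycled to all trees, or a tibble
#'   with columns `tree_id`, `has_introns`.
#' @inheritParams classify_tree
#' @return Tibble with one [classify_tree()] row per tree. Category counts
#'   over the batch always sum to the number of trees.
#' @export
classify_trees <- function(trees, lineage_map, introns = FALSE,
                           well_min = 90, weak_min = 60,
                           recipient_lineages = ARCHAEPLASTIDA) {
  ids <- names(trees) %||% sprintf("tree%03d", seq_along(trees))
  if (is.data.frame(introns)) {
    flag <- setNames(introns$has_introns, introns$tree_id)[ids]
    flag[is.na(flag)] <- FALSE
  } else {
    flag <- rep(as.logical(introns), length.out = length(trees))
  }
  purrr::map_dfr(seq_along(trees), function(i) {
    lm <- lineage_map[lineage_map$leaf %in% trees[[i]]$tip.label, ]
    classify_tree(trees[[i]], lm, has_introns = flag[[i]], tree_id = ids[i],
                  well_min = well_min, weak_min = weak_min,
                  recipient_lineages = recipient_lineages)
  })
}
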