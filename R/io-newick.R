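#' Parse a newick string with node supports
#'
#' Parses newick text in the dialect emitted by common maximum-likelihood
#' programs: bootstrap supports stored as internal-node labels, numeric in
#' \[0, 100\]. Branch lengths are retained; unlabeled internal nodes carry an
#' absent (`NA`) support. Parsing then serializing preserves topology and
#' supports.
#'
#' @param text A single newick string (must end with `;`).
#' @return An [ape::read.tree()] `phylo` object whose `node.label` holds
#'   supports (`""` preserved as `NA` via `support_values()`).
#' @seealso [read_support_tree()], [write_support_tree()], [support_values()]
#' @export
#' @examples
#' tr <- parse_newick("((A,B)95,(C,D)80);")
#' support_values(tr)
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";\\s*$", text)) abort("newick text must terminate with ';'")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    abort(sprintf("unbalanced parentheses: %d '(' vs %d ')'", n_open, n_close))
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) abort(sprintf("newick parse error: %s",
                                                   conditionMessage(e))))
  if (is.null(tr)) abort("newick parse error: not a valid tree")
  if (anyDuplicated(tr$tip.label)) {
    abort(sprintf("duplicate leaf name(s): %s",
                  paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                        collapse = ", ")))
  }
  sup <- support_values(tr)
  bad <- !is.na(sup) & (sup < 0 | sup > 100)
  if (any(bad)) {
    abort(sprintf("node support(s) outside [0, 100]: %s",
                  paste(sup[bad], collapse = ", ")))
  }
  tr
}

#' Numeric support values of a support tree
#'
#' @param tree A `phylo` object.
#' @return Numeric vector of length `tree$Nnode`; `NA` where the internal
#'   node carries no (or a non-numeric) label.
#' @export
support_values <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Read / write newick support trees
#'
#' @param path File path; files may hold one tree per line.
#' @return `read_support_tree()`: a `phylo` (single tree) or `multiPhylo`
#'   (several); `write_support_tree()`: `path`, invisibly.
#' @rdname support_tree_io
#' @export
read_support_tree <- function(path) {
  if (!file.exists(path)) abort(sprintf("tree file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  trees <- lapply(lines, parse_newick)
  if (length(trees) == 1L) trees[[1L]] else structure(trees, class = "multiPhylo")
}

#' @param tree A `phylo` object (supports as node labels).
#' @rdname support_tree_io
#' @export
write_support_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
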