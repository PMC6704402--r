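# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use naive position-by-position algorithms, not the
# package's vectorized code paths.

brute_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# position-by-position six-frame ORF scan
brute_orfs <- function(seq, min_aa, mode = "atg_to_stop") {
  stops <- c("TAA", "TAG", "TGA")
  out <- list()
  L <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else brute_revcomp(seq)
    for (frame in 0:2) {
      codon_at <- function(i) substr(s, i + 1, i + 3)  # i is 0-based nt pos
      i <- frame
      anchors <- integer()
      while (i + 3 <= L) {
        cd <- codon_at(i)
        is_anchor <- if (mode == "atg_to_stop") {
          # an ATG with no in-frame ATG-since-last-stop before it
          ok <- cd == "ATG"
          if (ok) {
            j <- i - 3
            while (j >= frame) {
              cj <- codon_at(j)
              if (cj %in% stops) break
              if (cj == "ATG") { ok <- FALSE; break }
              j <- j - 3
            }
          }
          ok
        } else {
          # first codon after a stop (or the frame start)
          i == frame || codon_at(i - 3) %in% stops
        }
        if (is_anchor && !(cd %in% stops)) anchors <- c(anchors, i)
        i <- i + 3
      }
      for (a in anchors) {
        j <- a
        while (j + 3 <= L && !(codon_at(j) %in% stops)) j <- j + 3
        stopped <- j + 3 <= L
        aa <- (j - a) / 3
        if (aa < min_aa) next
        nt0 <- a
        nt1 <- j + (if (stopped) 3 else 0)
        if (strand == "+") {
          st <- nt0; en <- nt1
        } else {
          st <- L - nt1; en <- L - nt0
        }
        out[[length(out) + 1]] <- data.frame(
          strand = strand, frame = frame, start = st, end = en,
          aa_len = aa, truncated = !stopped
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(), frame = integer(),
                      start = integer(), end = integer(),
                      aa_len = integer(), truncated = logical()))
  }
  df <- do.call(rbind, out)
  df[order(df$strand, df$frame, df$start), ]
}

# brute-force bipartition enumeration: a leaf set is monophyletic (unrooted
# sense) iff removing some edge splits the leaves into exactly that set and
# its complement; components found by breadth-first search
brute_monophyletic <- function(tree, leaf_set) {
  n_tip <- length(tree$tip.label)
  if (length(leaf_set) %in% c(1L, n_tip)) return(TRUE)
  target <- sort(match(leaf_set, tree$tip.label))
  edges <- tree$edge
  nodes <- sort(unique(as.vector(edges)))
  for (drop in seq_len(nrow(edges))) {
    adj <- edges[-drop, , drop = FALSE]
    # BFS from one endpoint of the dropped edge
    comp <- edges[drop, 1]
    seen <- comp
    repeat {
      nxt <- unique(c(adj[adj[, 1] %in% seen, 2], adj[adj[, 2] %in% seen, 1]))
      nxt <- setdiff(nxt, seen)
      if (!length(nxt)) break
      seen <- c(seen, nxt)
    }
    side <- sort(intersect(seen, seq_len(n_tip)))
    other <- sort(setdiff(seq_len(n_tip), side))
    if (identical(side, target) || identical(other, target)) return(TRUE)
  }
  FALSE
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
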