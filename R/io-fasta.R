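#' Read a FASTA file into a tibble
#'
#' Thin, strict wrapper around [Biostrings::readBStringSet()]. Sequences are
#' uppercased, record order is preserved and line wrapping is ignored. The
#' reader rejects rather than repairs malformed input: duplicate record ids
#' and empty sequences are hard errors.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of `"nucleotide"` (characters `ACGTN` only),
#'   `"protein"` (IUPAC amino-acid one-letter codes plus `*` and `-`), or
#'   `"any"` (no alphabet check). Alignment gaps (`-`) are accepted for both.
#' @return A tibble with columns `id` (character, unique) and `seq`
#'   (character, upper case).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b", "GG"), f)
#' read_fasta(f)
read_fasta <- function(path, alphabet = c("any", "nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence for record(s): %s",
                  paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  ok_chars <- switch(alphabet,
    nucleotide = "^[ACGTN-]+$",
    protein    = "^[ACDEFGHIKLMNPQRSTVWYXBZJUO*-]+$",
    any        = NULL
  )
  if (!is.null(ok_chars)) {
    bad <- !grepl(ok_chars, seqs)
    if (any(bad)) {
      abort(sprintf("sequence(s) outside %s alphabet: %s", alphabet,
                    paste(ids[bad], collapse = ", ")))
    }
  }
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write a tibble of sequences to FASTA
#'
#' @param seqs Tibble with columns `id` and `seq` (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  if (anyDuplicated(seqs$id)) abort("duplicate ids in `seqs`")
  ss <- Biostrings::BStringSet(setNames(seqs$seq, seqs$id))
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}
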