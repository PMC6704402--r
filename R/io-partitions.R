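#' Write a RAxML-style partition file
#'
#' One line per alignment block, `MODEL, name = start-end`, with 1-based
#' inclusive coordinates. Blocks must tile the supermatrix exactly: ascending,
#' non-overlapping and with no gaps.
#'
#' @param blocks Tibble with columns `name`, `start`, `end` (1-based
#'   inclusive).
#' @param path Output path.
#' @param model Substitution model string written for every block
#'   (placeholder; model choice is delegated to the ML program).
#' @return `path`, invisibly.
#' @export
#' @examples
#' f <- tempfile()
#' write_partitions(tibble::tibble(name = c("OG1", "OG2"),
#'                                 start = c(1, 251), end = c(250, 300)), f)
#' readLines(f)
write_partitions <- function(blocks, path, model = "AUTO") {
  stopifnot(all(c("name", "start", "end") %in% names(blocks)))
  if (nrow(blocks) == 0L) abort("no blocks to write")
  if (any(blocks$end < blocks$start)) abort("block end before start")
  if (blocks$start[1L] != 1L) abort("first block must start at 1")
  if (nrow(blocks) > 1L) {
    gap <- blocks$start[-1L] - blocks$end[-nrow(blocks)]
    bad <- which(gap != 1L)
    if (length(bad)) {
      abort(sprintf("blocks must be contiguous and ascending; gap/overlap after block '%s'",
                    blocks$name[bad[1L]]))
    }
  }
  writeLines(sprintf("%s, %s = %d-%d", model, blocks$name,
                     as.integer(blocks$start), as.integer(blocks$end)), path)
  invisible(path)
}

#' Read a RAxML-style partition file
#'
#' @param path Partition file written by [write_partitions()].
#' @return Tibble with columns `model`, `name`, `start`, `end`.
#' @export
read_partitions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec(
    "^\\s*([^,]+?)\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", lines))
  bad <- which(lengths(m) != 5L)
  if (length(bad)) abort(sprintf("malformed partition line %d", bad[1L]))
  tibble(
    model = vapply(m, `[[`, "", 2L),
    name  = vapply(m, `[[`, "", 3L),
    start = as.integer(vapply(m, `[[`, "", 4L)),
    end   = as.integer(vapply(m, `[[`, "", 5L))
  )
}
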