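#' Read a minimal VCF into a variant tibble
#'
#' Strict minimal-subset reader for the ploidy diagnostic: only `CHROM`,
#' `POS`, `REF`, `ALT`, `QUAL` and per-site depths are used. Depth is taken
#' from the INFO field: total coverage from `DP`, alternate read count from
#' `AO` (alternate observations) or, failing that, from the second value of
#' an `AD` ref,alt pair. All other fields are ignored and never required.
#' `POS` stays 1-based, unchanged.
#'
#' @param path Path to a VCF (v4.x) file.
#' @return Tibble with columns `contig`, `pos` (1-based), `ref`, `alt`
#'   (single bases), `coverage`, `alt_count`, `quality` (`NA` when the QUAL
#'   column is `.`).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  ao <- suppressWarnings(as.integer(vcfR::extract.info(v, "AO")))
  if (all(is.na(ao))) {
    ad <- vcfR::extract.info(v, "AD")
    ao <- suppressWarnings(as.integer(sub("^[^,]*,", "", ad)))
  }
  out <- tibble(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    coverage = dp,
    alt_count = ao,
    quality = suppressWarnings(as.numeric(fix$QUAL))
  )
  validate_variants(out)
  out
}

validate_variants <- function(x) {
  stopifnot(all(c("contig", "pos", "ref", "alt", "coverage", "alt_count")
                %in% names(x)))
  if (any(is.na(x$coverage)) || any(is.na(x$alt_count))) {
    abort("missing DP/AO (or AD) depth field on some record(s)")
  }
  if (any(x$coverage < 1L)) abort("coverage must be >= 1 on every record")
  if (any(x$alt_count < 0L | x$alt_count > x$coverage)) {
    abort("alt_count must satisfy 0 <= alt_count <= coverage")
  }
  if (any(nchar(x$ref) != 1L) || any(nchar(x$alt) != 1L)) {
    abort("only single-base REF/ALT records are supported")
  }
  invisible(x)
}

#' Write a variant tibble as minimal VCF
#'
#' Inverse of [read_vcf()]; depths are written as `DP`/`AO` INFO keys.
#'
#' @param variants Tibble as returned by [read_vcf()] or [gen_variant_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  validate_variants(variants)
  qual <- variants$quality %||% rep(NA_real_, nrow(variants))
  if (!"quality" %in% names(variants)) qual <- rep(NA_real_, nrow(variants))
  else qual <- variants$quality
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AO,Number=1,Type=Integer,Description=\"Alternate observation count\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\tDP=%d;AO=%d",
                  variants$contig, as.integer(variants$pos),
                  variants$ref, variants$alt,
                  ifelse(is.na(qual), ".", format(qual, trim = TRUE)),
                  as.integer(variants$coverage), as.integer(variants$alt_count))
  writeLines(c(header, body), path)
  invisible(path)
}
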