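#' Normalize variant representations to a canonical parsimonious form
#'
#' Reduces each (chrom, pos, ref, alt) tuple to its left-aligned,
#' parsimonious spelling without consulting a reference genome: shared
#' trailing bases are trimmed, then shared leading bases are trimmed (the
#' position advances) as long as both alleles keep at least one base. For
#' indels this leaves the single shared leading base that VCF uses as the
#' anchor. Two spellings of the same genomic change normalize to equal keys,
#' so the result is the join key used throughout the package.
#'
#' Normalization is idempotent and deterministic. Full reference-aware
#' left-alignment across repeat tracts is out of scope; trimming is purely
#' allele-based.
#'
#' @param calls Data frame with at least `chrom`, `pos` (1-based), `ref`,
#'   `alt` columns. `ref`/`alt` must be non-empty A/C/G/T strings and a row
#'   must not have `ref == alt` after trimming. Multiallelic records must
#'   already be split (one alt per row).
#' @param chr_policy How to harmonize contig names before comparison:
#'   `"strip"` (default) removes a leading `"chr"`, `"add"` prepends it,
#'   `"asis"` leaves names untouched.
#' @return The input tibble with `chrom`, `pos`, `ref`, `alt` replaced by
#'   their normalized values (other columns untouched, row order preserved).
#' @examples
#' normalize_variants(data.frame(chrom = "1", pos = 100, ref = "CAA", alt = "CA"))
#' @export
normalize_variants <- function(calls, chr_policy = c("strip", "add", "asis")) {
  chr_policy <- match.arg(chr_policy)
  calls <- as_tibble(calls)
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(calls))
  if (length(miss) > 0) {
    .stop_format(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(calls) == 0) return(calls)

  chrom <- apply_chr_policy(as.character(calls$chrom), chr_policy)
  pos <- as.integer(calls$pos)
  ref <- toupper(as.character(calls$ref))
  alt <- toupper(as.character(calls$alt))

  bad <- !grepl("^[ACGT]+$", ref) | !grepl("^[ACGT]+$", alt) |
    is.na(pos) | pos < 1L
  if (any(bad)) {
    i <- which(bad)[1]
    .stop_variant(sprintf(
      "invalid variant at row %d: %s:%s %s>%s (alleles must be non-empty ACGT, pos >= 1)",
      i, calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i]
    ))
  }

  trimmed <- trim_alleles(pos, ref, alt)
  same <- trimmed$ref == trimmed$alt
  if (any(same)) {
    i <- which(same)[1]
    .stop_variant(sprintf(
      "invalid variant at row %d: %s:%s %s>%s (ref equals alt after trimming)",
      i, calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i]
    ))
  }
  calls$chrom <- chrom
  calls$pos <- trimmed$pos
  calls$ref <- trimmed$ref
  calls$alt <- trimmed$alt
  calls
}

#' Normalize a single variant
#'
#' Scalar convenience wrapper around [normalize_variants()].
#'
#' @param chrom Chromosome name.
#' @param pos 1-based position of the first `ref` base.
#' @param ref,alt Reference and alternate alleles (non-empty ACGT strings).
#' @inheritParams normalize_variants
#' @return A one-row tibble with the normalized `chrom`, `pos`, `ref`, `alt`.
#' @examples
#' normalize_variant("1", 100, "AT", "GT")
#' @export
normalize_variant <- function(chrom, pos, ref, alt, chr_policy = "strip") {
  normalize_variants(
    tibble(chrom = chrom, pos = pos, ref = ref, alt = alt),
    chr_policy = chr_policy
  )
}

#' Build a string key identifying a normalized variant
#'
#' @param calls Data frame with `chrom`, `pos`, `ref`, `alt` columns
#'   (assumed already normalized).
#' @return Character vector `"chrom:pos:ref:alt"`, one element per row.
#' @export
variant_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

apply_chr_policy <- function(chrom, policy) {
  switch(policy,
    strip = sub("^chr", "", chrom),
    add = if_else(grepl("^chr", chrom), chrom, paste0("chr", chrom)),
    asis = chrom
  )
}

# Vectorized stepwise trimming; allele lengths are small so the while loops
# run at most a handful of iterations over the whole vector.
trim_alleles <- function(pos, ref, alt) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    can <- nr > 1L & na > 1L &
      substr(ref, nr, nr) == substr(alt, na, na)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 1L, nchar(ref[can]) - 1L)
    alt[can] <- substr(alt[can], 1L, nchar(alt[can]) - 1L)
  }
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    can <- nr > 1L & na > 1L &
      substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 2L, nchar(ref[can]))
    alt[can] <- substr(alt[can], 2L, nchar(alt[can]))
    pos[can] <- pos[can] + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}
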