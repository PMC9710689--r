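#' Read tumor (or normal) variant calls from VCF or TSV
#'
#' Parses caller output into the package's canonical call table and
#' normalizes every record with [normalize_variants()]. Multiallelic VCF
#' records are split into one row per alternate allele. The VAF fallback
#' chain is: explicit per-sample `AF` FORMAT field, then `AD`-derived
#' (`alt_depth / total_depth`), then a `vaf` TSV column; when an explicit AF
#' and the AD-derived value disagree by more than 0.01 a warning is emitted
#' and the explicit field wins. A record with zero depth and no AF is kept
#' with `vaf = NA` (it can never pass phase 1).
#'
#' @param path Path to a `.vcf` (optionally bgzipped) or tab-delimited file.
#' @param format `"auto"` (default; by file extension), `"vcf"` or `"tsv"`.
#'   TSV files need columns `chrom`, `pos`, `ref`, `alt` and may carry
#'   `total_depth`, `alt_depth`, `vaf`, `filter_status`, `consequence`,
#'   `sample_id`.
#' @param sample_id Sample to extract from a multi-sample VCF (default: the
#'   first sample), and the `sample_id` value stamped on the output.
#' @param chr_policy Contig-name policy passed to [normalize_variants()].
#' @param consequence_key INFO key holding the functional consequence term
#'   in VCF input (default `"CSQ"`).
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `total_depth`, `alt_depth`, `vaf`, `filter_status`, `consequence`,
#'   in file order.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          sample_id = NULL, chr_policy = "strip",
                          consequence_key = "CSQ") {
  format <- match.arg(format)
  if (!file.exists(path)) .stop_io(paste0("file not found: ", path))
  if (format == "auto") format <- sniff_format(path)
  calls <- switch(format,
    vcf = read_variants_vcf(path, sample_id, consequence_key),
    tsv = read_variants_tsv(path, sample_id)
  )
  calls <- reconcile_vaf(calls)
  normalize_variants(calls, chr_policy = chr_policy)
}

sniff_format <- function(path) {
  base <- sub("\\.(gz|bgz)$", "", path)
  if (grepl("\\.vcf$", base, ignore.case = TRUE)) "vcf" else "tsv"
}

read_variants_vcf <- function(path, sample_id, consequence_key) {
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(vcf)
  smp <- pick_sample(vcf, sample_id)

  dp <- vcf_sample_field(vcf, "DP", smp)
  af <- vcf_sample_field(vcf, "AF", smp)
  adr <- vcf_ad_field(vcf, smp)

  csq <- rep(NA_character_, n)
  if (consequence_key %in% names(VariantAnnotation::info(vcf))) {
    val <- VariantAnnotation::info(vcf)[[consequence_key]]
    if (is.list(val) || methods::is(val, "List")) {
      csq <- map_chr(as.list(val), ~ if (length(.x)) as.character(.x[[1]]) else NA_character_)
    } else {
      csq <- as.character(val)
    }
  }

  tibble(
    sample_id = smp$label,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf)),
    total_depth = if (is.null(dp)) adr$total else as.integer(dp),
    alt_depth = adr$alt,
    vaf = if (is.null(af)) rep(NA_real_, n) else as.numeric(af),
    filter_status = as.character(VariantAnnotation::filt(vcf)),
    consequence = csq
  )
}

pick_sample <- function(vcf, sample_id) {
  smps <- colnames(vcf)
  if (length(smps) == 0) {
    return(list(idx = NULL, label = sample_id %||% NA_character_))
  }
  if (is.null(sample_id)) return(list(idx = 1L, label = smps[1]))
  idx <- match(sample_id, smps)
  if (is.na(idx)) {
    .stop_format(sprintf(
      "sample '%s' not in VCF (samples: %s)", sample_id,
      paste(smps, collapse = ", ")
    ))
  }
  list(idx = idx, label = sample_id)
}

vcf_sample_field <- function(vcf, field, smp) {
  g <- VariantAnnotation::geno(vcf)
  if (is.null(smp$idx) || !(field %in% names(g))) return(NULL)
  m <- g[[field]]
  if (length(dim(m)) >= 2) m[, smp$idx] else m
}

vcf_ad_field <- function(vcf, smp) {
  n <- length(vcf)
  empty <- list(total = rep(NA_integer_, n), alt = rep(NA_integer_, n))
  g <- VariantAnnotation::geno(vcf)
  if (is.null(smp$idx) || !("AD" %in% names(g))) return(empty)
  ad <- g$AD
  if (is.array(ad) && length(dim(ad)) == 3 && dim(ad)[3] == 2) {
    refd <- as.integer(ad[, smp$idx, 1])
    altd <- as.integer(ad[, smp$idx, 2])
    return(list(total = refd + altd, alt = altd))
  }
  if (is.matrix(ad) && is.list(ad[1, smp$idx])) {
    vals <- ad[, smp$idx]
    refd <- map_int(vals, ~ if (length(.x) >= 1) as.integer(.x[[1]]) else NA_integer_)
    altd <- map_int(vals, ~ if (length(.x) >= 2) as.integer(.x[[2]]) else NA_integer_)
    return(list(total = refd + altd, alt = altd))
  }
  empty
}

read_variants_tsv <- function(path, sample_id) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  miss <- setdiff(c("chrom", "pos", "ref", "alt"), names(df))
  if (length(miss) > 0) {
    .stop_format(paste0(
      "TSV is missing mandatory column(s): ", paste(miss, collapse = ", ")
    ))
  }
  n <- nrow(df)
  tibble(
    sample_id = as.character(
      sample_id %||% (if ("sample_id" %in% names(df)) df$sample_id else NA_character_)
    ),
    chrom = as.character(df$chrom),
    pos = as.integer(df$pos),
    ref = as.character(df$ref),
    alt = as.character(df$alt),
    total_depth = if ("total_depth" %in% names(df)) as.integer(df$total_depth) else rep(NA_integer_, n),
    alt_depth = if ("alt_depth" %in% names(df)) as.integer(df$alt_depth) else rep(NA_integer_, n),
    vaf = if ("vaf" %in% names(df)) as.numeric(df$vaf) else rep(NA_real_, n),
    filter_status = if ("filter_status" %in% names(df)) as.character(df$filter_status) else rep("PASS", n),
    consequence = if ("consequence" %in% names(df)) as.character(df$consequence) else rep(NA_character_, n)
  )
}

# Fill the VAF fallback chain and flag AF-vs-AD disagreement (> 0.01).
reconcile_vaf <- function(calls) {
  derived <- if_else(
    !is.na(calls$total_depth) & calls$total_depth > 0 & !is.na(calls$alt_depth),
    calls$alt_depth / calls$total_depth, NA_real_
  )
  clash <- !is.na(calls$vaf) & !is.na(derived) & abs(calls$vaf - derived) > 0.01
  if (any(clash)) {
    warn(sprintf(
      "%d record(s) have AF disagreeing with AD-derived VAF by > 0.01; keeping the explicit AF",
      sum(clash)
    ))
  }
  calls$vaf <- if_else(is.na(calls$vaf), derived, calls$vaf)
  nodepth <- is.na(calls$vaf)
  if (any(nodepth)) {
    inform(sprintf(
      "%d record(s) have no usable depth or AF; kept with undefined VAF", sum(nodepth)
    ))
  }
  calls
}

#' Write variant calls to VCF or TSV
#'
#' Inverse of [read_variants()]: TSV output uses the canonical column set;
#' VCF output stores depth/VAF in `AD`/`DP`/`AF` FORMAT fields and the
#' consequence in the `CSQ` INFO field. Coordinates are written 1-based
#' (VCF convention) in both formats.
#'
#' @param calls Call tibble as produced by [read_variants()].
#' @param path Output path.
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(calls, path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- sniff_format(path)
  if (format == "tsv") {
    readr::write_tsv(calls, path)
  } else {
    vcf <- build_vcf(calls, info_cols = list(), sample_label = first_sample(calls))
    VariantAnnotation::writeVcf(vcf, path)
  }
  invisible(path)
}

#' Write classified variants (with evidence and labels) to TSV or VCF
#'
#' Emits one row/record per variant carrying the variant key, VAF and depth,
#' consequence, every database's evidence, the final label, the deciding
#' phase and the ordered reason codes. In VCF output these are INFO fields
#' (`SS_LABEL`, `SS_PHASE`, `SS_REASON`, plus one `SS_*` key per evidence
#' column), all declared in the header. Output is deterministic for
#' identical input.
#'
#' @param classified Result of [classify_cohort()] (an annotated, labeled
#'   call tibble).
#' @param path Output path.
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_classified <- function(classified, path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- sniff_format(path)
  out <- classified
  out$reasons <- map_chr(out$reasons, paste, collapse = ";")
  if (format == "tsv") {
    readr::write_tsv(out, path)
    return(invisible(path))
  }
  evid <- evidence_columns(classified)
  info_cols <- c(
    list(
      SS_LABEL = list(values = as.character(out$label), type = "String",
                      desc = "somaticsieve classification label"),
      SS_PHASE = list(values = as.integer(out$phase), type = "Integer",
                      desc = "Decision-tree phase that fixed the label (0 = default)"),
      SS_REASON = list(values = out$reasons, type = "String",
                       desc = "Ordered reason codes; first is deciding")
    ),
    evid
  )
  vcf <- build_vcf(out, info_cols = info_cols, sample_label = first_sample(out))
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}

first_sample <- function(calls) {
  s <- calls$sample_id
  s <- s[!is.na(s)]
  if (length(s)) s[1] else "SAMPLE"
}

evidence_columns <- function(classified) {
  cols <- names(classified)
  evid <- list()
  for (nm in grep("^af_", cols, value = TRUE)) {
    evid[[paste0("SS_", toupper(nm))]] <- list(
      values = classified[[nm]], type = "Float",
      desc = paste0("Population allele frequency in ", sub("^af_", "", nm))
    )
  }
  for (nm in grep("^in_", cols, value = TRUE)) {
    evid[[paste0("SS_", toupper(nm))]] <- list(
      values = as.integer(classified[[nm]]), type = "Integer",
      desc = paste0("Present in ", sub("^in_", "", nm), " (1/0)")
    )
  }
  for (nm in grep("^common_", cols, value = TRUE)) {
    evid[[paste0("SS_", toupper(nm))]] <- list(
      values = as.integer(classified[[nm]]), type = "Integer",
      desc = paste0("Flagged common in ", sub("^common_", "", nm), " (1/0)")
    )
  }
  if ("cosmic_id" %in% cols) {
    evid$SS_COSMIC_ID <- list(values = classified$cosmic_id, type = "String",
                              desc = "Somatic-catalogue identifier")
  }
  if ("clinvar_sig" %in% cols) {
    evid$SS_CLNSIG <- list(values = classified$clinvar_sig, type = "String",
                           desc = "Clinical significance assertions")
  }
  evid
}

# Assemble a VariantAnnotation::VCF object from a call tibble plus optional
# INFO columns described as list(values=, type=, desc=).
build_vcf <- function(calls, info_cols, sample_label) {
  n <- nrow(calls)
  gr <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$pos, width = nchar(calls$ref))
  )
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(calls$ref),
    ALT = Biostrings::DNAStringSetList(as.list(calls$alt)),
    QUAL = rep(NA_real_, n),
    FILTER = if_else(is.na(calls$filter_status), ".", calls$filter_status)
  )

  info_cols <- c(list(
    CSQ = list(values = calls$consequence, type = "String",
               desc = "Functional consequence")
  ), info_cols)
  info_df <- S4Vectors::DataFrame(lapply(info_cols, function(x) {
    v <- x$values
    if (x$type == "String") {
      v <- as.character(v)
      v[is.na(v)] <- "."
      # INFO strings must not contain whitespace/semicolons
      v <- gsub("[; ]", "_", v)
    }
    v
  }))
  info_hdr <- S4Vectors::DataFrame(
    Number = rep("1", length(info_cols)),
    Type = map_chr(info_cols, "type"),
    Description = map_chr(info_cols, "desc"),
    row.names = names(info_cols)
  )

  refd <- if_else(
    !is.na(calls$total_depth) & !is.na(calls$alt_depth),
    calls$total_depth - calls$alt_depth, NA_integer_
  )
  geno <- S4Vectors::SimpleList(
    AD = array(c(refd, calls$alt_depth), dim = c(n, 1, 2),
               dimnames = list(NULL, sample_label, NULL)),
    DP = matrix(as.integer(calls$total_depth), ncol = 1,
                dimnames = list(NULL, sample_label)),
    AF = matrix(as.numeric(calls$vaf), ncol = 1,
                dimnames = list(NULL, sample_label))
  )
  geno_hdr <- S4Vectors::DataFrame(
    Number = c("R", "1", "A"),
    Type = c("Integer", "Integer", "Float"),
    Description = c("Allelic depths (ref, alt)", "Total read depth",
                    "Variant allele fraction"),
    row.names = c("AD", "DP", "AF")
  )
  hdr <- VariantAnnotation::VCFHeader(samples = sample_label)
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    fileformat = S4Vectors::DataFrame(Value = "VCFv4.2", row.names = "fileformat")
  )
  VariantAnnotation::info(hdr) <- info_hdr
  VariantAnnotation::geno(hdr) <- geno_hdr
  VariantAnnotation::VCF(
    rowRanges = gr, fixed = fixed, info = info_df,
    colData = S4Vectors::DataFrame(row.names = sample_label),
    exptData = list(header = hdr), geno = geno
  )
}

#' Read back a classified TSV or VCF written by [write_classified()]
#'
#' @param path File written by [write_classified()].
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @return A tibble with at least the variant key columns, `label`, `phase`
#'   and `reasons` (list column of reason codes).
#' @export
read_classified <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") format <- sniff_format(path)
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE)
    df$chrom <- as.character(df$chrom)
    df$pos <- as.integer(df$pos)
    df$reasons <- strsplit(df$reasons, ";", fixed = TRUE)
    return(as_tibble(df))
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  tibble(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = map_chr(as.list(VariantAnnotation::alt(vcf)), ~ as.character(.x[[1]])),
    label = as.character(info$SS_LABEL),
    phase = as.integer(info$SS_PHASE),
    reasons = strsplit(as.character(info$SS_REASON), ";", fixed = TRUE)
  )
}
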