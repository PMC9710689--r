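#' Load a local evidence database from VCF or TSV
#'
#' Reads one evidence source into memory with all keys normalized via
#' [normalize_variants()]. Three kinds are supported:
#' * `population` — germline population allele frequencies (1000 Genomes,
#'   ESP, ExAC-style) or presence/`COMMON`-flag catalogues (dbSNP-style);
#' * `somatic` — a somatically-acquired-mutation catalogue (COSMIC-style);
#' * `clinical` — clinical-significance assertions (ClinVar-style).
#'
#' Duplicate keys after normalization are collapsed by a fixed rule (kept
#' maximum AF for population sources, first identifier / union of
#' significance terms otherwise) and reported via a message.
#'
#' @param path Database file. TSV needs `chrom`, `pos`, `ref`, `alt` plus a
#'   payload column (`af` and optional `common` for population; `id` and
#'   optional `count` for somatic; `significance` for clinical). VCF input
#'   takes the AF from `af_key`, a dbSNP-style `COMMON` INFO flag, the `ID`
#'   column as catalogue identifier, and `CLNSIG` for significance.
#' @param kind `"population"`, `"somatic"` or `"clinical"`.
#' @param name Registry name (e.g. `"EXAC"`); stored uppercase.
#' @param priority Integer rank; lower = higher priority. Used to pick which
#'   database a germline call is attributed to when several qualify.
#' @param format `"auto"`, `"vcf"` or `"tsv"`.
#' @param af_key INFO key holding the allele frequency in VCF input.
#' @param chr_policy Contig-name policy, as in [normalize_variants()].
#' @return An object of class `"sieve_db"`: a list with `name`, `kind`,
#'   `priority` and a normalized `records` tibble.
#' @export
load_database <- function(path, kind = c("population", "somatic", "clinical"),
                          name, priority = NA_integer_,
                          format = c("auto", "vcf", "tsv"),
                          af_key = "AF", chr_policy = "strip") {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (!file.exists(path)) .stop_io(paste0("database file not found: ", path))
  if (format == "auto") format <- sniff_format(path)

  raw <- if (format == "tsv") {
    read_db_tsv(path, kind)
  } else {
    read_db_vcf(path, kind, af_key)
  }
  if (nrow(raw) == 0) {
    warn(paste0("database '", name, "' is empty: ", path))
  } else {
    bad_af <- "af" %in% names(raw) &&
      any(!is.na(raw$af) & (raw$af < 0 | raw$af > 1))
    if (isTRUE(bad_af)) {
      i <- which(!is.na(raw$af) & (raw$af < 0 | raw$af > 1))[1]
      .stop_format(sprintf(
        "database '%s': allele frequency outside [0, 1] at record %d (af = %s)",
        name, i, raw$af[i]
      ))
    }
    raw <- normalize_variants(raw, chr_policy = chr_policy)
    raw <- dedupe_db_records(raw, kind, name)
  }
  structure(
    list(name = toupper(name), kind = kind,
         priority = as.integer(priority), records = raw),
    class = "sieve_db"
  )
}

read_db_tsv <- function(path, kind) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  miss <- setdiff(c("chrom", "pos", "ref", "alt"), names(df))
  if (length(miss) > 0) {
    .stop_format(paste0(
      "database TSV missing column(s): ", paste(miss, collapse = ", ")
    ))
  }
  n <- nrow(df)
  out <- tibble(
    chrom = as.character(df$chrom), pos = as.integer(df$pos),
    ref = as.character(df$ref), alt = as.character(df$alt)
  )
  if (kind == "population") {
    out$af <- if ("af" %in% names(df)) as.numeric(df$af) else rep(NA_real_, n)
    out$common_flag <- if ("common" %in% names(df)) as.logical(df$common) else rep(NA, n)
  } else if (kind == "somatic") {
    out$catalogue_id <- if ("id" %in% names(df)) as.character(df$id) else rep(NA_character_, n)
    out$occurrence_count <- if ("count" %in% names(df)) as.integer(df$count) else rep(NA_integer_, n)
  } else {
    if (!"significance" %in% names(df)) {
      .stop_format("clinical database TSV missing 'significance' column")
    }
    out$significance <- as.character(df$significance)
  }
  out
}

read_db_vcf <- function(path, kind, af_key) {
  vcf <- VariantAnnotation::expand(
    VariantAnnotation::readVcf(path, genome = "unknown")
  )
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  n <- length(vcf)
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(VariantAnnotation::alt(vcf))
  )
  info_scalar <- function(key) {
    if (!key %in% names(info)) return(NULL)
    val <- info[[key]]
    if (is.list(val) || methods::is(val, "List")) {
      map_chr(as.list(val), ~ if (length(.x)) as.character(.x[[1]]) else NA_character_)
    } else {
      as.character(val)
    }
  }
  if (kind == "population") {
    afv <- info_scalar(af_key)
    out$af <- if (is.null(afv)) rep(NA_real_, n) else suppressWarnings(as.numeric(afv))
    if ("COMMON" %in% names(info)) {
      v <- info$COMMON
      out$common_flag <- if (is.logical(v)) v else as.integer(as.character(v)) == 1L
    } else {
      out$common_flag <- rep(NA, n)
    }
  } else if (kind == "somatic") {
    out$catalogue_id <- names(rr) %||% rep(NA_character_, n)
    cnt <- info_scalar("CNT")
    out$occurrence_count <- if (is.null(cnt)) rep(NA_integer_, n) else as.integer(cnt)
  } else {
    sig <- info_scalar("CLNSIG")
    if (is.null(sig)) .stop_format("clinical VCF lacks a CLNSIG INFO field")
    out$significance <- sig
  }
  out
}

dedupe_db_records <- function(df, kind, name) {
  key <- variant_key(df)
  if (!anyDuplicated(key)) return(df)
  ndup <- sum(duplicated(key))
  inform(sprintf(
    "database '%s': %d duplicate key(s) after normalization collapsed", name, ndup
  ))
  df$.key <- key
  df <- if (kind == "population") {
    df |>
      group_by(.data$.key) |>
      summarise(
        chrom = first(.data$chrom), pos = first(.data$pos),
        ref = first(.data$ref), alt = first(.data$alt),
        af = if (all(is.na(.data$af))) NA_real_ else max(.data$af, na.rm = TRUE),
        common_flag = if (all(is.na(.data$common_flag))) NA else any(.data$common_flag, na.rm = TRUE),
        .groups = "drop"
      )
  } else if (kind == "somatic") {
    df |>
      group_by(.data$.key) |>
      summarise(
        chrom = first(.data$chrom), pos = first(.data$pos),
        ref = first(.data$ref), alt = first(.data$alt),
        catalogue_id = first(.data$catalogue_id),
        occurrence_count = if (all(is.na(.data$occurrence_count))) NA_integer_
          else as.integer(sum(.data$occurrence_count, na.rm = TRUE)),
        .groups = "drop"
      )
  } else {
    df |>
      group_by(.data$.key) |>
      summarise(
        chrom = first(.data$chrom), pos = first(.data$pos),
        ref = first(.data$ref), alt = first(.data$alt),
        significance = paste(unique(unlist(strsplit(.data$significance, ","))), collapse = ","),
        .groups = "drop"
      )
  }
  select(df, -".key")
}

#' Assemble a configured database set
#'
#' Bundles the loaded evidence sources with the evidence-interpretation
#' switches the classifier consults. The default germline priority order is
#' ExAC (highest), then 1000 Genomes, ESP, and dbSNP last — reflecting
#' dbSNP's comparatively poor germline precision (it also harbours
#' pathogenic somatic entries). Priorities must be unique; they only govern
#' which database a germline call is attributed to in the reason code, not
#' whether the variant is germline (allele-frequency evidence is pooled
#' any-hit).
#'
#' @param ... `"sieve_db"` objects from [load_database()]. At most one each
#'   of kind `"somatic"` and `"clinical"`.
#' @param dbsnp_presence_is_germline If `TRUE`, a presence-only population
#'   hit (no AF) counts as germline evidence even without a `COMMON` flag.
#'   Default `FALSE`: presence-only hits decide only when flagged common.
#' @param maf_folding If `TRUE`, stored allele frequencies are folded to the
#'   minor allele (`min(af, 1 - af)`) before comparison with the cutoff.
#'   Default `FALSE`: the stored AF is compared directly.
#' @return An object of class `"sieve_db_set"`.
#' @examples
#' \dontrun{
#' dbs <- db_set(
#'   load_database("exac.tsv", "population", "EXAC", priority = 1),
#'   load_database("cosmic.tsv", "somatic", "COSMIC"),
#'   load_database("clinvar.tsv", "clinical", "CLINVAR")
#' )
#' }
#' @export
db_set <- function(..., dbsnp_presence_is_germline = FALSE, maf_folding = FALSE) {
  dbs <- list(...)
  if (length(dbs) == 1 && is.list(dbs[[1]]) && !inherits(dbs[[1]], "sieve_db")) {
    dbs <- dbs[[1]]
  }
  if (!all(map_lgl(dbs, inherits, "sieve_db"))) {
    .stop_config("db_set() takes sieve_db objects from load_database()")
  }
  kinds <- map_chr(dbs, "kind")
  pop <- dbs[kinds == "population"]
  som <- dbs[kinds == "somatic"]
  cli <- dbs[kinds == "clinical"]
  if (length(som) > 1 || length(cli) > 1) {
    .stop_config("at most one somatic and one clinical database are supported")
  }
  if (length(pop) > 0) {
    pr <- map_int(pop, "priority")
    if (any(is.na(pr))) {
      # fill unassigned priorities after the assigned ones, in input order
      pr[is.na(pr)] <- max(c(0L, pr[!is.na(pr)])) + seq_len(sum(is.na(pr)))
      pop <- map2(pop, pr, function(d, p) { d$priority <- p; d })
    }
    if (anyDuplicated(pr)) {
      .stop_config("population database priorities must be unique")
    }
    pop <- pop[order(pr)]
  }
  nms <- map_chr(pop, "name")
  if (anyDuplicated(nms)) .stop_config("population database names must be unique")
  structure(
    list(
      population = setNames(pop, nms),
      somatic = if (length(som)) som[[1]] else NULL,
      clinical = if (length(cli)) cli[[1]] else NULL,
      dbsnp_presence_is_germline = isTRUE(dbsnp_presence_is_germline),
      maf_folding = isTRUE(maf_folding)
    ),
    class = "sieve_db_set"
  )
}

#' @export
print.sieve_db_set <- function(x, ...) {
  cat("<sieve_db_set>\n")
  for (db in x$population) {
    cat(sprintf("  population %-8s priority %d, %d record(s)\n",
                db$name, db$priority, nrow(db$records)))
  }
  if (!is.null(x$somatic)) {
    cat(sprintf("  somatic    %-8s %d record(s)\n",
                x$somatic$name, nrow(x$somatic$records)))
  }
  if (!is.null(x$clinical)) {
    cat(sprintf("  clinical   %-8s %d record(s)\n",
                x$clinical$name, nrow(x$clinical$records)))
  }
  cat("  dbsnp_presence_is_germline:", x$dbsnp_presence_is_germline,
      " maf_folding:", x$maf_folding, "\n")
  invisible(x)
}

#' Annotate variant calls against a database set
#'
#' Pure exact-key join: each call is paired with whatever evidence each
#' source holds for its normalized key; absence of evidence is a valid
#' state (all evidence columns `NA`/`FALSE`). Input order is preserved and
#' no rows are added or dropped.
#'
#' Added columns, per population database `name` (lower-cased):
#' `in_<name>` (presence), `af_<name>` (allele frequency, `NA` if
#' presence-only), `common_<name>` (common flag, `NA` if the source has
#' none); plus `in_cosmic`, `cosmic_id`, `cosmic_n` for the somatic
#' catalogue and `in_clinvar`, `clinvar_sig` for the clinical source.
#'
#' @param calls Normalized call tibble (from [read_variants()] or
#'   [normalize_variants()]).
#' @param dbs A [db_set()].
#' @return `calls` with evidence columns appended.
#' @export
annotate <- function(calls, dbs) {
  stopifnot(inherits(dbs, "sieve_db_set"))
  calls <- as_tibble(calls)
  keycols <- c("chrom", "pos", "ref", "alt")
  for (db in dbs$population) {
    nm <- tolower(db$name)
    rec <- db$records
    hit <- select(rec, all_of(keycols), "af", "common_flag")
    names(hit) <- c(keycols, paste0("af_", nm), paste0("common_", nm))
    hit[[paste0("in_", nm)]] <- TRUE
    calls <- left_join(calls, hit, by = keycols)
    calls[[paste0("in_", nm)]] <- !is.na(calls[[paste0("in_", nm)]])
  }
  if (!is.null(dbs$somatic)) {
    rec <- dbs$somatic$records
    hit <- select(rec, all_of(keycols), "catalogue_id", "occurrence_count")
    names(hit) <- c(keycols, "cosmic_id", "cosmic_n")
    hit$in_cosmic <- TRUE
    calls <- left_join(calls, hit, by = keycols)
    calls$in_cosmic <- !is.na(calls$in_cosmic)
  } else {
    calls$in_cosmic <- FALSE
    calls$cosmic_id <- NA_character_
    calls$cosmic_n <- NA_integer_
  }
  if (!is.null(dbs$clinical)) {
    rec <- dbs$clinical$records
    hit <- select(rec, all_of(keycols), "significance")
    names(hit) <- c(keycols, "clinvar_sig")
    hit$in_clinvar <- TRUE
    calls <- left_join(calls, hit, by = keycols)
    calls$in_clinvar <- !is.na(calls$in_clinvar)
  } else {
    calls$in_clinvar <- FALSE
    calls$clinvar_sig <- NA_character_
  }
  attr(calls, "db_registry") <- db_registry(dbs)
  calls
}

# Small registry tibble the classifier uses to rank qualifying databases.
db_registry <- function(dbs) {
  if (length(dbs$population) == 0) {
    return(tibble(name = character(), column = character(), priority = integer()))
  }
  tibble(
    name = map_chr(dbs$population, "name"),
    column = tolower(map_chr(dbs$population, "name")),
    priority = map_int(dbs$population, "priority")
  )
}
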