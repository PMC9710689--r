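# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

make_call <- function(chrom = "1", pos = 100L, ref = "A", alt = "G",
                      total_depth = 100L, alt_depth = 30L,
                      vaf = alt_depth / total_depth,
                      filter_status = "PASS",
                      consequence = "missense_variant",
                      sample_id = "T1") {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
    ref = ref, alt = alt, total_depth = as.integer(total_depth),
    alt_depth = as.integer(alt_depth), vaf = vaf,
    filter_status = filter_status, consequence = consequence
  )
}

db_tibble <- function(chrom = character(), pos = integer(),
                      ref = character(), alt = character(), ...) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt, ...)
}

make_pop_db <- function(name, priority, records = NULL) {
  if (is.null(records)) {
    records <- db_tibble(af = numeric(), common_flag = logical())
  }
  somaticsieve:::new_sieve_db(name, "population", priority, records)
}

make_cosmic_db <- function(records = NULL) {
  if (is.null(records)) {
    records <- db_tibble(catalogue_id = character(), occurrence_count = integer())
  }
  somaticsieve:::new_sieve_db("COSMIC", "somatic", NA_integer_, records)
}

make_clinvar_db <- function(records = NULL) {
  if (is.null(records)) records <- db_tibble(significance = character())
  somaticsieve:::new_sieve_db("CLINVAR", "clinical", NA_integer_, records)
}

# Standard four-population + somatic + clinical set with empty records,
# used when tests inject evidence columns directly.
make_empty_dbset <- function(dbsnp_presence_is_germline = FALSE,
                             maf_folding = FALSE) {
  db_set(
    make_pop_db("EXAC", 1L), make_pop_db("KG1000", 2L),
    make_pop_db("ESP", 3L), make_pop_db("DBSNP", 4L),
    make_cosmic_db(), make_clinvar_db(),
    dbsnp_presence_is_germline = dbsnp_presence_is_germline,
    maf_folding = maf_folding
  )
}

# Evidence columns for a call tibble, defaulting to "no evidence anywhere".
add_evidence <- function(calls,
                         af_exac = NA_real_, af_kg1000 = NA_real_,
                         af_esp = NA_real_, af_dbsnp = NA_real_,
                         in_dbsnp = FALSE, common_dbsnp = NA,
                         cosmic = FALSE, clinvar = NA_character_) {
  n <- nrow(calls)
  rep_n <- function(x) rep(x, length.out = n)
  calls$af_exac <- rep_n(af_exac);   calls$in_exac <- !is.na(calls$af_exac)
  calls$common_exac <- rep_n(NA)
  calls$af_kg1000 <- rep_n(af_kg1000); calls$in_kg1000 <- !is.na(calls$af_kg1000)
  calls$common_kg1000 <- rep_n(NA)
  calls$af_esp <- rep_n(af_esp);     calls$in_esp <- !is.na(calls$af_esp)
  calls$common_esp <- rep_n(NA)
  calls$af_dbsnp <- rep_n(af_dbsnp)
  calls$in_dbsnp <- rep_n(in_dbsnp) | !is.na(calls$af_dbsnp)
  calls$common_dbsnp <- rep_n(common_dbsnp)
  calls$in_cosmic <- rep_n(cosmic)
  calls$cosmic_id <- ifelse(calls$in_cosmic, "COSM000001", NA_character_)
  calls$cosmic_n <- ifelse(calls$in_cosmic, 3L, NA_integer_)
  calls$clinvar_sig <- rep_n(clinvar)
  calls$in_clinvar <- !is.na(calls$clinvar_sig)
  calls
}

quiet_classify <- function(...) suppressMessages(classify_cohort(...))
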