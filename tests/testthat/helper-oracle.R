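# Independent straight-line re-implementation of the three decision rules,
# written against the published description only (no shared code with the
# package). Scalar, deliberately naive; used as the reference in
# oracle-equivalence tests.
#
# evidence: list with per-database af (named, NA = absent), dbsnp_present,
# dbsnp_common, cosmic (logical), clinvar (character or NA).
oracle_classify <- function(filter_status, total_depth, vaf, consequence,
                            ev, t,
                            dbsnp_presence_is_germline = FALSE,
                            maf_folding = FALSE,
                            clinvar_overrides_cosmic = FALSE) {
  # phase 1: quality pass / variant type
  if (is.na(filter_status) || filter_status != "PASS") return("filtered")
  if (is.na(total_depth) || total_depth < t$min_depth) return("filtered")
  if (is.na(vaf) || vaf < t$min_vaf) return("filtered")
  if (is.na(consequence) ||
      !consequence %in% t$consequence_whitelist) return("filtered")

  # germline evidence: any population database at/above the MAF cutoff
  germ <- FALSE
  for (af in ev$af) {
    if (!is.na(af)) {
      a <- if (maf_folding) min(af, 1 - af) else af
      if (a >= t$germline_maf_cutoff) germ <- TRUE
    }
  }
  if (isTRUE(ev$dbsnp_present)) {
    if (isTRUE(ev$dbsnp_common) || dbsnp_presence_is_germline) germ <- TRUE
  }

  benign <- FALSE
  if (!is.na(ev$clinvar)) {
    terms <- tolower(strsplit(ev$clinvar, "[,;|/]")[[1]])
    benign <- any(terms %in% c("benign", "likely_benign")) &&
      !any(grepl("pathogenic", terms)) && !any(grepl("conflicting", terms))
  }

  # phase 2: somatic catalogue overrides germline databases
  if (isTRUE(ev$cosmic)) {
    if (clinvar_overrides_cosmic && benign) return("germline")
    return("somatic")
  }
  if (germ) return("germline")
  # phase 3: benign clinical rescue, else default somatic
  if (benign) return("germline")
  "somatic"
}

# Exhaustive evidence truth table. Levels per AF-bearing database: absent /
# 0.005 / 0.01 / 0.02; for the presence-only database: absent /
# present-noncommon / present-common / present with AF 0.02.
evidence_truth_table <- function() {
  af_levels <- c(NA, 0.005, 0.01, 0.02)
  dbsnp_levels <- c("absent", "present", "common", "af")
  grid <- expand.grid(
    qual = c("PASS", "q10"),
    csq = c("missense_variant", "synonymous_variant"),
    exac = af_levels, kg1000 = af_levels, esp = af_levels,
    dbsnp = dbsnp_levels,
    cosmic = c(FALSE, TRUE),
    clinvar = c(NA, "benign", "likely_benign", "pathogenic",
                "conflicting_interpretations_of_pathogenicity"),
    stringsAsFactors = FALSE
  )
  grid$af_dbsnp <- ifelse(grid$dbsnp == "af", 0.02, NA_real_)
  grid$in_dbsnp <- grid$dbsnp != "absent"
  grid$common_dbsnp <- ifelse(grid$dbsnp == "common", TRUE,
                              ifelse(grid$dbsnp == "present", FALSE, NA))
  grid
}
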