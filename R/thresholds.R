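#' Classification thresholds and assay-mode defaults
#'
#' Bundles every tunable cutoff the decision tree and the gold-standard rule
#' use. The assay `mode` selects default tumor VAF/depth gates: targeted
#' panels (`"TS"`) are sequenced deep and use `min_depth = 50`; whole-exome
#' (`"WES"`) uses `min_depth = 20`; both default to `min_vaf = 0.05`. These
#' depth/VAF defaults are this package's own suggested values and can (and
#' often should) be overridden per assay. The germline evidence cutoff
#' (`germline_maf_cutoff = 0.01`, i.e. a population minor allele frequency of
#' 1%) and the matched-normal gold-standard cutoff (`normal_af_cutoff = 0.05`,
#' strict "> 5%") are the published operating points of the method.
#'
#' @param mode `"TS"` (targeted sequencing, default) or `"WES"`; selects
#'   default `min_vaf`/`min_depth`.
#' @param min_vaf Minimum tumor variant allele fraction to pass phase 1
#'   (fraction in \[0, 1\]).
#' @param min_depth Minimum total read depth to pass phase 1 (integer >= 0).
#' @param germline_maf_cutoff Population allele frequency at or above which a
#'   germline-database hit counts as germline evidence (0 < x < 1).
#' @param normal_af_cutoff Matched-normal allele fraction strictly above
#'   which a tumor variant is gold-standard germline (0 < x < 1).
#' @param consequence_whitelist Character vector of Sequence Ontology
#'   consequence terms treated as non-synonymous (phase 1 keeps only these).
#' @return A list of class `"sieve_thresholds"`.
#' @examples
#' thresholds("WES")
#' thresholds("TS", min_vaf = 0.1)
#' @export
thresholds <- function(mode = c("TS", "WES"),
                       min_vaf = NULL,
                       min_depth = NULL,
                       germline_maf_cutoff = 0.01,
                       normal_af_cutoff = 0.05,
                       consequence_whitelist = default_consequence_whitelist()) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    TS = list(min_vaf = 0.05, min_depth = 50L),
    WES = list(min_vaf = 0.05, min_depth = 20L)
  )
  min_vaf <- min_vaf %||% defaults$min_vaf
  min_depth <- as.integer(min_depth %||% defaults$min_depth)

  if (!is.numeric(min_vaf) || min_vaf < 0 || min_vaf > 1) {
    .stop_config("min_vaf must be in [0, 1]")
  }
  if (is.na(min_depth) || min_depth < 0L) {
    .stop_config("min_depth must be a non-negative integer")
  }
  if (!is.numeric(germline_maf_cutoff) ||
      germline_maf_cutoff <= 0 || germline_maf_cutoff >= 1) {
    .stop_config("germline_maf_cutoff must be in (0, 1)")
  }
  if (!is.numeric(normal_af_cutoff) ||
      normal_af_cutoff <= 0 || normal_af_cutoff >= 1) {
    .stop_config("normal_af_cutoff must be in (0, 1)")
  }
  if (length(consequence_whitelist) == 0) {
    .stop_config("consequence_whitelist must be non-empty")
  }

  structure(
    list(
      mode = mode,
      min_vaf = min_vaf,
      min_depth = min_depth,
      germline_maf_cutoff = germline_maf_cutoff,
      normal_af_cutoff = normal_af_cutoff,
      consequence_whitelist = as.character(consequence_whitelist)
    ),
    class = "sieve_thresholds"
  )
}

#' Consequence terms treated as non-synonymous by default
#'
#' @return Character vector of Sequence Ontology terms.
#' @export
default_consequence_whitelist <- function() {
  c(
    "missense_variant", "stop_gained", "stop_lost", "start_lost",
    "frameshift_variant", "inframe_insertion", "inframe_deletion",
    "splice_acceptor_variant", "splice_donor_variant",
    "protein_altering_variant"
  )
}

#' @export
print.sieve_thresholds <- function(x, ...) {
  cat("<sieve_thresholds> mode:", x$mode, "\n")
  cat("  min_vaf:", x$min_vaf, " min_depth:", x$min_depth, "\n")
  cat("  germline_maf_cutoff:", x$germline_maf_cutoff,
      " normal_af_cutoff (strict >):", x$normal_af_cutoff, "\n")
  cat("  consequence_whitelist:",
      paste(x$consequence_whitelist, collapse = ", "), "\n")
  invisible(x)
}
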