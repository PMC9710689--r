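#' Phase 1: quality, depth, VAF and consequence filtration
#'
#' A call fails phase 1 if any gate fails: the caller filter is not `PASS`,
#' total depth is below `min_depth`, the VAF is below `min_vaf` or
#' undefined, or the consequence is not in the non-synonymous whitelist.
#' All failing gates are reported, not just the first; a zero-depth call can
#' never pass (its VAF is undefined unless supplied explicitly, and the
#' depth gate fails for any `min_depth > 0`).
#'
#' @param calls Normalized call tibble.
#' @param t A [thresholds()] object.
#' @return `calls` with logical `pass1` and a `p1_reasons` list column of
#'   failure codes (`FAIL_QUAL`, `FAIL_DEPTH`, `FAIL_VAF`, `SYNONYMOUS`).
#' @export
phase1_quality <- function(calls, t) {
  stopifnot(inherits(t, "sieve_thresholds"))
  calls <- as_tibble(calls)
  fail_qual <- is.na(calls$filter_status) | calls$filter_status != "PASS"
  fail_depth <- is.na(calls$total_depth) | calls$total_depth < t$min_depth
  fail_vaf <- is.na(calls$vaf) | calls$vaf < t$min_vaf
  fail_csq <- is.na(calls$consequence) |
    !(calls$consequence %in% t$consequence_whitelist)
  calls$p1_reasons <- pmap(
    list(fail_qual, fail_depth, fail_vaf, fail_csq),
    function(q, d, v, c) {
      c("FAIL_QUAL"[q], "FAIL_DEPTH"[d], "FAIL_VAF"[v], "SYNONYMOUS"[c])
    }
  )
  calls$pass1 <- !(fail_qual | fail_depth | fail_vaf | fail_csq)
  calls
}

#' Phase 2: germline-database screen with somatic-catalogue override
#'
#' For calls that passed phase 1: membership in the somatic catalogue makes
#' the call somatic outright — even when germline evidence coexists (reason
#' `COSMIC_OVERRIDE` in that case, `COSMIC` otherwise). Otherwise the call
#' is germline when any population source supplies qualifying evidence: an
#' allele frequency at or above `germline_maf_cutoff` (folded to the minor
#' allele first when the `maf_folding` switch is on), or a presence-only
#' record that is flagged common (or any presence-only record when
#' `dbsnp_presence_is_germline` is on). The germline reason names the
#' highest-priority qualifying database (`GERMLINE_DB:<NAME>`). With no
#' deciding evidence the call stays undecided for phase 3.
#'
#' @param annotated Output of [annotate()] (evidence columns present).
#' @param t A [thresholds()] object.
#' @param dbs The [db_set()] used for annotation.
#' @return `annotated` with `p2_label` (`"somatic"`, `"germline"`,
#'   `"undecided"`) and a `p2_reasons` list column.
#' @export
phase2_database <- function(annotated, t, dbs) {
  stopifnot(inherits(t, "sieve_thresholds"), inherits(dbs, "sieve_db_set"))
  annotated <- as_tibble(annotated)
  reg <- attr(annotated, "db_registry") %||% db_registry(dbs)
  n <- nrow(annotated)

  qual <- matrix(FALSE, nrow = n, ncol = nrow(reg),
                 dimnames = list(NULL, reg$name))
  for (i in seq_len(nrow(reg))) {
    qual[, i] <- db_evidence_qualifies(
      annotated[[paste0("af_", reg$column[i])]],
      annotated[[paste0("in_", reg$column[i])]],
      annotated[[paste0("common_", reg$column[i])]],
      t$germline_maf_cutoff, dbs
    )
  }
  any_germline <- if (ncol(qual) > 0) rowSums(qual) > 0 else rep(FALSE, n)
  # highest-priority (lowest rank) qualifying database per row
  best_db <- rep(NA_character_, n)
  if (ncol(qual) > 0) {
    ord <- order(reg$priority)
    for (i in rev(ord)) best_db[qual[, i]] <- reg$name[i]
  }

  cosmic <- annotated$in_cosmic
  annotated$p2_label <- dplyr::case_when(
    cosmic ~ "somatic",
    any_germline ~ "germline",
    TRUE ~ "undecided"
  )
  annotated$p2_reasons <- pmap(
    list(cosmic, any_germline, best_db),
    function(co, ge, db) {
      if (co) {
        if (ge) "COSMIC_OVERRIDE" else "COSMIC"
      } else if (ge) {
        paste0("GERMLINE_DB:", db)
      } else {
        character(0)
      }
    }
  )
  annotated
}

db_evidence_qualifies <- function(af, present, common, cutoff, dbs) {
  af_cmp <- if (dbs$maf_folding) pmin(af, 1 - af) else af
  by_af <- !is.na(af_cmp) & af_cmp >= cutoff
  presence_only <- present & is.na(af)
  by_presence <- presence_only &
    (isTRUE(dbs$dbsnp_presence_is_germline) | (!is.na(common) & common))
  by_af | by_presence
}

#' Phase 3: benign clinical-significance rescue and the somatic default
#'
#' Refines what phase 2 left open. An undecided call whose clinical record
#' qualifies as benign (contains `benign` or `likely_benign`, carries no
#' pathogenic-family term and no conflicting assertion) becomes germline
#' (`CLINVAR_BENIGN`); any other undecided call defaults to somatic
#' (`NO_EVIDENCE_DEFAULT_SOMATIC`) so that every surviving variant receives
#' a label. A catalogue-somatic call from phase 2 is retained by default;
#' set `clinvar_overrides_cosmic = TRUE` to let a benign clinical record
#' overturn it.
#'
#' @param annotated Output of [phase2_database()].
#' @param clinvar_overrides_cosmic Should a qualifying benign record
#'   overturn catalogue-somatic calls? Default `FALSE`.
#' @return `annotated` with `p3_label` and `p3_reasons` columns.
#' @export
phase3_clinical <- function(annotated, clinvar_overrides_cosmic = FALSE) {
  annotated <- as_tibble(annotated)
  benign <- clinvar_benign_qualifies(annotated$clinvar_sig)
  lab <- annotated$p2_label
  out_label <- character(nrow(annotated))
  out_reason <- vector("list", nrow(annotated))
  for (i in seq_along(out_label)) {
    if (lab[i] == "germline") {
      out_label[i] <- "germline"; out_reason[i] <- list(character(0))
    } else if (lab[i] == "somatic") {
      if (clinvar_overrides_cosmic && benign[i]) {
        out_label[i] <- "germline"; out_reason[i] <- list("CLINVAR_BENIGN")
      } else {
        out_label[i] <- "somatic"; out_reason[i] <- list(character(0))
      }
    } else if (benign[i]) {
      out_label[i] <- "germline"; out_reason[i] <- list("CLINVAR_BENIGN")
    } else {
      out_label[i] <- "somatic"; out_reason[i] <- list("NO_EVIDENCE_DEFAULT_SOMATIC")
    }
  }
  annotated$p3_label <- out_label
  annotated$p3_reasons <- out_reason
  annotated
}

# Conservative benign test: at least one benign/likely_benign term, no
# pathogenic-family term, no conflicting assertion.
clinvar_benign_qualifies <- function(sig) {
  map_lgl(sig, function(s) {
    if (is.na(s)) return(FALSE)
    terms <- tolower(trimws(strsplit(s, "[,;|/]")[[1]]))
    terms <- gsub(" ", "_", terms)
    has_benign <- any(terms %in% c("benign", "likely_benign"))
    has_path <- any(terms %in% c("pathogenic", "likely_pathogenic")) |
      any(grepl("pathogenic", terms))
    has_conflict <- any(grepl("conflicting", terms))
    has_benign && !has_path && !has_conflict
  })
}

#' Classify a cohort of tumor-only variant calls
#'
#' Runs the full three-phase decision tree: quality filtration, the
#' germline-database screen with somatic-catalogue override, and the benign
#' clinical rescue, annotating against `dbs` first if the evidence columns
#' are not already present. Every call that passes phase 1 receives a
#' `somatic` or `germline` label (the tree is total); phase-1 failures are
#' labeled `filtered`. The result is deterministic and independent of
#' cohort order.
#'
#' @param calls Normalized call tibble (annotated or not).
#' @param dbs A [db_set()].
#' @param t A [thresholds()] object.
#' @param clinvar_overrides_cosmic Passed to [phase3_clinical()].
#' @return A tibble of class `"sieve_classification"`: the annotated input
#'   plus `label` (`somatic`/`germline`/`filtered`), `phase` (1, 2, 3, or 0
#'   for the evidence-free default) and `reasons` (list column, deciding
#'   reason first).
#' @examples
#' \dontrun{
#' read_variants("tumor.vcf") |> classify_cohort(dbs, thresholds("TS"))
#' }
#' @export
classify_cohort <- function(calls, dbs, t = thresholds(),
                            clinvar_overrides_cosmic = FALSE) {
  stopifnot(inherits(dbs, "sieve_db_set"), inherits(t, "sieve_thresholds"))
  calls <- as_tibble(calls)
  if (!all(c("in_cosmic", "in_clinvar") %in% names(calls))) {
    calls <- annotate(calls, dbs)
  }
  res <- phase1_quality(calls, t)
  res <- phase2_database(res, t, dbs)
  res <- phase3_clinical(res, clinvar_overrides_cosmic)

  res$label <- dplyr::case_when(
    !res$pass1 ~ "filtered",
    res$p2_label == "germline" ~ "germline",
    TRUE ~ res$p3_label
  )
  res$phase <- dplyr::case_when(
    !res$pass1 ~ 1L,
    res$p2_label %in% c("germline", "somatic") &
      !(res$p3_label != res$p2_label) ~ 2L,
    map_chr(res$p3_reasons, ~ if (length(.x)) .x[1] else "") == "CLINVAR_BENIGN" ~ 3L,
    TRUE ~ 0L
  )
  res$reasons <- pmap(
    list(res$pass1, res$p1_reasons, res$p2_reasons, res$p3_reasons),
    function(p1, r1, r2, r3) {
      if (!p1) r1 else c(r3[r3 == "CLINVAR_BENIGN"], r2,
                         r3[r3 != "CLINVAR_BENIGN"])
    }
  )
  res <- select(res, -"p1_reasons", -"p2_reasons", -"p3_reasons",
                -"p2_label", -"p3_label")
  counts <- table(factor(res$label, levels = c("filtered", "somatic", "germline")))
  inform(sprintf(
    "classified %d variant(s): %d filtered, %d somatic, %d germline",
    nrow(res), counts[["filtered"]], counts[["somatic"]], counts[["germline"]]
  ))
  class(res) <- c("sieve_classification", class(res))
  attr(res, "thresholds") <- t
  attr(res, "clinvar_overrides_cosmic") <- clinvar_overrides_cosmic
  res
}

#' Classify a single variant call
#'
#' Scalar wrapper over [classify_cohort()] for one already-annotated call.
#'
#' @param call One-row call tibble.
#' @param ev Optional one-row evidence tibble to bind onto `call` (columns
#'   as produced by [annotate()]); if `NULL`, `call` is annotated against
#'   `dbs`.
#' @inheritParams classify_cohort
#' @return One-row `"sieve_classification"` tibble.
#' @export
classify <- function(call, dbs, t = thresholds(), ev = NULL,
                     clinvar_overrides_cosmic = FALSE) {
  if (!is.null(ev)) call <- dplyr::bind_cols(as_tibble(call), as_tibble(ev))
  suppressMessages(
    classify_cohort(call, dbs, t, clinvar_overrides_cosmic = clinvar_overrides_cosmic)
  )
}

#' @export
glance.sieve_classification <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_filtered = sum(x$label == "filtered"),
    n_somatic = sum(x$label == "somatic"),
    n_germline = sum(x$label == "germline")
  )
}

#' @export
tidy.sieve_classification <- function(x, ...) {
  out <- as_tibble(x)[, c("sample_id", "chrom", "pos", "ref", "alt",
                          "vaf", "total_depth", "label", "phase")]
  out$deciding_reason <- map_chr(x$reasons, ~ .x[1] %||% NA_character_)
  out
}

#' Plot the label composition of a classified cohort by deciding phase
#'
#' @param object A `"sieve_classification"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sieve_classification <- function(object, ...) {
  df <- as_tibble(object) |>
    count(.data$label, phase = factor(.data$phase))
  ggplot(df, aes(x = .data$label, y = .data$n, fill = .data$phase)) +
    geom_col() +
    labs(x = "label", y = "variants", fill = "deciding phase",
         title = "Tumor-only classification by phase") +
    theme_minimal()
}
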