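#' Build the paired-normal gold standard
#'
#' Implements the matched-normal labeling rule used to validate tumor-only
#' classification: a tumor variant that also appears in the matched normal
#' with an allele fraction strictly above `normal_af_cutoff` (default 5%)
#' is germline; a tumor variant absent from the normal — or matched only at
#' an allele fraction at or below the cutoff — is somatic. Matching is by
#' normalized variant key only (presence and allele fraction, not
#' genotype); variants seen only in the normal are ignored.
#'
#' @param tumor_calls,normal_calls Normalized call tibbles for the matched
#'   pair.
#' @param t A [thresholds()] object supplying `normal_af_cutoff`.
#' @return A tibble of class `"sieve_truth"` with one row per unique tumor
#'   key: `chrom`, `pos`, `ref`, `alt`, `truth_label`
#'   (`"somatic"`/`"germline"`), `normal_vaf` (`NA` when unmatched), and a
#'   `source_samples` attribute recording the tumor/normal sample ids.
#' @examples
#' \dontrun{
#' truth <- build_gold_standard(read_variants("tumor.vcf"),
#'                              read_variants("normal.vcf"), thresholds("TS"))
#' }
#' @export
build_gold_standard <- function(tumor_calls, normal_calls, t = thresholds()) {
  stopifnot(inherits(t, "sieve_thresholds"))
  keycols <- c("chrom", "pos", "ref", "alt")
  tum <- distinct(as_tibble(tumor_calls), across(all_of(keycols)))
  nrm <- as_tibble(normal_calls) |>
    group_by(across(all_of(keycols))) |>
    summarise(normal_vaf = suppressWarnings(max(.data$vaf, na.rm = TRUE)),
              .groups = "drop") |>
    mutate(normal_vaf = if_else(is.finite(.data$normal_vaf),
                                .data$normal_vaf, NA_real_))
  out <- left_join(tum, nrm, by = keycols)
  out$truth_label <- if_else(
    !is.na(out$normal_vaf) & out$normal_vaf > t$normal_af_cutoff,
    "germline", "somatic"
  )
  attr(out, "source_samples") <- c(
    tumor = first_sample(as_tibble(tumor_calls)),
    normal = first_sample(as_tibble(normal_calls))
  )
  class(out) <- c("sieve_truth", class(out))
  out
}

#' Score predicted labels against a gold standard
#'
#' Computes the confusion matrix and the published metrics over the keys
#' present in both the predictions and the truth set, with somatic as the
#' positive class: sensitivity is the fraction of truth-somatic variants
#' predicted somatic, specificity the fraction of truth-germline variants
#' predicted germline. Variants the classifier `filtered` at phase 1 are
#' excluded from the matrix by default (and counted separately); with
#' `filtered = "as_error"` they are scored as misclassifications of
#' whichever truth class they belong to, for stress analyses.
#'
#' @param predicted Tibble with key columns and a `label` column
#'   (`somatic`/`germline`/`filtered`), e.g. a [classify_cohort()] result.
#' @param truth A `"sieve_truth"` tibble from [build_gold_standard()], or
#'   any tibble with the key columns and `truth_label`.
#' @param filtered `"exclude"` (default) or `"as_error"`.
#' @return An object of class `"sieve_eval"`: a list with counts
#'   `tp_somatic`, `fn_somatic`, `tn_germline`, `fp_germline`,
#'   `sensitivity`, `specificity` (`NA` when a truth class is empty),
#'   `n_evaluated`, `n_unmatched` (predicted keys absent from truth) and
#'   `n_filtered` (predictions excluded as phase-1 failures).
#' @export
evaluate <- function(predicted, truth, filtered = c("exclude", "as_error")) {
  filtered <- match.arg(filtered)
  keycols <- c("chrom", "pos", "ref", "alt")
  pred <- as_tibble(predicted)[, c(keycols, "label")]
  pred$label <- as.character(pred$label)
  bad <- !pred$label %in% c("somatic", "germline", "filtered")
  if (any(bad)) {
    .stop_format(paste0("unknown predicted label(s): ",
                        paste(unique(pred$label[bad]), collapse = ", ")))
  }
  dup <- pred |>
    distinct(across(all_of(c(keycols, "label")))) |>
    count(across(all_of(keycols))) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    .stop_format(sprintf(
      "%d predicted key(s) carry conflicting labels (first: %s)",
      nrow(dup), variant_key(dup)[1]
    ))
  }
  pred <- distinct(pred, across(all_of(c(keycols, "label"))))

  n_filtered <- sum(pred$label == "filtered")
  if (filtered == "exclude") pred <- filter(pred, .data$label != "filtered")

  tr <- as_tibble(truth)[, c(keycols, "truth_label")]
  joined <- inner_join(pred, tr, by = keycols)
  n_unmatched <- nrow(pred) - nrow(joined)

  tp <- sum(joined$truth_label == "somatic" & joined$label == "somatic")
  fn <- sum(joined$truth_label == "somatic" & joined$label != "somatic")
  tn <- sum(joined$truth_label == "germline" & joined$label == "germline")
  fp <- sum(joined$truth_label == "germline" & joined$label != "germline")

  structure(
    list(
      tp_somatic = tp, fn_somatic = fn, tn_germline = tn, fp_germline = fp,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      n_evaluated = nrow(joined),
      n_unmatched = n_unmatched,
      n_filtered = n_filtered,
      filtered_policy = filtered
    ),
    class = "sieve_eval"
  )
}

#' @export
print.sieve_eval <- function(x, ...) {
  cat("<sieve_eval> somatic-vs-germline evaluation\n")
  cat(sprintf("  evaluated: %d  (unmatched: %d, filtered %s: %d)\n",
              x$n_evaluated, x$n_unmatched,
              if (x$filtered_policy == "exclude") "excluded" else "as error",
              x$n_filtered))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d\n",
              x$tp_somatic, x$fn_somatic, x$tn_germline, x$fp_germline))
  cat(sprintf("  sensitivity: %s  specificity: %s\n",
              format_metric(x$sensitivity), format_metric(x$specificity)))
  invisible(x)
}

format_metric <- function(v) {
  if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
}

#' @export
tidy.sieve_eval <- function(x, ...) {
  tibble(
    truth = c("somatic", "somatic", "germline", "germline"),
    predicted = c("somatic", "germline", "germline", "somatic"),
    n = c(x$tp_somatic, x$fn_somatic, x$tn_germline, x$fp_germline)
  )
}

#' @export
glance.sieve_eval <- function(x, ...) {
  tibble(
    sensitivity = x$sensitivity, specificity = x$specificity,
    tp = x$tp_somatic, fn = x$fn_somatic,
    tn = x$tn_germline, fp = x$fp_germline,
    n_evaluated = x$n_evaluated, n_unmatched = x$n_unmatched,
    n_filtered = x$n_filtered
  )
}

#' Confusion-matrix plot for an evaluation report
#'
#' @param object A `"sieve_eval"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sieve_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$truth, y = .data$predicted, fill = .data$n)) +
    geom_tile() +
    geom_text(aes(label = .data$n)) +
    labs(title = "Somatic-vs-germline confusion matrix",
         subtitle = sprintf("sensitivity %s, specificity %s",
                            format_metric(object$sensitivity),
                            format_metric(object$specificity))) +
    theme_minimal()
}

#' Write / read a truth set as TSV
#'
#' @param truth A `"sieve_truth"` tibble.
#' @param path Output path.
#' @return `path` invisibly (writer); a truth tibble (reader).
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(as_tibble(truth), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(c("chrom", "pos", "ref", "alt", "truth_label"), names(df))
  if (length(miss) > 0) {
    .stop_format(paste0("truth TSV missing column(s): ",
                        paste(miss, collapse = ", ")))
  }
  df$chrom <- as.character(df$chrom)
  class(df) <- c("sieve_truth", class(df))
  df
}
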