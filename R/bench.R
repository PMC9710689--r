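#' End-to-end synthetic benchmark of the tumor-only classifier
#'
#' Mirrors the paired-normal validation design at synthetic scale:
#' simulate a matched tumor/normal cohort with databases
#' ([simulate_cohort()]), classify the tumor calls tumor-only
#' ([classify_cohort()]), build the gold standard from the simulated pair
#' ([build_gold_standard()]), and score the predictions ([evaluate()]).
#' With complete, uncontaminated databases (`db_sensitivity = 1`,
#' `db_false_common = 0`, `cosmic_sensitivity = 1`,
#' `cosmic_germline_leak = 0`) the decision rules recover the truth
#' exactly, so sensitivity and specificity are both 1; degrading database
#' completeness degrades them in expectation.
#'
#' @param params A [sim_params()] object.
#' @param t A [thresholds()] object (defaults to targeted-sequencing mode).
#' @param clinvar_overrides_cosmic Passed to [classify_cohort()].
#' @param filtered Passed to [evaluate()].
#' @return A `"sieve_eval"` report carrying the full simulation parameters
#'   in its `"params"` attribute and the classified cohort in
#'   `"classified"`.
#' @examples
#' run_bench(sim_params(n_variants = 200, seed = 3))
#' @export
run_bench <- function(params, t = thresholds("TS"),
                      clinvar_overrides_cosmic = FALSE,
                      filtered = "exclude") {
  stopifnot(inherits(params, "sieve_sim_params"))
  sim <- simulate_cohort(params)
  classified <- suppressMessages(classify_cohort(
    sim$tumor, sim$dbs, t,
    clinvar_overrides_cosmic = clinvar_overrides_cosmic
  ))
  truth <- build_gold_standard(sim$tumor, sim$normal, t)
  report <- evaluate(classified, truth, filtered = filtered)
  attr(report, "params") <- unclass(params)
  attr(report, "classified") <- classified
  attr(report, "truth") <- truth
  report
}
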