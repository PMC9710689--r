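t_def <- thresholds("TS")

test_that("the matched-normal rule is strict at the 5% boundary", {
  tumor <- dplyr::bind_rows(
    make_call(pos = 10),  # matched at 48% -> germline
    make_call(pos = 20),  # matched at exactly 5% -> somatic (strict >)
    make_call(pos = 30),  # matched just above 5% -> germline
    make_call(pos = 40),  # absent from normal -> somatic
    make_call(pos = 50)   # matched at 1% -> somatic
  )
  normal <- dplyr::bind_rows(
    make_call(pos = 10, vaf = 0.48, sample_id = "N1"),
    make_call(pos = 20, vaf = 0.05, sample_id = "N1"),
    make_call(pos = 30, vaf = 0.0500001, sample_id = "N1"),
    make_call(pos = 50, vaf = 0.01, sample_id = "N1"),
    make_call(pos = 99, vaf = 0.50, sample_id = "N1")  # normal-only: ignored
  )
  truth <- build_gold_standard(tumor, normal, t_def)
  expect_equal(nrow(truth), 5)
  lab <- setNames(truth$truth_label, truth$pos)
  expect_equal(lab[["10"]], "germline")
  expect_equal(lab[["20"]], "somatic")
  expect_equal(lab[["30"]], "germline")
  expect_equal(lab[["40"]], "somatic")
  expect_equal(lab[["50"]], "somatic")
  expect_false(99 %in% truth$pos)
})

test_that("gold-standard matching is by normalized key, not spelling", {
  tumor <- make_call(pos = 100, ref = "CAA", alt = "CA",
                     consequence = "frameshift_variant")
  normal <- make_call(pos = 100, ref = "CAAT", alt = "CAT", vaf = 0.5,
                      sample_id = "N1", consequence = "frameshift_variant")
  truth <- build_gold_standard(normalize_variants(tumor),
                               normalize_variants(normal), t_def)
  expect_equal(truth$truth_label, "germline")
})

test_that("evaluation reproduces perfect and degenerate confusion matrices", {
  keys <- tibble::tibble(
    chrom = "1", pos = seq(10L, 200L, by = 10L), ref = "A", alt = "G"
  )
  truth <- keys
  truth$truth_label <- rep(c("somatic", "germline"), each = 10)
  class(truth) <- c("sieve_truth", class(truth))

  pred_perfect <- keys
  pred_perfect$label <- truth$truth_label
  rep <- evaluate(pred_perfect, truth)
  expect_equal(rep$sensitivity, 1.0)
  expect_equal(rep$specificity, 1.0)
  expect_equal(rep$n_evaluated, 20)

  pred_all_somatic <- keys
  pred_all_somatic$label <- "somatic"
  rep <- evaluate(pred_all_somatic, truth)
  expect_equal(rep$sensitivity, 1.0)
  expect_equal(rep$specificity, 0.0)

  # single-class truth leaves the other metric undefined
  truth_som <- truth[truth$truth_label == "somatic", ]
  rep <- evaluate(pred_perfect, truth_som)
  expect_true(is.na(rep$specificity))
  expect_equal(rep$sensitivity, 1.0)
  expect_equal(rep$n_unmatched, 10)
})

test_that("counts equal a brute-force per-key tally on random predictions", {
  set.seed(31)
  n <- 1000
  keys <- tibble::tibble(
    chrom = "1", pos = sample(seq(10L, 1e5L, by = 10L), n), ref = "A", alt = "G"
  )
  truth <- keys
  truth$truth_label <- sample(c("somatic", "germline"), n, TRUE)
  pred <- keys[sample(n, 900), ]  # some predicted keys missing from truth scope
  pred$label <- sample(c("somatic", "germline", "filtered"), 900, TRUE,
                       prob = c(0.45, 0.45, 0.1))
  rep <- evaluate(pred, truth)

  tally <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  for (i in seq_len(nrow(pred))) {
    if (pred$label[i] == "filtered") next
    j <- which(truth$pos == pred$pos[i])
    tl <- truth$truth_label[j]
    pl <- pred$label[i]
    if (tl == "somatic") {
      if (pl == "somatic") tally["tp"] <- tally["tp"] + 1 else tally["fn"] <- tally["fn"] + 1
    } else {
      if (pl == "germline") tally["tn"] <- tally["tn"] + 1 else tally["fp"] <- tally["fp"] + 1
    }
  }
  expect_equal(rep$tp_somatic, unname(tally["tp"]))
  expect_equal(rep$fn_somatic, unname(tally["fn"]))
  expect_equal(rep$tn_germline, unname(tally["tn"]))
  expect_equal(rep$fp_germline, unname(tally["fp"]))
  expect_equal(rep$tp_somatic + rep$fn_somatic + rep$tn_germline + rep$fp_germline,
               rep$n_evaluated)
})

test_that("label swap maps sensitivity and specificity onto each other exactly", {
  set.seed(37)
  n <- 400
  keys <- tibble::tibble(
    chrom = "1", pos = seq(10L, by = 10L, length.out = n), ref = "A", alt = "G"
  )
  truth <- keys; truth$truth_label <- sample(c("somatic", "germline"), n, TRUE)
  pred <- keys; pred$label <- sample(c("somatic", "germline"), n, TRUE)
  swap <- function(x) ifelse(x == "somatic", "germline", "somatic")
  truth_sw <- truth; truth_sw$truth_label <- swap(truth$truth_label)
  pred_sw <- pred; pred_sw$label <- swap(pred$label)
  a <- evaluate(pred, truth)
  b <- evaluate(pred_sw, truth_sw)
  expect_identical(a$sensitivity, b$specificity)
  expect_identical(a$specificity, b$sensitivity)
  expect_identical(a$tp_somatic, b$tn_germline)
  expect_identical(a$fn_somatic, b$fp_germline)
})

test_that("conflicting duplicate predictions are rejected; filtered handling is configurable", {
  keys <- tibble::tibble(chrom = "1", pos = c(10L, 10L), ref = "A", alt = "G")
  pred <- keys; pred$label <- c("somatic", "germline")
  truth <- keys[1, ]; truth$truth_label <- "somatic"
  expect_error(evaluate(pred, truth), "conflicting", class = "sieve_format_error")

  pred2 <- tibble::tibble(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "G",
                          label = c("filtered", "somatic"))
  truth2 <- tibble::tibble(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "G",
                           truth_label = c("germline", "somatic"))
  rep_ex <- evaluate(pred2, truth2)
  expect_equal(rep_ex$n_evaluated, 1)
  expect_equal(rep_ex$n_filtered, 1)
  rep_err <- evaluate(pred2, truth2, filtered = "as_error")
  expect_equal(rep_err$n_evaluated, 2)
  expect_equal(rep_err$fp_germline, 1)  # filtered germline-truth scored as error
})

test_that("truth sets and evaluation reports serialize round-trip", {
  sim <- simulate_cohort(sim_params(n_variants = 100, seed = 41))
  truth <- build_gold_standard(sim$tumor, sim$normal, t_def)
  path <- tempfile(fileext = ".tsv")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$truth_label, truth$truth_label)
  expect_identical(variant_key(back), variant_key(truth))

  rep <- evaluate(quiet_classify(sim$tumor, sim$dbs, t_def), truth)
  g <- glance(rep)
  expect_equal(g$tp + g$fn + g$tn + g$fp, g$n_evaluated)
  expect_equal(sum(tidy(rep)$n), rep$n_evaluated)
  expect_s3_class(autoplot(rep), "ggplot")
  expect_output(print(rep), "sensitivity")
})
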