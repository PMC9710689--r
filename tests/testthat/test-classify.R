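t_def <- thresholds("TS")

test_that("phase 1 gates depth, VAF, filter and consequence independently", {
  dbs <- make_empty_dbset()
  calls <- dplyr::bind_rows(
    make_call(pos = 10, total_depth = 100, alt_depth = 30),
    make_call(pos = 20, total_depth = 100, alt_depth = 30,
              consequence = "synonymous_variant"),
    make_call(pos = 30, total_depth = 5, alt_depth = 0, vaf = 0.02,
              filter_status = "q10"),
    make_call(pos = 40, total_depth = 0, alt_depth = 0, vaf = NA_real_)
  )
  p1 <- phase1_quality(annotate(calls, dbs), t_def)
  expect_equal(p1$pass1, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(p1$p1_reasons[[2]], "SYNONYMOUS")
  expect_setequal(p1$p1_reasons[[3]], c("FAIL_QUAL", "FAIL_DEPTH", "FAIL_VAF"))
  # zero depth can never pass: both depth and VAF gates fail
  expect_setequal(p1$p1_reasons[[4]], c("FAIL_DEPTH", "FAIL_VAF"))
})

test_that("phase 2 applies the 1% cutoff and the somatic-catalogue override", {
  dbs <- make_empty_dbset()
  base <- make_call()
  run_p2 <- function(...) {
    ann <- add_evidence(base, ...)
    attr(ann, "db_registry") <- somaticsieve:::db_registry(dbs)
    phase2_database(phase1_quality(ann, t_def), t_def, dbs)
  }
  # catalogue hit + germline AF: somatic with override reason
  r <- run_p2(af_exac = 0.015, cosmic = TRUE)
  expect_equal(r$p2_label, "somatic")
  expect_equal(r$p2_reasons[[1]], "COSMIC_OVERRIDE")
  # catalogue hit alone
  r <- run_p2(cosmic = TRUE)
  expect_equal(r$p2_reasons[[1]], "COSMIC")
  # population AF at 2%: germline, named by the qualifying database
  r <- run_p2(af_kg1000 = 0.02)
  expect_equal(r$p2_label, "germline")
  expect_equal(r$p2_reasons[[1]], "GERMLINE_DB:KG1000")
  # the highest-priority qualifying database wins the attribution
  r <- run_p2(af_kg1000 = 0.02, af_exac = 0.05)
  expect_equal(r$p2_reasons[[1]], "GERMLINE_DB:EXAC")
  # below the cutoff: undecided
  expect_equal(run_p2(af_esp = 0.009)$p2_label, "undecided")
  # inclusive boundary: exactly 1% is germline evidence
  expect_equal(run_p2(af_esp = 0.01)$p2_label, "germline")
  expect_equal(run_p2()$p2_label, "undecided")
})

test_that("phase 2 threshold behaviour matches direct comparison on an AF grid", {
  dbs <- make_empty_dbset()
  afs <- c(0.001, 0.005, 0.0099, 0.01, 0.0101, 0.02, 0.3, 0.5, 0.9)
  calls <- dplyr::bind_rows(purrr::imap(afs, function(af, i) {
    add_evidence(make_call(pos = i * 10), af_exac = af)
  }))
  attr(calls, "db_registry") <- somaticsieve:::db_registry(dbs)
  r <- phase2_database(phase1_quality(calls, t_def), t_def, dbs)
  expect_equal(r$p2_label, ifelse(afs >= 0.01, "germline", "undecided"))
  # with minor-allele folding, near-fixed alternate alleles stop qualifying
  dbs_fold <- make_empty_dbset(maf_folding = TRUE)
  r2 <- phase2_database(phase1_quality(calls, t_def), t_def, dbs_fold)
  expect_equal(r2$p2_label,
               ifelse(pmin(afs, 1 - afs) >= 0.01, "germline", "undecided"))
})

test_that("presence-only hits decide only when flagged common or explicitly enabled", {
  base <- make_call()
  run <- function(dbs, ...) {
    ann <- add_evidence(base, ...)
    quiet_classify(ann, dbs, t_def)
  }
  dbs <- make_empty_dbset()
  r <- run(dbs, in_dbsnp = TRUE, common_dbsnp = NA)
  expect_equal(r$label, "somatic")
  expect_equal(r$reasons[[1]][1], "NO_EVIDENCE_DEFAULT_SOMATIC")
  expect_equal(run(dbs, in_dbsnp = TRUE, common_dbsnp = TRUE)$label, "germline")
  dbs_on <- make_empty_dbset(dbsnp_presence_is_germline = TRUE)
  expect_equal(run(dbs_on, in_dbsnp = TRUE, common_dbsnp = NA)$label, "germline")
})

test_that("phase 3 rescues benign variants and defaults the rest to somatic", {
  dbs <- make_empty_dbset()
  run <- function(...) quiet_classify(add_evidence(make_call(), ...), dbs, t_def)
  r <- run(clinvar = "benign")
  expect_equal(r$label, "germline")
  expect_equal(r$phase, 3L)
  expect_equal(r$reasons[[1]][1], "CLINVAR_BENIGN")
  expect_equal(run(clinvar = "likely_benign")$label, "germline")
  # non-benign, mixed or conflicting assertions do not qualify
  expect_equal(run(clinvar = "pathogenic")$label, "somatic")
  expect_equal(run(clinvar = "benign,pathogenic")$label, "somatic")
  expect_equal(run(clinvar = "conflicting_interpretations_of_pathogenicity")$label,
               "somatic")
  # no clinical hit: default somatic at phase 0
  r <- run()
  expect_equal(r$label, "somatic")
  expect_equal(r$phase, 0L)
  expect_equal(r$reasons[[1]], "NO_EVIDENCE_DEFAULT_SOMATIC")
  # a phase-2 germline call is final; benign rescue is never consulted
  r <- run(af_exac = 0.30, clinvar = "benign")
  expect_equal(r$phase, 2L)
  expect_equal(r$reasons[[1]][1], "GERMLINE_DB:EXAC")
  # catalogue-somatic survives benign unless the switch inverts it
  r <- run(cosmic = TRUE, clinvar = "benign")
  expect_equal(r$label, "somatic")
  r2 <- quiet_classify(add_evidence(make_call(), cosmic = TRUE, clinvar = "benign"),
                       dbs, t_def, clinvar_overrides_cosmic = TRUE)
  expect_equal(r2$label, "germline")
  expect_equal(r2$phase, 3L)
})

test_that("classify matches the straight-line oracle on the full evidence truth table", {
  grid <- evidence_truth_table()
  n <- nrow(grid)
  calls <- make_call()[rep(1, n), ]
  calls$pos <- seq_len(n) * 10L
  calls$filter_status <- grid$qual
  calls$consequence <- grid$csq
  calls <- add_evidence(calls,
    af_exac = grid$exac, af_kg1000 = grid$kg1000, af_esp = grid$esp,
    af_dbsnp = grid$af_dbsnp, in_dbsnp = grid$in_dbsnp,
    common_dbsnp = grid$common_dbsnp,
    cosmic = grid$cosmic, clinvar = grid$clinvar
  )
  for (dbsnp_sw in c(FALSE, TRUE)) {
    for (fold_sw in c(FALSE, TRUE)) {
      for (clin_sw in c(FALSE, TRUE)) {
        dbs <- make_empty_dbset(dbsnp_presence_is_germline = dbsnp_sw,
                                maf_folding = fold_sw)
        got <- quiet_classify(calls, dbs, t_def,
                              clinvar_overrides_cosmic = clin_sw)$label
        want <- vapply(seq_len(n), function(i) {
          oracle_classify(
            grid$qual[i], 100L, 0.3, grid$csq[i],
            list(af = c(grid$exac[i], grid$kg1000[i], grid$esp[i], grid$af_dbsnp[i]),
                 dbsnp_present = grid$in_dbsnp[i],
                 dbsnp_common = grid$common_dbsnp[i],
                 cosmic = grid$cosmic[i], clinvar = grid$clinvar[i]),
            t_def,
            dbsnp_presence_is_germline = dbsnp_sw,
            maf_folding = fold_sw,
            clinvar_overrides_cosmic = clin_sw
          )
        }, character(1))
        expect_identical(got, want)
      }
    }
  }
})

test_that("classification is total, deterministic and order-independent", {
  sim <- simulate_cohort(sim_params(n_variants = 500, seed = 13))
  res <- quiet_classify(sim$tumor, sim$dbs, t_def)
  expect_true(all(res$label %in% c("filtered", "somatic", "germline")))
  expect_true(all(res$label[res$pass1] %in% c("somatic", "germline")))
  expect_true(all(lengths(res$reasons) > 0))
  expect_true(all((res$label == "filtered") == (res$phase == 1L)))

  res2 <- quiet_classify(sim$tumor, sim$dbs, t_def)
  expect_identical(res$label, res2$label)

  perm <- sample(nrow(sim$tumor))
  res_perm <- quiet_classify(sim$tumor[perm, ], sim$dbs, t_def)
  expect_identical(res_perm$label, res$label[perm])
  expect_identical(res_perm$reasons, res$reasons[perm])
})

test_that("raising the MAF cutoff never converts somatic calls to germline", {
  sim <- simulate_cohort(sim_params(n_variants = 600, seed = 17))
  cutoffs <- c(0.005, 0.01, 0.02, 0.05)
  germline_sets <- purrr::map(cutoffs, function(cut) {
    t <- thresholds("TS", germline_maf_cutoff = cut)
    res <- quiet_classify(sim$tumor, sim$dbs, t)
    variant_key(res[res$label == "germline", ])
  })
  for (i in seq_len(length(cutoffs) - 1)) {
    expect_true(all(germline_sets[[i + 1]] %in% germline_sets[[i]]))
  }
})

test_that("adding a somatic-catalogue hit never yields a germline label", {
  sim <- simulate_cohort(sim_params(n_variants = 400, seed = 19))
  ann <- annotate(sim$tumor, sim$dbs)
  base <- quiet_classify(ann, sim$dbs, t_def)
  forced <- ann
  forced$in_cosmic <- TRUE
  forced$cosmic_id <- dplyr::coalesce(forced$cosmic_id, "COSM_FORCED")
  res <- quiet_classify(forced, sim$dbs, t_def)
  expect_false(any(res$label == "germline"))
  # and previously somatic calls stay somatic
  expect_true(all(res$label[base$label == "somatic"] == "somatic"))
})

test_that("cohort summaries and tidiers report the label composition", {
  sim <- simulate_cohort(sim_params(n_variants = 200, seed = 23))
  expect_message(res <- classify_cohort(sim$tumor, sim$dbs, t_def), "classified")
  g <- glance(res)
  expect_equal(g$n, 200)
  expect_equal(g$n_filtered + g$n_somatic + g$n_germline, 200)
  td <- tidy(res)
  expect_equal(nrow(td), 200)
  expect_true(all(c("label", "phase", "deciding_reason") %in% names(td)))
  expect_s3_class(autoplot(res), "ggplot")
})
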