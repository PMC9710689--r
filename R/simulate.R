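#' Parameters for the synthetic tumor/normal cohort generator
#'
#' Defines the study conditions the simulator emulates: a matched
#' tumor/normal pair from a deep targeted assay, with evidence databases of
#' configurable completeness and contamination. Defaults describe a
#' realistic targeted-panel cohort: a 57/43 germline/somatic split (the
#' class balance typically observed in paired targeted validation cohorts),
#' mean depth 200x, tumor purity 0.8, germline databases that catalogue 90%
#' of true germline variants at common frequency, a somatic catalogue
#' holding 80% of true somatic variants while leaking 2% of germline ones,
#' and benign clinical assertions on 30% of germline variants.
#'
#' @param n_variants Number of distinct variants (> 0).
#' @param germline_fraction Probability a variant is truth-germline.
#' @param db_sensitivity Per-database probability that a truth-germline
#'   variant is present in a germline population database at an allele
#'   frequency at/above the 1% cutoff.
#' @param db_false_common Probability that a truth-somatic variant
#'   erroneously appears in a germline database at/above the cutoff.
#' @param cosmic_sensitivity Probability a truth-somatic variant is in the
#'   somatic catalogue.
#' @param cosmic_germline_leak Probability a truth-germline variant is in
#'   the somatic catalogue (catalogues do harbour some germline variants).
#' @param clinvar_benign_rate Probability a truth-germline variant carries
#'   a benign/likely-benign clinical record.
#' @param clinvar_pathogenic_rate Probability a truth-somatic variant
#'   carries a pathogenic clinical record (non-deciding evidence).
#' @param tumor_purity Tumor cell fraction; expected somatic tumor VAF is
#'   `tumor_purity / 2`.
#' @param mean_depth Mean sequencing depth (Poisson).
#' @param indel_fraction Fraction of variants generated as 1-3 bp indels
#'   (written non-parsimoniously to exercise normalization).
#' @param synonymous_fraction Fraction of variants given a synonymous
#'   consequence (these fail phase 1 by design).
#' @param db_rare_rate Probability of an additional sub-cutoff (rare)
#'   population-database record for any variant; non-deciding evidence.
#' @param contig Name of the synthetic contig.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A validated list of class `"sieve_sim_params"`.
#' @export
sim_params <- function(n_variants = 1000,
                       germline_fraction = 0.57,
                       db_sensitivity = 0.9,
                       db_false_common = 0.01,
                       cosmic_sensitivity = 0.8,
                       cosmic_germline_leak = 0.02,
                       clinvar_benign_rate = 0.3,
                       clinvar_pathogenic_rate = 0.1,
                       tumor_purity = 0.8,
                       mean_depth = 200,
                       indel_fraction = 0.1,
                       synonymous_fraction = 0.1,
                       db_rare_rate = 0.05,
                       contig = "1",
                       seed = 1L) {
  p <- list(
    n_variants = as.integer(n_variants),
    germline_fraction = germline_fraction,
    db_sensitivity = db_sensitivity,
    db_false_common = db_false_common,
    cosmic_sensitivity = cosmic_sensitivity,
    cosmic_germline_leak = cosmic_germline_leak,
    clinvar_benign_rate = clinvar_benign_rate,
    clinvar_pathogenic_rate = clinvar_pathogenic_rate,
    tumor_purity = tumor_purity,
    mean_depth = as.integer(mean_depth),
    indel_fraction = indel_fraction,
    synonymous_fraction = synonymous_fraction,
    db_rare_rate = db_rare_rate,
    contig = as.character(contig),
    seed = as.integer(seed)
  )
  if (is.na(p$n_variants) || p$n_variants < 1L) {
    .stop_config("n_variants must be a positive integer")
  }
  probs <- c("germline_fraction", "db_sensitivity", "db_false_common",
             "cosmic_sensitivity", "cosmic_germline_leak",
             "clinvar_benign_rate", "clinvar_pathogenic_rate",
             "tumor_purity", "indel_fraction", "synonymous_fraction",
             "db_rare_rate")
  for (nm in probs) {
    v <- p[[nm]]
    if (!is.numeric(v) || is.na(v) || v < 0 || v > 1) {
      .stop_config(paste0(nm, " must be a probability in [0, 1]"))
    }
  }
  if (p$mean_depth < 1L) .stop_config("mean_depth must be >= 1")
  structure(p, class = "sieve_sim_params")
}

#' Simulate an annotated tumor/normal cohort with known truth
#'
#' Draws a deterministic cohort from [sim_params()]: germline variants are
#' heterozygous (true allele fraction 0.5) or homozygous (1.0) in both
#' samples; somatic variants are absent from the normal and present in the
#' tumor at `tumor_purity / 2`. Observed depths are Poisson around
#' `mean_depth` and alternate-read counts binomial given depth and the true
#' allele fraction — the simplest noise model consistent with depth-based
#' thresholds. Database membership is drawn per the Bernoulli rates in the
#' parameters. Positions are unique and spaced so indels never collide;
#' indel records are written with an extra shared trailing base so that
#' readers must normalize them.
#'
#' @param params A [sim_params()] object.
#' @param dir If non-`NULL`, the cohort is also written to this directory
#'   as `tumor.vcf`, `normal.vcf`, `truth.tsv`, one TSV per database, and
#'   a `config.yaml` declaring the database set.
#' @return A list of class `"sieve_sim"` with elements `tumor`, `normal`
#'   (call tibbles), `truth` (a `"sieve_truth"` tibble), `dbs` (a
#'   [db_set()]), `params`, and (when written) `files`.
#' @examples
#' sim <- simulate_cohort(sim_params(n_variants = 50, seed = 7))
#' table(sim$truth$truth_label)
#' @export
simulate_cohort <- function(params, dir = NULL) {
  stopifnot(inherits(params, "sieve_sim_params"))
  sim <- withr::with_seed(params$seed, generate_cohort(params))
  sim$params <- params
  class(sim) <- "sieve_sim"
  if (!is.null(dir)) sim$files <- write_cohort(sim, dir)
  sim
}

generate_cohort <- function(p) {
  n <- p$n_variants
  bases <- c("A", "C", "G", "T")
  # spacing >= 6 keeps 1-3 bp indels (plus padding base) from overlapping
  pos <- sort(sample(seq(10L, n * 20L, by = 6L), n))
  is_germ <- runif(n) < p$germline_fraction
  is_indel <- runif(n) < p$indel_fraction

  ref <- sample(bases, n, replace = TRUE)
  alt <- map_chr(ref, ~ sample(setdiff(bases, .x), 1))
  indel_len <- sample(1:3, n, replace = TRUE)
  ins <- runif(n) < 0.5
  for (i in which(is_indel)) {
    extra <- paste(sample(bases, indel_len[i], replace = TRUE), collapse = "")
    if (ins[i]) {
      alt[i] <- paste0(ref[i], extra)
    } else {
      ref[i] <- paste0(ref[i], extra)
      alt[i] <- substr(ref[i], 1, 1)
    }
  }

  true_tumor_af <- if_else(
    is_germ,
    if_else(runif(n) < 2 / 3, 0.5, 1.0),
    p$tumor_purity / 2
  )
  true_normal_af <- if_else(is_germ, true_tumor_af, 0)

  draw_sample <- function(true_af, sample_id) {
    depth <- pmax(rpois(n, p$mean_depth), 1L)
    altd <- rbinom(n, depth, true_af)
    tibble(
      sample_id = sample_id,
      chrom = p$contig, pos = pos, ref = ref, alt = alt,
      total_depth = as.integer(depth), alt_depth = as.integer(altd),
      vaf = altd / depth,
      filter_status = "PASS",
      consequence = NA_character_
    )
  }
  csq <- if_else(
    runif(n) < p$synonymous_fraction,
    "synonymous_variant",
    sample(default_consequence_whitelist(), n, replace = TRUE)
  )
  tumor <- draw_sample(true_tumor_af, "TUMOR")
  tumor$consequence <- csq
  normal <- draw_sample(true_normal_af, "NORMAL")
  normal$consequence <- csq
  # normal calls are restricted to sites with any alt evidence, as a caller would emit
  normal <- filter(normal, .data$alt_depth > 0)

  key <- tibble(chrom = p$contig, pos = pos, ref = ref, alt = alt)
  key_norm <- normalize_variants(key)

  pop_db <- function(name, priority) {
    member <- if_else(is_germ, runif(n) < p$db_sensitivity,
                      runif(n) < p$db_false_common)
    rare <- !member & runif(n) < p$db_rare_rate
    af <- rep(NA_real_, n)
    af[member] <- runif(sum(member), 0.01, 0.5)
    af[rare] <- runif(sum(rare), 1e-4, 0.009)
    rec <- key_norm[member | rare, ]
    rec$af <- af[member | rare]
    rec$common_flag <- rec$af >= 0.01
    new_sieve_db(name, "population", priority, rec)
  }
  dbsnp_db <- function(priority) {
    member <- if_else(is_germ, runif(n) < p$db_sensitivity,
                      runif(n) < p$db_false_common)
    rare <- !member & runif(n) < p$db_rare_rate
    rec <- key_norm[member | rare, ]
    rec$af <- NA_real_                      # presence-only source
    rec$common_flag <- member[member | rare]
    new_sieve_db("DBSNP", "population", priority, rec)
  }
  cosmic_member <- if_else(is_germ, runif(n) < p$cosmic_germline_leak,
                           runif(n) < p$cosmic_sensitivity)
  cosmic_rec <- key_norm[cosmic_member, ]
  cosmic_rec$catalogue_id <- sprintf("COSM%06d", which(cosmic_member))
  cosmic_rec$occurrence_count <- rpois(sum(cosmic_member), 4L) + 1L
  clin_benign <- is_germ & runif(n) < p$clinvar_benign_rate
  clin_path <- !is_germ & runif(n) < p$clinvar_pathogenic_rate
  clin_rec <- key_norm[clin_benign | clin_path, ]
  clin_rec$significance <- if_else(
    clin_benign[clin_benign | clin_path],
    sample(c("benign", "likely_benign", "benign,likely_benign"),
           nrow(clin_rec), replace = TRUE),
    "pathogenic"
  )

  dbs <- db_set(
    pop_db("EXAC", 1L),
    pop_db("KG1000", 2L),
    pop_db("ESP", 3L),
    dbsnp_db(4L),
    new_sieve_db("COSMIC", "somatic", NA_integer_, cosmic_rec),
    new_sieve_db("CLINVAR", "clinical", NA_integer_, clin_rec)
  )

  truth <- key_norm
  truth$truth_label <- if_else(is_germ, "germline", "somatic")
  class(truth) <- c("sieve_truth", class(truth))

  list(tumor = tumor, normal = normal, truth = truth, dbs = dbs)
}

new_sieve_db <- function(name, kind, priority, records) {
  structure(
    list(name = toupper(name), kind = kind,
         priority = as.integer(priority), records = as_tibble(records)),
    class = "sieve_db"
  )
}

#' Write a simulated cohort to disk in the standard formats
#'
#' @param sim A `"sieve_sim"` object from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sieve_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    tumor = file.path(dir, "tumor.vcf"),
    normal = file.path(dir, "normal.vcf"),
    truth = file.path(dir, "truth.tsv")
  )
  write_variants(pad_indels(sim$tumor), files[["tumor"]], "vcf")
  write_variants(pad_indels(sim$normal), files[["normal"]], "vcf")
  write_truth(sim$truth, files[["truth"]])

  db_decl <- list()
  for (db in c(sim$dbs$population,
               list(sim$dbs$somatic, sim$dbs$clinical))) {
    if (is.null(db)) next
    f <- file.path(dir, paste0("db_", tolower(db$name), ".tsv"))
    rec <- db$records
    out <- switch(db$kind,
      population = rename(rec, common = "common_flag"),
      somatic = rename(rec, id = "catalogue_id", count = "occurrence_count"),
      clinical = rec
    )
    readr::write_tsv(out, f)
    files[[paste0("db_", tolower(db$name))]] <- f
    db_decl[[tolower(db$name)]] <- list(
      path = basename(f), kind = db$kind, name = db$name,
      priority = if (is.na(db$priority)) NULL else db$priority,
      format = "tsv"
    )
  }
  cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(list(
    mode = "TS",
    switches = list(
      dbsnp_presence_is_germline = sim$dbs$dbsnp_presence_is_germline,
      maf_folding = sim$dbs$maf_folding
    ),
    databases = db_decl
  ), cfg)
  files[["config"]] <- cfg
  invisible(files)
}

# Re-spell indels non-parsimoniously (one shared trailing base) so that the
# reader's normalization path is exercised by simulated files.
pad_indels <- function(calls) {
  is_indel <- nchar(calls$ref) != nchar(calls$alt)
  # deterministic pad base so written files are byte-identical across runs
  pad <- c("A", "C", "G", "T")[(calls$pos[is_indel] %% 4) + 1]
  calls$ref[is_indel] <- paste0(calls$ref[is_indel], pad)
  calls$alt[is_indel] <- paste0(calls$alt[is_indel], pad)
  calls
}
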