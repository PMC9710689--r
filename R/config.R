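#' Read a run configuration file
#'
#' The configuration is a nestable key-value YAML file declaring the assay
#' mode, threshold overrides, evidence-interpretation switches and the
#' database files, e.g.:
#'
#' ```yaml
#' mode: TS
#' thresholds:
#'   min_vaf: 0.05
#'   min_depth: 50
#' switches:
#'   dbsnp_presence_is_germline: false
#'   maf_folding: false
#'   clinvar_overrides_cosmic: false
#'   chr_policy: strip
#' databases:
#'   exac: {path: db_exac.tsv, kind: population, name: EXAC, priority: 1, format: tsv}
#'   cosmic: {path: db_cosmic.tsv, kind: somatic, name: COSMIC, format: tsv}
#' ```
#'
#' Relative database paths are resolved against the config file's
#' directory. Unknown top-level keys are rejected.
#'
#' @param path Path to the YAML configuration.
#' @return A list of class `"sieve_config"` with elements `mode`,
#'   `thresholds` (a [thresholds()] object), `switches` and `databases`
#'   (declarations; load them with [load_config_dbs()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stop_config(paste0("config file not found: ", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) .stop_config(paste0("cannot parse config: ", conditionMessage(e))))
  known <- c("mode", "thresholds", "switches", "databases", "out_prefix", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    .stop_config(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  mode <- raw$mode %||% "TS"
  if (!mode %in% c("TS", "WES")) .stop_config("mode must be TS or WES")
  th_over <- raw$thresholds %||% list()
  th <- do.call(thresholds, c(list(mode = mode), th_over))
  sw <- modifyList(
    list(dbsnp_presence_is_germline = FALSE, maf_folding = FALSE,
         clinvar_overrides_cosmic = FALSE, chr_policy = "strip"),
    raw$switches %||% list()
  )
  if (!sw$chr_policy %in% c("strip", "add", "asis")) {
    .stop_config("chr_policy must be strip, add or asis")
  }
  dbs <- raw$databases %||% list()
  cfgdir <- dirname(normalizePath(path, mustWork = TRUE))
  dbs <- map(dbs, function(d) {
    if (is.null(d$path)) .stop_config("each database declaration needs a path")
    if (!grepl("^(/|[A-Za-z]:)", d$path)) d$path <- file.path(cfgdir, d$path)
    d
  })
  structure(
    list(mode = mode, thresholds = th, switches = sw, databases = dbs,
         out_prefix = raw$out_prefix, log_level = raw$log_level %||% "info",
         path = path),
    class = "sieve_config"
  )
}

#' Load every database declared in a run configuration
#'
#' @param config A `"sieve_config"` from [read_run_config()].
#' @return A [db_set()] with the configured switches applied.
#' @export
load_config_dbs <- function(config) {
  stopifnot(inherits(config, "sieve_config"))
  dbs <- map(config$databases, function(d) {
    load_database(
      d$path, kind = d$kind %||% "population",
      name = d$name %||% toupper(tools::file_path_sans_ext(basename(d$path))),
      priority = d$priority %||% NA_integer_,
      format = d$format %||% "auto",
      af_key = d$af_key %||% "AF",
      chr_policy = config$switches$chr_policy
    )
  })
  db_set(unname(dbs),
         dbsnp_presence_is_germline = config$switches$dbsnp_presence_is_germline,
         maf_folding = config$switches$maf_folding)
}

#' Validate a run configuration before computing
#'
#' Checks that every declared database file exists and parses at the
#' declared format, that thresholds are in range, and that population
#' priorities are unique. Mirrors a workflow "check inputs" step: it
#' returns an itemized findings table rather than stopping at the first
#' problem.
#'
#' @param config A `"sieve_config"` object or the path to a config file.
#' @return A tibble of findings with columns `level` (`"error"`/`"warning"`),
#'   `item` and `message`; zero rows means the configuration passed. The
#'   logical attribute `"ok"` summarises the outcome.
#' @export
check_inputs <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "sieve_config"))
  findings <- list()
  note <- function(level, item, message) {
    findings[[length(findings) + 1]] <<- tibble(
      level = level, item = item, message = message
    )
  }

  t <- config$thresholds
  if (t$min_vaf < 0 || t$min_vaf > 1) {
    note("error", "thresholds.min_vaf", "must be in [0, 1]")
  }
  if (t$min_depth < 0) note("error", "thresholds.min_depth", "must be >= 0")

  if (length(config$databases) == 0) {
    note("warning", "databases", "no databases declared; phase 2/3 will see no evidence")
  }
  prios <- compact(map(config$databases, "priority"))
  if (length(prios) > 0 && anyDuplicated(unlist(prios))) {
    note("error", "databases.priority", "population priorities must be unique")
  }
  for (nm in names(config$databases)) {
    d <- config$databases[[nm]]
    item <- paste0("databases.", nm)
    if (!file.exists(d$path)) {
      note("error", item, paste0("file not found: ", d$path))
      next
    }
    kind <- d$kind %||% "population"
    if (!kind %in% c("population", "somatic", "clinical")) {
      note("error", item, paste0("unknown kind: ", kind))
      next
    }
    ok <- tryCatch({
      load_database(d$path, kind = kind, name = d$name %||% nm,
                    format = d$format %||% "auto", af_key = d$af_key %||% "AF")
      TRUE
    }, error = function(e) {
      note("error", item, conditionMessage(e))
      FALSE
    })
    invisible(ok)
  }
  out <- if (length(findings)) list_rbind(findings) else
    tibble(level = character(), item = character(), message = character())
  attr(out, "ok") <- !any(out$level == "error")
  out
}
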