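#' Validate pipeline inputs without mutating them
#'
#' Checks the schema and plausibility of every input referenced by a run
#' configuration and returns the full list of problems found (empty when
#' everything is consistent): missing files, missing columns, negative
#' expression values, cohorts without age metadata, plates without anchor
#' conditions.
#'
#' @param config Run configuration list (see [run_full()]) or YAML path.
#' @return Character vector of problems (length 0 when clean).
#' @export
validate_inputs <- function(config) {
  config <- load_run_config(config)
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)
  if (is.null(config$panel)) {
    note("no panel input configured")
  } else if (!file.exists(config$panel)) {
    note(paste0("panel file not found: ", config$panel))
  } else {
    panel <- tryCatch(read_panel(config$panel), error = function(e) e)
    if (inherits(panel, "error")) {
      note(paste0("panel: ", conditionMessage(panel)))
    }
  }
  if (!is.null(config$cohort)) {
    if (!file.exists(config$cohort)) {
      note(paste0("cohort file not found: ", config$cohort))
    } else {
      cohort <- tryCatch(read_cohort(config$cohort), error = function(e) e)
      if (inherits(cohort, "error")) {
        note(paste0("cohort: ", conditionMessage(cohort)))
      } else if (all(is.na(cohort$age))) {
        note("cohort has no usable age metadata")
      }
    }
  }
  for (f in c(surrogate_config = config$surrogate_config,
              hela_concentrations = config$hela_concentrations)) {
    if (!is.null(f) && !file.exists(f)) note(paste0("config file not found: ", f))
  }
  problems
}

load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config$seed <- config$seed %||% 1L
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates fit, classification, optional cohort projection, and the
#' two surrogate models, writing a reproducible report bundle: `model.yaml`,
#' `classifications.tsv`, `cohort_summary.json`, `eta.tsv`,
#' `competence.tsv`, and `run.log`. Every table carries a header comment
#' with package version, configuration hash and seed; rerunning the same
#' configuration reproduces the outputs bit-for-bit.
#'
#' @param config List (or YAML path) with elements: `panel` (labelled panel
#'   TSV, required), `cohort` (optional mRNA TSV), `surrogate_config` and
#'   `hela_concentrations` (optional YAML overrides), `quantile_policy`
#'   (out-of-IQR handling for patient inference; the pipeline defaults to
#'   `"clamp"` so ratio-based functional groups stay defined at the cohort
#'   tails), `mimetics` (optional named doses in uM for in-silico
#'   administration), `seed`, `outdir`.
#' @return Invisibly, the list of written file paths.
#' @export
run_full <- function(config) {
  config <- load_run_config(config)
  problems <- validate_inputs(config)
  if (length(problems)) {
    stop("input validation failed:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  outdir <- config$outdir %||% "apoptosense_run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- config_hash(config)
  stamp <- sprintf(
    "# apoptosense %s | config %s | seed %s",
    as.character(utils::packageVersion("apoptosense")), cfg_hash, config$seed)
  logf <- file.path(outdir, "run.log")
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = logf, append = TRUE)
  }
  cat(stamp, "\n", file = logf)
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  write_tsv_stamped <- function(df, path) {
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }

  panel <- run_stage("read_panel", read_panel(config$panel))
  model <- run_stage("fit", fit_sensitivity_model(panel))
  write_sensitivity_model(model, file.path(outdir, "model.yaml"))
  log_line("fit", sprintf("retained %d components; shrinkage %.3g",
                          model$pca$n_retained, model$lda$shrinkage))
  cls <- run_stage("classify", classify(model, panel))
  write_tsv_stamped(cls, file.path(outdir, "classifications.tsv"))

  if (!is.null(config$cohort)) {
    cohort <- run_stage("read_cohort", read_cohort(config$cohort))
    cohort <- run_stage("filter_paediatric", filter_paediatric(cohort))
    map <- run_stage("quantile_map", fit_quantile_map(
      cohort, panel, policy = config$quantile_policy %||% "clamp"))
    proj <- run_stage("project", project_cohort(cohort, model, map))
    jsonlite::write_json(
      list(meta = stamp, removed = as.list(attr(cohort, "removed")),
           summary = proj$summary),
      file.path(outdir, "cohort_summary.json"), auto_unbox = TRUE, digits = NA)
    log_line("project", sprintf("%d patients projected", nrow(proj$patients)))
  } else {
    jsonlite::write_json(list(meta = stamp, summary = NULL),
                         file.path(outdir, "cohort_summary.json"),
                         auto_unbox = TRUE)
  }

  scfg <- if (is.null(config$surrogate_config)) default_surrogate_config()
          else read_surrogate_config(config$surrogate_config)
  hela <- if (is.null(config$hela_concentrations)) default_hela_concentrations()
          else read_hela_concentrations(config$hela_concentrations)
  conc <- to_concentrations(panel, hela)
  mim <- unlist(config$mimetics) %||% numeric()
  eta_tab <- run_stage("eta", {
    do.call(rbind, lapply(rownames(conc), function(id) {
      st <- bcl2_state(conc[id, c("BAX", "BAK", "BCL2", "BCLXL", "MCL1")],
                       mimetics = mim)
      sd_res <- stress_dose(st, scfg)
      data.frame(sample_id = id, eta_uM = sd_res$eta,
                 reachable = sd_res$reachable)
    }))
  })
  write_tsv_stamped(eta_tab, file.path(outdir, "eta.tsv"))

  comp_tab <- run_stage("execute", {
    do.call(rbind, lapply(rownames(conc), function(id) {
      traj <- simulate_caspase_execution(
        conc[id, c("APAF1", "CASP9", "CASP3", "SMAC", "XIAP")],
        rates = scfg$caspase_rates)
      data.frame(sample_id = id,
                 cleaved_60min = traj$cleaved[which.min(abs(traj$time - 60))],
                 competent = is_execution_competent(traj))
    }))
  })
  write_tsv_stamped(comp_tab, file.path(outdir, "competence.tsv"))
  log_line("done", "all stages complete")
  invisible(file.path(outdir, c("model.yaml", "classifications.tsv",
                                "cohort_summary.json", "eta.tsv",
                                "competence.tsv", "run.log")))
}

# order-independent hash of the configuration document
config_hash <- function(config) {
  config$outdir <- NULL
  s <- yaml::as.yaml(config[order(names(config))])
  # small stable polynomial hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
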