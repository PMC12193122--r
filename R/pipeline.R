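# End-to-end orchestration: simulate (or read) summary statistics, select
# instruments, run the estimator battery and sensitivity analyses for the
# total effect and both mediation steps, compose the mediation table, and
# optionally run the fingerprint screen. Every artifact is a UTF-8 TSV or
# JSON under out_dir; all stochastic stages derive their seeds from the
# single configured seed, so a rerun of the same config is numerically
# identical.

#' Run the two-sample / two-step MR mediation pipeline
#'
#' @param config A list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{seed}{Master seed; mandatory, validated before any compute.}
#'     \item{simulation}{Arguments for [simulation_config()] (its own `seed`
#'       defaults to the master seed), or omitted when `tables` given.}
#'     \item{tables}{Paths `exposure`, `mediator`, `outcome`, optional `ld`.}
#'     \item{selection}{Arguments for [selection_config()] (optional).}
#'     \item{ivw_model}{`"random"` (default) or `"fixed"`.}
#'     \item{n_boot, n_sim}{Weighted-median bootstrap and PRESSO simulation
#'       counts (defaults 1000 each).}
#'     \item{alpha}{Significance gate for mediation steps (default 0.05):
#'       step 1 runs only when the total-effect IVW p is below it, step 2
#'       only when the step-1 IVW p also is. Set `gate = FALSE` to always
#'       evaluate.}
#'     \item{radial, radial_alpha}{Radial outlier pruning during selection
#'       (defaults `TRUE`, 0.05).}
#'     \item{presso}{Run MR-PRESSO sensitivity analysis (default `TRUE`).}
#'     \item{screen}{Optional list with `candidates`, `references`
#'       fingerprint TSV paths, `nbits` and `top_k`.}
#'     \item{out_dir}{Output directory (created if missing).}
#'   }
#' @param out_dir Overrides `config$out_dir`.
#' @return Invisibly, the report bundle: instrument sets, `mr_fit`s,
#'   `mr_presso` results, the `mediation_result` (or `NULL` when gated out),
#'   screen hits, and the provenance list. Artifacts written: the input (or
#'   simulated) tables, `mr_results.tsv`, `sensitivity.tsv`,
#'   `mediation.tsv`, `screen.tsv`, `provenance.json`, `run.log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1) config <- read_pipeline_config(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("pipeline config must set a seed")
  seed <- as.integer(config$seed)
  out_dir <- out_dir %||% config$out_dir %||% stop("pipeline config must set out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_path <- file.path(out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message("[mrmediate] ", line)
    log_lines <<- c(log_lines, line)
  }
  say("mrmediate %s pipeline run, seed %d",
      as.character(utils::packageVersion("mrmediate")), seed)

  cfg_sel <- do.call(selection_config, config$selection %||% list())
  ivw_model <- config$ivw_model %||% "random"
  n_boot <- config$n_boot %||% 1000
  n_sim <- config$n_sim %||% 1000
  alpha <- config$alpha %||% 0.05
  gate <- config$gate %||% TRUE
  use_radial <- config$radial %||% TRUE
  radial_alpha <- config$radial_alpha %||% 0.05
  use_presso <- config$presso %||% TRUE

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    sim <- simulate_mediation_gwas(do.call(simulation_config, sim_args))
    exposure <- sim$exposure; mediator <- sim$mediator; outcome <- sim$outcome
    ld <- sim$ld; truth <- sim$truth
    write_gwas_table(exposure, file.path(out_dir, "exposure.tsv"))
    write_gwas_table(mediator, file.path(out_dir, "mediator.tsv"))
    write_gwas_table(outcome, file.path(out_dir, "outcome.tsv"))
    write_truth(truth, file.path(out_dir, "truth.json"))
    say("simulated %d exposure + %d mediator instruments",
        length(truth$gamma), length(truth$delta))
  } else if (!is.null(config$tables)) {
    tb <- config$tables
    exposure <- read_gwas_table(tb$exposure, trait_name = "exposure")
    mediator <- read_gwas_table(tb$mediator, trait_name = "mediator")
    outcome <- read_gwas_table(tb$outcome, trait_name = "outcome",
                               trait_type = "binary")
    ld <- if (!is.null(tb$ld)) read_ld(tb$ld) else NULL
    say("read tables: %d/%d/%d records", n_records(exposure),
        n_records(mediator), n_records(outcome))
  } else {
    stop("pipeline config needs either 'simulation' or 'tables'")
  }

  fit_step <- function(exp_tab, out_tab, label, wm_seed, presso_seed) {
    set <- select_instruments(exp_tab, out_tab, ld = ld, cfg = cfg_sel,
                              radial = use_radial, radial_alpha = radial_alpha)
    say("%s: %d instrument(s) after selection", label, n_instruments(set))
    fit <- mr_fit(set, model = ivw_model, n_boot = n_boot, seed = wm_seed)
    pres <- if (use_presso && n_instruments(set) >= 4) {
      mr_presso(set, n_sim = n_sim, seed = presso_seed, model = ivw_model)
    } else NULL
    list(set = set, fit = fit, presso = pres, label = label)
  }

  # --- total effect, step 1, step 2 --------------------------------------
  total <- fit_step(exposure, outcome, "total (exposure->outcome)",
                    seed + 11L, seed + 12L)
  p_total <- total$fit$estimates$pvalue[total$fit$estimates$method == "IVW"]
  step1 <- step2 <- NULL
  mediation <- NULL
  if (!gate || p_total < alpha) {
    step1 <- fit_step(exposure, mediator, "step1 (exposure->mediator)",
                      seed + 21L, seed + 22L)
    p_a <- step1$fit$estimates$pvalue[step1$fit$estimates$method == "IVW"]
    if (!gate || p_a < alpha) {
      step2 <- fit_step(mediator, outcome, "step2 (mediator->outcome)",
                        seed + 31L, seed + 32L)
      mediation <- mediate(total$fit, step1$fit, step2$fit,
                           exposure = exposure$trait_name,
                           mediator = mediator$trait_name,
                           outcome = outcome$trait_name)
      say("mediation: indirect %.4g (p %.3g), |proportion| %.2f%%",
          mediation$indirect, mediation$p_indirect, mediation$proportion_abs)
    } else {
      say("step1 IVW p = %.3g >= %.2g: mediation gated out", p_a, alpha)
    }
  } else {
    say("total-effect IVW p = %.3g >= %.2g: mediation gated out", p_total, alpha)
  }

  # --- artifacts ----------------------------------------------------------
  steps <- Filter(Negate(is.null), list(total = total, step1 = step1, step2 = step2))
  mr_rows <- do.call(rbind, lapply(names(steps), function(nm) {
    s <- steps[[nm]]
    est <- s$fit$estimates
    if (!is.null(s$presso)) {
      est <- rbind(est, s$presso$raw_estimate, s$presso$corrected_estimate)
    }
    cbind(step = nm, est)
  }))
  utils::write.table(mr_rows, file.path(out_dir, "mr_results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sens_rows <- do.call(rbind, lapply(names(steps), function(nm) {
    s <- steps[[nm]]
    het <- s$fit$heterogeneity
    int <- s$fit$estimates[s$fit$estimates$method == "Egger-intercept", ]
    data.frame(step = nm,
               q_ivw = het$Q[het$method == "IVW"], q_ivw_p = het$pvalue[het$method == "IVW"],
               q_egger = het$Q[het$method == "Egger"], q_egger_p = het$pvalue[het$method == "Egger"],
               egger_intercept = int$beta, egger_intercept_p = int$pvalue,
               presso_global_p = if (!is.null(s$presso)) s$presso$global_p else NA_real_,
               presso_n_outliers = if (!is.null(s$presso)) nrow(s$presso$outliers) else NA_integer_,
               presso_distortion_p = if (!is.null(s$presso)) s$presso$distortion_p else NA_real_,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(sens_rows, file.path(out_dir, "sensitivity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(mediation)) {
    med_tab <- pathway_table(list(mediation), alpha = alpha)
    utils::write.table(as.data.frame(med_tab), file.path(out_dir, "mediation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  screen_hits <- NULL
  if (!is.null(config$screen)) {
    sc <- config$screen
    nbits <- sc$nbits %||% 2048
    cand <- read_fingerprints(sc$candidates, nbits = nbits)
    refs <- read_fingerprints(sc$references, nbits = nbits)
    screen_hits <- screen_candidates(cand$fingerprints, refs$fingerprints,
                                     scores = cand$scores,
                                     top_k = sc$top_k %||% Inf)
    utils::write.table(screen_hits, file.path(out_dir, "screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    say("screen: %d hit(s) written", nrow(screen_hits))
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("mrmediate")),
    seed = seed,
    config = config[setdiff(names(config), "out_dir")],
    instrument_counts = lapply(steps, function(s) as.list(s$set$provenance)),
    radial_removed = lapply(steps, function(s) s$set$radial$removed %||% character(0))
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, log_path)

  invisible(list(total = total, step1 = step1, step2 = step2,
                 mediation = mediation, screen = screen_hits,
                 truth = truth, provenance = provenance, out_dir = out_dir))
}

#' Read a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON, mirroring the list accepted by
#' [run_pipeline()].
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
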