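#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: input paths (or the
#' simulator settings standing in for them), instrument specs, the purge and
#' activation rules, and the MCMC budget. Unknown keys are rejected so typos
#' in config files fail loudly.
#'
#' @param outdir output directory for all artifacts.
#' @param patient_ratings,observer_ratings paths to input CSVs; `NULL` with
#'   `simulate = TRUE` generates them.
#' @param simulate generate synthetic inputs (default when no paths given).
#' @param seed master seed for every source of randomness.
#' @param mcmc_preset `"desk"`, `"paper"` or `"fast"` (see [mcmc_preset()]).
#' @param purge_rule `"positive"` or `"two_sided"` (see [purge_network()]).
#' @param activation `"intercept"` or `"raw_mean"` (see [node_parameters()]).
#' @param compare_models fit fixed- and random-effects node models and
#'   select by DIC (default `TRUE`).
#' @param n_physicians,patients_per_physician,recorded_consultations_per_physician,raters_per_consultation
#'   simulator design (defaults: the reference study design).
#' @param make_figures render PDF figures (off by default so headless batch
#'   runs produce text artifacts only).
#' @param verbose log stage progress to stderr.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = "sdmnet_output",
                            patient_ratings = NULL, observer_ratings = NULL,
                            simulate = is.null(patient_ratings),
                            seed = 1, mcmc_preset = "desk",
                            purge_rule = "positive",
                            activation = "intercept",
                            compare_models = TRUE,
                            n_physicians = 29, patients_per_physician = 10,
                            recorded_consultations_per_physician = 3,
                            raters_per_consultation = 2,
                            make_figures = FALSE, verbose = TRUE) {
  cfg <- list(outdir = outdir, patient_ratings = patient_ratings,
              observer_ratings = observer_ratings, simulate = simulate,
              seed = as.integer(seed), mcmc_preset = mcmc_preset,
              purge_rule = purge_rule, activation = activation,
              compare_models = compare_models,
              n_physicians = n_physicians,
              patients_per_physician = patients_per_physician,
              recorded_consultations_per_physician =
                recorded_consultations_per_physician,
              raters_per_consultation = raters_per_consultation,
              make_figures = make_figures, verbose = verbose)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- formals(pipeline_config)
  env <- new.env()
  for (nm in known) { # formals order: later defaults may use earlier keys
    if (!nm %in% names(cfg)) cfg[nm] <- list(eval(defaults[[nm]], env))
    assign(nm, cfg[[nm]], envir = env)
  }
  stopifnot(cfg$mcmc_preset %in% c("desk", "paper", "fast"),
            cfg$purge_rule %in% c("positive", "two_sided"),
            cfg$activation %in% c("intercept", "raw_mean"))
  if (!cfg$simulate) {
    for (p in c(cfg$patient_ratings, cfg$observer_ratings)) {
      if (!is.null(p) && !file.exists(p)) {
        stop("input path does not exist: ", p, call. = FALSE)
      }
    }
    if (is.null(cfg$patient_ratings)) {
      stop("`patient_ratings` path required when simulate = FALSE",
           call. = FALSE)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML config file with keys matching the
#'   [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Run the full skills-network analysis pipeline
#'
#' Stages: `simulate` (optional) generates patient and observer rating
#' tables with ground truth; `score_observer` computes physician-level
#' competence, variance decomposition and inter-rater reliability;
#' `fit_network` estimates, selects and purges the skills networks and
#' derives node parameters; `predict` screens node parameters, fits the
#' final prediction models and scores every physician; `report` writes the
#' coefficient tables, scatter data and (optionally) figures. Each stage
#' writes CSV/JSON artifacts into `outdir` and logs record counts; a stage
#' failure aborts with a stage-tagged error, retaining earlier outputs.
#'
#' @param config a [pipeline_config()], or a path to a YAML config file.
#' @param stages subset of stages to run (in pipeline order).
#' @return invisibly, a list with the main in-memory artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "score_observer",
                                    "fit_network", "predict", "report")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "pipeline.log")
  log_line <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    cat(line, "\n", file = logfile, append = TRUE)
    msg("%s", line, verbose = config$verbose)
  }
  run_stage <- function(stage, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    log_line(stage, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  mc <- mcmc_preset(config$mcmc_preset, seed = config$seed)
  art <- list()

  if ("simulate" %in% stages && config$simulate) {
    art$sim <- run_stage("simulate", {
      sim <- simulate_study(design = study_design(
        n_physicians = config$n_physicians,
        patients_per_physician = config$patients_per_physician,
        recorded_consultations_per_physician =
          config$recorded_consultations_per_physician,
        raters_per_consultation = config$raters_per_consultation,
        seed = config$seed))
      write_table_csv(sim$patient_ratings,
                      file.path(config$outdir, "patient_ratings.csv"))
      write_table_csv(sim$observer_ratings,
                      file.path(config$outdir, "observer_ratings.csv"))
      write_table_csv(sim$true_parameters,
                      file.path(config$outdir, "true_node_parameters.csv"))
      log_line("simulate", "%d patient and %d observer records for %d physicians",
               nrow(sim$patient_ratings), nrow(sim$observer_ratings),
               config$n_physicians)
      sim
    })
    patient_tab <- art$sim$patient_ratings
    observer_tab <- art$sim$observer_ratings
  } else {
    patient_tab <- read_patient_ratings(
      config$patient_ratings %||%
        file.path(config$outdir, "patient_ratings.csv"))
    observer_tab <- if (!is.null(config$observer_ratings) ||
                        file.exists(file.path(config$outdir,
                                              "observer_ratings.csv"))) {
      read_observer_ratings(config$observer_ratings %||%
                              file.path(config$outdir, "observer_ratings.csv"))
    } else NULL
  }

  if ("score_observer" %in% stages && !is.null(observer_tab)) {
    art$competence <- run_stage("score_observer", {
      comp <- physician_competence(observer_tab, verbose = config$verbose)
      vd <- variance_decomposition(observer_tab)
      irr <- interrater_reliability(observer_tab)
      write_table_csv(comp, file.path(config$outdir, "competence.csv"))
      jsonlite::write_json(
        list(variance_decomposition = vd, interrater_reliability = irr),
        file.path(config$outdir, "observer_quality.json"),
        dataframe = "rows", digits = NA, pretty = TRUE)
      log_line("score_observer",
               "scored %d physician x instrument combinations",
               nrow(comp))
      comp
    })
  }

  if ("fit_network" %in% stages) {
    art$network_fit <- run_stage("fit_network", {
      fit <- fit_skills_network(patient_tab, config = mc,
                                compare = config$compare_models,
                                purge_rule = config$purge_rule,
                                verbose = config$verbose)
      write_table_csv(network_edges(fit),
                      file.path(config$outdir, "edges.csv"))
      write_table_csv(fit$selection,
                      file.path(config$outdir, "model_selection.csv"))
      fit
    })
    art$node_params <- run_stage("fit_network", {
      np <- node_parameters(art$network_fit, activation = config$activation,
                            table = patient_tab)
      write_table_csv(np, file.path(config$outdir, "node_parameters.csv"))
      np
    })
  }

  if ("predict" %in% stages) {
    if (is.null(art$node_params)) {
      npath <- file.path(config$outdir, "node_parameters.csv")
      if (!file.exists(npath)) {
        stop("pipeline stage 'predict' failed: no node parameters ",
             "available (run fit_network first)", call. = FALSE)
      }
      art$node_params <- read.csv(npath)
    }
    if (is.null(art$competence)) {
      cpath <- file.path(config$outdir, "competence.csv")
      if (!file.exists(cpath)) {
        stop("pipeline stage 'predict' failed: no competence scores ",
             "available (run score_observer first)", call. = FALSE)
      }
      art$competence <- read.csv(cpath)
    }
    art$screening <- run_stage("predict", {
      scr <- screen_predictors(art$node_params, art$competence, config = mc)
      write_table_csv(scr$results, file.path(config$outdir, "screening.csv"))
      log_line("predict", "retained skills: %s",
               if (length(scr$retained_skills))
                 paste(scr$retained_skills, collapse = ", ") else "none")
      scr
    })
    art$models <- run_stage("predict", {
      mods <- fit_final_model(art$node_params, art$competence,
                              art$screening$retained_skills, config = mc)
      coefs <- do.call(rbind, lapply(mods, function(m) {
        cbind(outcome = m$outcome, m$coefficients)
      }))
      write_table_csv(coefs,
                      file.path(config$outdir, "model_coefficients.csv"))
      jsonlite::write_json(
        lapply(mods, function(m) m$fit_statistics),
        file.path(config$outdir, "fit_statistics.json"),
        dataframe = "rows", digits = NA, pretty = TRUE)
      mods
    })
    art$predictions <- run_stage("predict", {
      pred <- predict_competence(art$models, art$node_params,
                                 verbose = config$verbose)
      write_table_csv(pred, file.path(config$outdir, "predictions.csv"))
      pred
    })
  }

  if ("report" %in% stages && !is.null(art$models)) {
    run_stage("report", {
      for (m in art$models) {
        rep <- fit_report(m)
        write_table_csv(rep$scatter,
                        file.path(config$outdir,
                                  sprintf("scatter_%s.csv", m$outcome)))
      }
      if (config$make_figures && !is.null(art$network_fit)) {
        grDevices::pdf(file.path(config$outdir, "figures.pdf"),
                       width = 8, height = 6)
        on.exit(grDevices::dev.off(), add = TRUE)
        render_reports(art$node_params, art$network_fit, art$predictions,
                       seed = config$seed)
      }
      invisible(NULL)
    })
  }
  log_line("pipeline", "complete")
  invisible(art)
}
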