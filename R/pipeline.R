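# End-to-end pipeline: simulate -> fingerprint -> featurize -> split ->
# tune -> train -> predict -> evaluate -> clinical.
#
# Each stage is runnable stand-alone given its declared inputs: stages pull
# what they need from the in-memory state when an earlier stage ran in the
# same call, and from the artifact files in `out_dir` (or the configured
# input paths) otherwise. Every artifact directory gets a manifest with the
# config hash and seed for provenance.

.pipeline_stages <- c("simulate", "fingerprint", "featurize", "split", "tune",
                      "train", "predict", "evaluate", "clinical")

#' Read a pipeline run configuration
#'
#' JSON (always) or YAML (when the `yaml` package is installed), with keys
#' matching the arguments of [run_pipeline()]'s `config` list: `seed`,
#' `out_dir`, `sim` (passed to [sim_config()]), `paths` (input tables),
#' `model` (passed to [model_config()]), `tune`, `train_frac`, `horizons`,
#' `n_bits`, `radius`.
#'
#' @param path Config file path.
#' @return The config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the recommendation pipeline
#'
#' Executes the requested stages in dependency order, writing every artifact
#' under `config$out_dir` together with a manifest (config hash, seed, row
#' counts and headline metrics per stage). Any stage failure aborts with the
#' stage named. All randomness derives from `config$seed`.
#'
#' @param config Configuration list (see [read_run_config()]) or a path to a
#'   JSON/YAML config file.
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, the final state (tables, features, model, reports).
#' @export
run_pipeline <- function(config, stages = "all") {
  if (is.character(config) && length(config) == 1) {
    config <- read_run_config(config)
  }
  if (identical(stages, "all")) stages <- .pipeline_stages
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  stages <- .pipeline_stages[.pipeline_stages %in% stages]

  out_dir <- config$out_dir %||% abort("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- config$paths %||% list()

  # fail fast on unresolvable inputs before any compute
  needs_tables <- any(c("fingerprint", "featurize", "split", "tune", "train",
                        "predict") %in% stages)
  if (needs_tables && !"simulate" %in% stages && is.null(config$sim)) {
    for (kind in c("phenotype", "mutations", "expression", "drugs", "response")) {
      p <- paths[[kind]] %||% file.path(out_dir, .artifact_name(kind))
      if (!file.exists(p)) {
        abort(sprintf("pipeline validation: no %s table available (looked for %s)",
                      kind, p))
      }
    }
  }

  state <- new.env(parent = emptyenv())
  state$log <- list()
  note <- function(stage, ...) {
    state$log[[stage]] <- c(state$log[[stage]], sprintf(...))
    message(sprintf("[ttrec:%s] %s", stage, sprintf(...)))
  }

  for (stage in stages) {
    res <- tryCatch(
      .run_stage(stage, state, config, paths, out_dir, seed, note),
      error = function(e) {
        abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
      }
    )
  }

  manifest <- list(
    package = "ttrec",
    version = as.character(utils::packageVersion("ttrec")),
    seed = seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    stages = stages,
    log = state$log,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(as.list(state))
}

.artifact_name <- function(kind) {
  switch(kind,
         phenotype = "phenotype.tsv", mutations = "mutations.tsv",
         expression = "expression.tsv", drugs = "drugs.csv",
         response = "response.tsv", bor = "bor.tsv", survival = "survival.tsv",
         abort(sprintf("unknown table kind %s", kind)))
}

.load_table <- function(state, kind, paths, out_dir) {
  if (!is.null(state$tables[[kind]])) return(state$tables[[kind]])
  p <- paths[[kind]] %||% file.path(out_dir, .artifact_name(kind))
  if (!file.exists(p)) abort(sprintf("no %s table at %s", kind, p))
  io_kind <- c(phenotype = "phenotype", mutations = "mutation",
               expression = "expression", drugs = "drug", response = "response",
               bor = "response", survival = "survival")[[kind]]
  tb <- read_cohort_table(p, io_kind, verbose = FALSE)
  if (is.null(state$tables)) state$tables <- list()
  state$tables[[kind]] <- tb
  tb
}

.ensure_features <- function(state, config, paths, out_dir) {
  if (!is.null(state$features)) return(state$features)
  fs <- featurize_cohort(
    .load_table(state, "phenotype", paths, out_dir),
    .load_table(state, "mutations", paths, out_dir),
    .load_table(state, "expression", paths, out_dir),
    .load_table(state, "drugs", paths, out_dir),
    n_bits = config$n_bits %||% 512, radius = config$radius %||% 2
  )
  state$features <- fs
  fs
}

.ensure_split <- function(state, config, paths, out_dir, seed) {
  if (!is.null(state$split)) return(state$split)
  fs <- .ensure_features(state, config, paths, out_dir)
  pairs <- build_pairs(fs$sample_features, fs$drug_features,
                       .load_table(state, "response", paths, out_dir),
                       phenotypes = .load_table(state, "phenotype", paths, out_dir),
                       schema = fs$schema)
  state$pairs <- pairs
  state$split <- stratified_split(pairs, train_frac = config$train_frac %||% 0.75,
                                  seed = derive_seed(seed, 2L))
  state$split
}

.model_config_from <- function(config, seed) {
  args <- config$model %||% list()
  args$seed <- args$seed %||% derive_seed(seed, 3L)
  do.call(model_config, args)
}

.run_stage <- function(stage, state, config, paths, out_dir, seed, note) {
  switch(stage,
    simulate = {
      sim_args <- config$sim %||% list()
      sim_args$seed <- sim_args$seed %||% seed
      cohort <- simulate_cohort(do.call(sim_config, sim_args))
      state$tables <- cohort[c("phenotype", "mutations", "expression", "drugs",
                               "response", "bor", "survival")]
      state$truth <- cohort$truth
      for (kind in names(state$tables)) {
        write_cohort_table(state$tables[[kind]],
                           file.path(out_dir, .artifact_name(kind)))
      }
      write_cohort_table(cohort$truth$signal, file.path(out_dir, "truth_signal.tsv"))
      note("simulate", "%d samples x %d drugs x %d genes",
           nrow(cohort$phenotype), nrow(cohort$drugs), ncol(cohort$expression))
    },
    fingerprint = {
      drugs <- .load_table(state, "drugs", paths, out_dir)
      fp <- fingerprint_drugs(drugs, n_bits = config$n_bits %||% 512,
                              radius = config$radius %||% 2)
      write_cohort_table(fp, file.path(out_dir, "fingerprints.tsv"))
      note("fingerprint", "%d drugs x %d bits", nrow(fp), ncol(fp))
    },
    featurize = {
      fs <- .ensure_features(state, config, paths, out_dir)
      jsonlite::write_json(
        list(sample_features = fs$schema$sample_features,
             drug_features = fs$schema$drug_features),
        file.path(out_dir, "schema.json"))
      note("featurize", "%d sample features, %d drug features",
           ncol(fs$sample_features), ncol(fs$drug_features))
    },
    split = {
      sp <- .ensure_split(state, config, paths, out_dir, seed)
      readr::write_tsv(
        dplyr::bind_rows(
          dplyr::mutate(dplyr::distinct(sp$train$index, .data$sample_id), set = "train"),
          dplyr::mutate(dplyr::distinct(sp$test$index, .data$sample_id), set = "test")
        ), file.path(out_dir, "split.tsv"), progress = FALSE)
      note("split", "%d train / %d test pairs", n_pairs(sp$train), n_pairs(sp$test))
    },
    tune = {
      sp <- .ensure_split(state, config, paths, out_dir, seed)
      targs <- config$tune %||% list()
      cfg <- .model_config_from(config, seed)
      if (!is.null(targs$epochs)) cfg$epochs <- as.integer(targs$epochs)
      cv <- cv_tune_alpha(sp$train,
                          alpha_grid = targs$alpha_grid %||% 10^(0:-5),
                          k = targs$k %||% 10, config = cfg,
                          seed = derive_seed(seed, 4L))
      state$cv <- cv
      readr::write_tsv(tidy(cv), file.path(out_dir, "cv_mse.tsv"), progress = FALSE)
      note("tune", "best alpha = %g", cv$best_alpha)
    },
    train = {
      sp <- .ensure_split(state, config, paths, out_dir, seed)
      cfg <- .model_config_from(config, seed)
      if (!is.null(state$cv)) cfg$l2_alpha <- state$cv$best_alpha
      fs <- .ensure_features(state, config, paths, out_dir)
      model <- train_recommender(sp$train, cfg, validation = sp$test,
                                 schema = fs$schema)
      state$model <- model
      save_model(model, file.path(out_dir, "model.json"))
      note("train", "%s model, final train MSE %.4g", cfg$architecture,
           utils::tail(model$history$train_mse, 1))
    },
    predict = {
      if (is.null(state$model)) {
        mp <- paths$model %||% file.path(out_dir, "model.json")
        state$model <- load_model(mp)
      }
      sp <- .ensure_split(state, config, paths, out_dir, seed)
      scores <- score_pairs(state$model, sp$test)
      state$scores <- scores
      readr::write_tsv(scores, file.path(out_dir, "scores.tsv"), progress = FALSE)
      note("predict", "%d held-out pairs scored", nrow(scores))
    },
    evaluate = {
      if (is.null(state$scores)) {
        sf <- paths$scores %||% file.path(out_dir, "scores.tsv")
        if (!file.exists(sf)) abort(sprintf("no scores at %s", sf))
        state$scores <- readr::read_tsv(sf, show_col_types = FALSE, progress = FALSE)
      }
      ev <- evaluate_scores(state$scores, min_n = config$min_n %||% 3)
      state$eval <- ev
      readr::write_tsv(tidy(ev), file.path(out_dir, "eval_report.tsv"),
                       progress = FALSE)
      jsonlite::write_json(list(overall = as.list(ev$overall)),
                           file.path(out_dir, "eval_overall.json"),
                           auto_unbox = TRUE, digits = NA)
      note("evaluate", "overall r = %.3f (n = %d)", ev$overall$r, ev$overall$n)
    },
    clinical = {
      surv <- .load_table(state, "survival", paths, out_dir)
      if (!"score" %in% names(surv)) {
        abort("clinical stage needs a survival table with a `score` column")
      }
      if (!is.null(state$tables$bor)) {
        surv$bor <- state$tables$bor$value[match(surv$patient_id,
                                                 state$tables$bor$sample_id)]
      }
      rep <- clinical_report(surv, horizons = as.numeric(config$horizons %||% c(6, 12)))
      state$clinical <- rep
      readr::write_tsv(tidy(rep), file.path(out_dir, "clinical_report.tsv"),
                       progress = FALSE)
      jsonlite::write_json(lapply(split(tidy(rep), seq_len(nrow(tidy(rep)))),
                                  as.list),
                           file.path(out_dir, "clinical_report.json"),
                           auto_unbox = TRUE, digits = NA)
      note("clinical", "log-rank p = %.3g", rep$logrank$p_value)
    }
  )
  invisible(NULL)
}
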