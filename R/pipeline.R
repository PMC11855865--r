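# End-to-end orchestration: simulate or ingest -> cohort -> encode (with
# optional drug-target substitution) -> train -> evaluate (incl. ablations)
# -> contribution analysis -> reports. One configuration object, all
# randomness flowing from declared seeds.

#' Pipeline run configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or `paths` (a list with
#' `event_stream` and optionally `drug_target`, `icd_lookup`) must be given.
#'
#' @param simulation A [sim_config()] for synthetic runs, or NULL.
#' @param paths Named list of input file paths, or NULL.
#' @param cohort A [cohort_spec()].
#' @param model A [model_config()] (its `model_kind` is the primary model).
#' @param models Character vector of model kinds to train (default: the
#'   primary model only).
#' @param method `"drug"` (Method 1: drug tokens, contributions pooled onto
#'   targets afterwards) or `"target"` (Method 2: drug tokens substituted by
#'   target tokens before vocabulary construction).
#' @param ablations Code types to ablate in evaluation (default none).
#' @param seeds Integer vector of distinct run seeds; models are retrained
#'   per seed and AUROC is reported as mean +/- SD across seeds.
#' @param min_support,q_cutoff RC-analysis settings.
#' @param out_dir Optional output directory for manifests and reports.
#' @return A `run_config` object.
#' @export
run_config <- function(simulation = NULL, paths = NULL,
                       cohort = cohort_spec(),
                       model = model_config(),
                       models = model$model_kind,
                       method = c("drug", "target"),
                       ablations = character(0),
                       seeds = 1L,
                       min_support = 10L,
                       q_cutoff = 0.05,
                       out_dir = NULL) {
  method <- match.arg(method)
  if (is.null(simulation) == is.null(paths)) {
    abort("exactly one of `simulation` or `paths` must be supplied.")
  }
  if (anyDuplicated(seeds)) abort("`seeds` must be distinct.")
  bad <- setdiff(ablations, CODE_TYPES)
  if (length(bad)) abort(sprintf("unknown ablation type(s): %s", paste(bad, collapse = ", ")))
  structure(list(
    simulation = simulation, paths = paths, cohort = cohort, model = model,
    models = toupper(models), method = method, ablations = ablations,
    seeds = as.integer(seeds), min_support = min_support,
    q_cutoff = q_cutoff, out_dir = out_dir
  ), class = "run_config")
}

#' Run the full pipeline
#'
#' Stages: load or simulate the event stream; mask same-day
#' delirium/psychosis co-occurrence; label patients and augment cases; for
#' each seed, split patients 8:1:1, build the vocabulary on the training
#' split (after target substitution when `method = "target"`), encode, train
#' each requested model with early stopping, and evaluate on the test split
#' (plus any requested ablations). Contribution analysis runs on the first
#' seed's primary (non-augmented) samples with the first trained model, at
#' the drug level, pooled onto targets (Method 1) or at the target-token
#' level (Method 2).
#'
#' @param config A [run_config()].
#' @return A list of class `ehr_run`: `cohort_manifest`, `evals` (per seed,
#'   model and ablation), `eval_summary` (mean +/- SD AUROC), `rc` (RC
#'   tables), `reports`, `counts`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("`config` must come from run_config().")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  map <- NULL
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", generate_cohort_stream(config$simulation))
    stream <- sim$stream
    map <- sim$drug_target
    truth <- sim$truth
  } else {
    stream <- stage("ingest", read_event_stream(config$paths$event_stream))
    if (!is.null(config$paths$drug_target)) {
      map <- read_drug_target_map(config$paths$drug_target)
    }
    if (!is.null(config$paths$icd_lookup)) {
      lookup <- read_icd_lookup(config$paths$icd_lookup)
      diag <- stream$code_type == "DIAG"
      stream$code[diag] <- map_icd9_to_icd10(stream$code[diag], lookup)
    }
  }

  cohort <- stage("cohort", {
    build_cohort(stream, config$cohort) |>
      augment_cases(seed = derive_seed(config$seeds[1], 11L))
  })
  counts <- list(
    n_patients = cohort$n_patients,
    n_cases = sum(cohort$samples$label == "case" & cohort$samples$provenance == "index"),
    n_controls = sum(cohort$samples$label == "control"),
    n_excluded = nrow(cohort$exclusions),
    n_samples = nrow(cohort$samples)
  )

  samples <- cohort$samples
  if (config$method == "target") {
    if (is.null(map)) abort("method = 'target' requires a drug-target map.")
    samples <- stage("substitute", substitute_targets(samples, map))
  }

  evals <- list()
  first_fit <- NULL
  first_encoded <- NULL
  for (seed in config$seeds) {
    run <- stage(paste0("train@seed", seed), {
      split <- split_cohort(samples, seed = seed)
      vocab <- build_vocabulary(split |> filter(.data$split == "train"))
      enc <- encode_samples(split, vocab)
      enc_train <- enc |> filter(.data$split == "train")
      enc_val <- enc |> filter(.data$split == "validation")
      enc_test <- enc |> filter(.data$split == "test")
      fits <- purrr::map(config$models, function(kind) {
        cfg <- config$model
        cfg$model_kind <- kind
        cfg$seed <- derive_seed(seed, 101L)
        train_risk_model(enc_train, enc_val, cfg)
      })
      ev <- purrr::map2(fits, config$models, function(fit, kind) {
        base <- evaluate_model(fit, enc_test) |> mutate(ablation = "none")
        abl <- purrr::map(config$ablations, function(a) {
          evaluate_model(fit, ablate_codes(enc_test, a, vocab)) |>
            mutate(ablation = a)
        })
        bind_rows(base, abl) |> mutate(model_kind = kind, seed = seed)
      }) |> bind_rows()
      list(fits = fits, enc = enc, eval = ev)
    })
    evals[[as.character(seed)]] <- run$eval
    if (is.null(first_fit)) {
      first_fit <- run$fits[[1]]
      first_encoded <- run$enc
      # record the first seed's patient-level split in the manifest
      cohort$samples <- left_join(
        cohort$samples,
        distinct(run$enc[, c("patient_id", "split")]),
        by = "patient_id")
    }
  }
  evals <- bind_rows(evals)
  eval_summary <- evals |>
    group_by(.data$model_kind, .data$ablation) |>
    summarise(mean_auroc = mean(.data$auroc),
              sd_auroc = if (n() > 1) sd(.data$auroc) else NA_real_,
              mean_f1 = mean(.data$f1), n_seeds = n(), .groups = "drop")

  rc <- stage("contribute", {
    primary <- first_encoded |> filter(.data$provenance == "index")
    fc <- compute_fc(first_fit, primary)
    out <- list(feature_level = rc_analysis(fc, config$min_support))
    if (config$method == "drug" && !is.null(map)) {
      pooled <- pool_fc_by_target(fc, map)
      out$target_pooled <- rc_analysis(pooled, config$min_support)
    }
    out
  })
  reports <- purrr::map(rc, rc_report, q_cutoff = config$q_cutoff,
                        map = if (!is.null(map)) map else NULL)

  result <- structure(list(
    cohort_manifest = cohort_manifest(cohort),
    exclusions = cohort$exclusions,
    counts = counts,
    evals = evals,
    eval_summary = eval_summary,
    rc = rc,
    reports = reports,
    truth = truth,
    model = first_fit,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    seeds = config$seeds
  ), class = "ehr_run")

  if (!is.null(config$out_dir)) write_run_outputs(result, config$out_dir)
  result
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$cohort_manifest, file.path(out_dir, "cohort_manifest.csv"))
  readr::write_csv(run$evals, file.path(out_dir, "evaluations.csv"))
  purrr::iwalk(run$rc, function(tab, nm) {
    readr::write_csv(tab, file.path(out_dir, paste0("rc_", nm, ".csv")))
  })
  jsonlite::write_json(
    list(config_hash = run$config_hash, seeds = run$seeds, counts = run$counts),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(run)
}

#' @export
print.ehr_run <- function(x, ...) {
  cat("<ehr_run> ", x$counts$n_patients, " patients (",
      x$counts$n_cases, " cases / ", x$counts$n_controls, " controls / ",
      x$counts$n_excluded, " excluded), ",
      length(x$seeds), " seed(s)\n", sep = "")
  print(x$eval_summary)
  invisible(x)
}

#' @exportS3Method generics::glance
glance.ehr_run <- function(x, ...) {
  as_tibble(x$counts) |>
    mutate(config_hash = x$config_hash)
}
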