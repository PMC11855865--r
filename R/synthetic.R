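# Synthetic longitudinal EHR generator with planted per-code effects.
#
# Every patient gets an anchoring dementia diagnosis at their first visit and
# a stream of coded encounters; a latent outcome model decides whether a
# psychosis-onset event (psychosis diagnosis or first antipsychotic order) is
# appended within the outcome window after a randomly chosen post-look-back
# encounter. Ground truth (per-code log-odds effects, realized case rate) is
# returned alongside the stream so downstream recovery can be scored.

SIM_ORIGIN <- as.Date("2015-01-01")

#' Default synthetic code catalog
#'
#' Builds a catalog of diagnosis, medication and abnormal-lab codes with a
#' common per-visit occurrence probability. Codes are synthetic identifiers
#' (`DX..`, `DB..`, `LAB..`); medication codes are DrugBank-style so they can
#' be joined to a drug-target map.
#'
#' @param n_diag,n_med,n_lab Number of codes of each type.
#' @param prevalence Per-visit occurrence probability, recycled across codes.
#' @return A tibble with columns `code`, `code_type`, `prevalence`.
#' @export
sim_code_catalog <- function(n_diag = 12, n_med = 12, n_lab = 6,
                             prevalence = 0.05) {
  codes <- c(
    if (n_diag > 0) sprintf("DX%02d", seq_len(n_diag)),
    if (n_med > 0) sprintf("DB%05d", 100L + seq_len(n_med)),
    if (n_lab > 0) sprintf("LAB%02d", seq_len(n_lab))
  )
  types <- rep(c("DIAG", "MED", "LAB_ABN"), times = c(n_diag, n_med, n_lab))
  tibble(code = codes, code_type = types,
         prevalence = rep_len(prevalence, length(codes)))
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic EHR generator.
#' Defaults describe a desk-scale cohort: ~1.5 years of history per patient,
#' around 20 encounters, a 1-year look-back and a 90-day outcome window, and
#' a baseline outcome probability of 0.2 per anchored encounter.
#'
#' @param n_patients Number of patients (0 allowed; yields an empty stream).
#' @param observation_days Days of history per patient; must be at least
#'   `lookback_days + outcome_window_days`.
#' @param visits_per_patient Mean encounter count (Poisson, floored at 2).
#' @param code_catalog Tibble `code, code_type, prevalence` (per-visit
#'   occurrence probabilities in (0,1)); see [sim_code_catalog()].
#' @param effects Named numeric vector of per-code log-odds contributions;
#'   codes absent from it carry effect 0.
#' @param order_effects Optional tibble `first, second, beta`: each row adds
#'   `beta` to the outcome logit when the first occurrence of code `first`
#'   precedes the first occurrence of code `second` in the look-back window
#'   (both present; same-day ties contribute nothing). Bag-of-codes models
#'   cannot see this signal; sequence models can.
#' @param baseline_logit Intercept of the outcome model on the logit scale.
#' @param lookback_days,outcome_window_days Window lengths in days.
#' @param drug_target Optional list with `n_targets` and
#'   `mean_targets_per_drug`; when present a drug-target map over the
#'   catalog's medication codes is generated with the stream.
#' @param ad_code,psychosis_code,antipsychotic_code,delirium_code Reserved
#'   codes for the anchoring diagnosis and the outcome events.
#' @param seed Integer seed; the same configuration regenerates an identical
#'   stream.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients,
                       observation_days = 550,
                       visits_per_patient = 20,
                       code_catalog = sim_code_catalog(),
                       effects = NULL,
                       baseline_logit = qlogis(0.2),
                       order_effects = NULL,
                       lookback_days = 365,
                       outcome_window_days = 90,
                       drug_target = NULL,
                       ad_code = "G30",
                       psychosis_code = "F29",
                       antipsychotic_code = "RXANTIPSY",
                       delirium_code = "F05",
                       seed = 1L) {
  n_patients <- assert_count(n_patients, "n_patients")
  observation_days <- assert_count(observation_days, "observation_days", min = 1L)
  lookback_days <- assert_count(lookback_days, "lookback_days", min = 1L)
  outcome_window_days <- assert_count(outcome_window_days, "outcome_window_days", min = 1L)
  if (observation_days < lookback_days + outcome_window_days) {
    abort(sprintf(
      "`observation_days` (%d) must be >= lookback_days + outcome_window_days (%d).",
      observation_days, lookback_days + outcome_window_days))
  }
  if (!is.data.frame(code_catalog) ||
      !all(c("code", "code_type", "prevalence") %in% names(code_catalog))) {
    abort("`code_catalog` needs columns code, code_type, prevalence.")
  }
  bad <- code_catalog$prevalence <= 0 | code_catalog$prevalence >= 1 |
    is.na(code_catalog$prevalence)
  if (any(bad)) {
    abort(sprintf("prevalence outside (0,1) for code(s): %s",
                  paste(code_catalog$code[bad], collapse = ", ")))
  }
  if (anyDuplicated(code_catalog$code)) abort("`code_catalog` codes must be unique.")
  effects <- effects %||% numeric(0)
  if (length(effects) && is.null(names(effects))) {
    abort("`effects` must be a named numeric vector (code -> log-odds).")
  }
  unknown <- setdiff(names(effects), code_catalog$code)
  if (length(unknown)) {
    abort(sprintf("`effects` names absent from catalog: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (!is.null(order_effects) &&
      !all(c("first", "second", "beta") %in% names(order_effects))) {
    abort("`order_effects` needs columns first, second, beta.")
  }
  structure(list(
    n_patients = n_patients,
    observation_days = observation_days,
    visits_per_patient = assert_number(visits_per_patient, "visits_per_patient"),
    code_catalog = as_tibble(code_catalog),
    effects = effects,
    baseline_logit = assert_number(baseline_logit, "baseline_logit"),
    order_effects = if (!is.null(order_effects)) as_tibble(order_effects) else NULL,
    lookback_days = lookback_days,
    outcome_window_days = outcome_window_days,
    drug_target = drug_target,
    ad_code = ad_code,
    psychosis_code = psychosis_code,
    antipsychotic_code = antipsychotic_code,
    delirium_code = delirium_code,
    seed = assert_count(seed, "seed")
  ), class = "sim_config")
}

#' Generate a synthetic cohort event stream with known ground truth
#'
#' Each patient receives `2 + Poisson` encounters over the observation span:
#' one early visit carrying the anchoring dementia diagnosis, one guaranteed
#' anchor-eligible visit (at least `lookback_days` of history before it and a
#' full outcome window after it), and the rest uniform over the span. Codes
#' occur independently per visit at their catalog prevalence. One anchor
#' encounter per patient is drawn uniformly among eligible visits; the
#' outcome probability at that anchor is
#' `plogis(baseline_logit + sum of effects over codes present in the
#' look-back window)`. Cases receive an outcome event (psychosis diagnosis or
#' antipsychotic order, 50/50) uniformly within the outcome window.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `stream` (tibble `patient_id, date,
#'   code_type, code`, sorted), `truth` (list: `code_effects`,
#'   `target_effects` when a map was requested, `case_rate`, `anchors`), and
#'   `drug_target` (tibble or NULL).
#' @export
generate_cohort_stream <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must come from sim_config().")
  cat <- config$code_catalog
  effects <- setNames(numeric(nrow(cat)), cat$code)
  effects[names(config$effects)] <- config$effects

  map <- NULL
  if (!is.null(config$drug_target)) {
    med_codes <- cat$code[cat$code_type == "MED"]
    if (!length(med_codes)) abort("drug_target requested but catalog has no MED codes.")
    map <- generate_drug_target_map(
      n_drugs = length(med_codes),
      n_targets = config$drug_target$n_targets,
      mean_targets_per_drug = config$drug_target$mean_targets_per_drug %||% 2,
      seed = derive_seed(config$seed, 7L),
      drug_ids = med_codes
    )
  }

  empty_stream <- tibble(patient_id = character(), date = as.Date(character()),
                         code_type = character(), code = character())
  if (config$n_patients == 0L) {
    return(list(
      stream = empty_stream,
      truth = list(code_effects = effects,
                   target_effects = target_effects_from_map(map, effects),
                   case_rate = NA_real_, anchors = tibble()),
      drug_target = map
    ))
  }

  n <- config$n_patients
  obs <- config$observation_days
  lb <- config$lookback_days
  win <- config$outcome_window_days
  res <- withr::with_seed(config$seed, {
    pid <- sprintf("P%06d", seq_len(n))
    # visit days: forced first visit (carries the AD anchor diagnosis),
    # forced anchor-eligible visit, plus Poisson extras uniform over the span
    first_day <- sample.int(15L, n, replace = TRUE) - 1L
    eligible_day <- lb + sample.int(obs - lb - win + 1L, n, replace = TRUE) - 1L
    n_extra <- rpois(n, max(config$visits_per_patient - 2, 0))
    extra <- tibble(
      patient_id = rep(pid, n_extra),
      day = unlist(purrr::map(n_extra, function(k) {
        sample.int(obs, k, replace = TRUE) - 1L
      }), use.names = FALSE) %||% integer(0)
    )
    visits <- bind_rows(
      tibble(patient_id = pid, day = first_day),
      tibble(patient_id = pid, day = eligible_day),
      extra
    ) |>
      distinct(.data$patient_id, .data$day) |>
      arrange(.data$patient_id, .data$day)

    # codes per visit: independent Bernoulli at catalog prevalence
    nv <- nrow(visits)
    code_rows <- purrr::pmap(cat, function(code, code_type, prevalence) {
      hit <- runif(nv) < prevalence
      tibble(patient_id = visits$patient_id[hit], day = visits$day[hit],
             code_type = code_type, code = code)
    }) |> bind_rows()

    ad_rows <- tibble(patient_id = pid, day = first_day,
                      code_type = "DIAG", code = config$ad_code)

    # anchor: uniform among visits eligible for both windows
    anchors <- visits |>
      filter(.data$day >= lb, .data$day <= obs - win) |>
      group_by(.data$patient_id) |>
      slice(sample.int(n(), 1L)) |>
      ungroup() |>
      rename(anchor_day = "day")

    window_rows <- code_rows |>
      inner_join(anchors, by = "patient_id") |>
      filter(.data$day >= .data$anchor_day - lb, .data$day < .data$anchor_day)
    exposure <- window_rows |> distinct(.data$patient_id, .data$code)
    eta <- exposure |>
      mutate(beta = effects[.data$code]) |>
      group_by(.data$patient_id) |>
      summarise(eta = sum(.data$beta), .groups = "drop")
    if (!is.null(config$order_effects)) {
      first_days <- window_rows |>
        group_by(.data$patient_id, .data$code) |>
        summarise(first_day = min(.data$day), .groups = "drop")
      ord_eta <- purrr::pmap(config$order_effects,
                             function(first, second, beta) {
        a <- first_days |> filter(.data$code == first) |>
          select("patient_id", day_a = "first_day")
        b <- first_days |> filter(.data$code == second) |>
          select("patient_id", day_b = "first_day")
        inner_join(a, b, by = "patient_id") |>
          filter(.data$day_a < .data$day_b) |>
          mutate(eta_add = beta) |>
          select("patient_id", "eta_add")
      }) |> bind_rows() |>
        group_by(.data$patient_id) |>
        summarise(eta_add = sum(.data$eta_add), .groups = "drop")
      if (nrow(ord_eta)) {
        eta <- eta |>
          left_join(ord_eta, by = "patient_id") |>
          mutate(eta = .data$eta + dplyr::coalesce(.data$eta_add, 0)) |>
          select("patient_id", "eta")
      }
    }
    anchors <- anchors |>
      left_join(eta, by = "patient_id") |>
      mutate(eta = config$baseline_logit + dplyr::coalesce(.data$eta, 0),
             p_outcome = plogis(.data$eta),
             is_case = rbinom(n(), 1L, .data$p_outcome) == 1L,
             outcome_day = if_else(.data$is_case,
                                   .data$anchor_day + sample.int(win, n(), replace = TRUE),
                                   NA_integer_),
             outcome_kind = if_else(runif(n()) < 0.5, "DIAG", "MED"))

    outcome_rows <- anchors |>
      filter(.data$is_case) |>
      mutate(code = if_else(.data$outcome_kind == "DIAG",
                            config$psychosis_code, config$antipsychotic_code)) |>
      select(patient_id = "patient_id", day = "outcome_day",
             code_type = "outcome_kind", code = "code")

    stream <- bind_rows(code_rows, ad_rows, outcome_rows) |>
      mutate(date = SIM_ORIGIN + .data$day) |>
      select(dplyr::all_of(STREAM_COLS)) |>
      arrange(.data$patient_id, .data$date, .data$code_type, .data$code)
    list(stream = stream, anchors = anchors)
  })

  list(
    stream = res$stream,
    truth = list(
      code_effects = effects,
      target_effects = target_effects_from_map(map, effects),
      case_rate = mean(res$anchors$is_case),
      anchors = res$anchors |>
        select("patient_id", "anchor_day", "p_outcome", "is_case", "outcome_day")
    ),
    drug_target = map
  )
}

target_effects_from_map <- function(map, effects) {
  if (is.null(map)) return(NULL)
  map |>
    mutate(beta = dplyr::coalesce(effects[.data$drug_id], 0)) |>
    group_by(.data$protein_id) |>
    summarise(beta = mean(.data$beta), .groups = "drop") |>
    (\(d) setNames(d$beta, d$protein_id))()
}

#' Generate a random many-to-many drug-target map
#'
#' Every drug is assigned at least one protein target; target counts are
#' `1 + Poisson(mean - 1)`, capped at `n_targets`, targets sampled without
#' replacement. When there are more drugs than targets, at least one target
#' is necessarily shared (pigeonhole).
#'
#' @param n_drugs,n_targets Counts (both >= 1).
#' @param mean_targets_per_drug Mean number of targets per drug (>= 1).
#' @param seed Integer seed.
#' @param drug_ids Optional character vector of drug identifiers (length
#'   `n_drugs`); defaults to DrugBank-style `DB00101...`.
#' @return A tibble `drug_id, protein_id`, one row per pair.
#' @export
generate_drug_target_map <- function(n_drugs, n_targets, mean_targets_per_drug = 2,
                                     seed = 1L, drug_ids = NULL) {
  n_drugs <- assert_count(n_drugs, "n_drugs", min = 1L)
  n_targets <- assert_count(n_targets, "n_targets", min = 1L)
  if (mean_targets_per_drug < 1) abort("`mean_targets_per_drug` must be >= 1.")
  drug_ids <- drug_ids %||% sprintf("DB%05d", 100L + seq_len(n_drugs))
  if (length(drug_ids) != n_drugs) abort("`drug_ids` must have length n_drugs.")
  proteins <- sprintf("PT%04d", seq_len(n_targets))
  withr::with_seed(seed, {
    k <- pmin(1L + rpois(n_drugs, mean_targets_per_drug - 1), n_targets)
    tibble(
      drug_id = rep(drug_ids, k),
      protein_id = unlist(purrr::map(k, function(ki) sample(proteins, ki)),
                          use.names = FALSE)
    ) |> arrange(.data$drug_id, .data$protein_id)
  })
}

#' Read/write helpers for the plain-text exchange formats
#'
#' The event stream is a delimiter-separated file with header
#' `patient_id,date,code_type,code` (ISO-8601 dates); the drug-target map is
#' a two-column TSV `drug_id<TAB>protein_id`.
#'
#' @param stream,map Tibbles as produced by the generator.
#' @param path File path.
#' @param delim Field delimiter for the event stream (default comma).
#' @return The input (writers, invisibly) or the parsed tibble (readers).
#' @name stream-io
NULL

#' @rdname stream-io
#' @export
write_event_stream <- function(stream, path, delim = ",") {
  assert_stream(stream)
  readr::write_delim(stream, path, delim = delim)
  invisible(stream)
}

#' @rdname stream-io
#' @export
read_event_stream <- function(path, delim = ",") {
  stream <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      date = readr::col_date(),
      code_type = readr::col_character(),
      code = readr::col_character()
    )
  )
  assert_stream(stream)
  stream
}

#' @rdname stream-io
#' @export
write_drug_target_map <- function(map, path) {
  readr::write_tsv(map[, c("drug_id", "protein_id")], path)
  invisible(map)
}

#' @rdname stream-io
#' @export
read_drug_target_map <- function(path) {
  map <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("drug_id", "protein_id") %in% names(map))) {
    abort("drug-target file needs columns drug_id and protein_id.")
  }
  as_tibble(map)
}
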