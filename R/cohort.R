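# Cohort construction: index-date selection, inclusion/exclusion, outcome
# labeling, delirium masking, case augmentation and patient-level splitting.
#
# Windows are half-open by design: the look-back is [index - lookback, index)
# and the outcome window is (index, index + window], so events on the index
# date itself belong to neither — the anchoring encounter cannot leak the
# label, and a same-day outcome disqualifies that candidate index.

EXCLUSION_REASONS <- c("NO_AD", "INSUFFICIENT_HISTORY", "PRIOR_PSYCHOSIS",
                       "PRIOR_ANTIPSYCHOTIC", "NO_ELIGIBLE_ENCOUNTER")

#' Cohort specification
#'
#' Code sets and window lengths defining the case/control rules: patients
#' must carry an anchoring diagnosis (e.g. Alzheimer's disease) strictly
#' before the index date, have at least `lookback_days` of record before it,
#' and no psychosis diagnosis or antipsychotic order before it. A case has a
#' psychosis or antipsychotic event within `(index, index + outcome_window]`;
#' a control has none there.
#'
#' @param ad_codes,psychosis_codes,antipsychotic_codes,delirium_codes
#'   Character vectors of codes. `psychosis_codes` and `delirium_codes` must
#'   be disjoint (the delirium rule masks same-day co-occurrence in time, not
#'   overlapping code sets).
#' @param lookback_days Look-back window length (default 365).
#' @param outcome_window_days Outcome window length (default 90).
#' @param augmentation_max_per_case Maximum additional earlier-anchor samples
#'   emitted per case patient (default 2).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(ad_codes = "G30",
                        psychosis_codes = "F29",
                        antipsychotic_codes = "RXANTIPSY",
                        delirium_codes = "F05",
                        lookback_days = 365,
                        outcome_window_days = 90,
                        augmentation_max_per_case = 2) {
  if (length(intersect(psychosis_codes, delirium_codes))) {
    abort("psychosis_codes and delirium_codes must be disjoint.")
  }
  structure(list(
    ad_codes = ad_codes,
    psychosis_codes = psychosis_codes,
    antipsychotic_codes = antipsychotic_codes,
    delirium_codes = delirium_codes,
    lookback_days = assert_count(lookback_days, "lookback_days", min = 1L),
    outcome_window_days = assert_count(outcome_window_days, "outcome_window_days", min = 1L),
    augmentation_max_per_case = assert_count(augmentation_max_per_case,
                                             "augmentation_max_per_case")
  ), class = "cohort_spec")
}

#' Mask psychosis diagnoses that co-occur with delirium
#'
#' Drops psychosis diagnosis records dated the same calendar day as any
#' delirium record for the same patient (transient delirium symptoms can be
#' misread as psychosis onset). All other records pass through unchanged.
#'
#' @param stream Event-stream tibble.
#' @param spec A [cohort_spec()].
#' @return The filtered stream.
#' @export
mask_delirium_psychosis <- function(stream, spec) {
  assert_stream(stream)
  delirium_days <- stream |>
    filter(.data$code %in% spec$delirium_codes) |>
    distinct(.data$patient_id, .data$date)
  if (!nrow(delirium_days)) return(stream)
  masked <- stream |>
    filter(.data$code %in% spec$psychosis_codes) |>
    semi_join(delirium_days, by = c("patient_id", "date"))
  anti_join(stream, masked, by = STREAM_COLS)
}

#' Label one patient timeline as case, control, or exclusion
#'
#' Scans the patient's encounter dates for eligible index candidates
#' (anchoring diagnosis strictly before, full look-back of record, no prior
#' or same-day outcome event). The patient is a case anchored at the latest
#' eligible encounter with an outcome in `(index, index + window]`; otherwise
#' a control anchored at the latest eligible encounter with no outcome in its
#' window; otherwise an exclusion with a machine-readable reason (`NO_AD`,
#' `INSUFFICIENT_HISTORY`, `PRIOR_PSYCHOSIS`, `PRIOR_ANTIPSYCHOTIC`,
#' `NO_ELIGIBLE_ENCOUNTER`).
#'
#' @param timeline Event-stream tibble for a single patient, sorted by date.
#' @param spec A [cohort_spec()].
#' @return A list: either `list(status = "case"/"control", sample = <tibble
#'   row with events list-column>, case_anchors = <Date vector>)` or
#'   `list(status = "excluded", reason = <string>)`.
#' @export
label_patient <- function(timeline, spec) {
  assert_stream(timeline, "timeline")
  if (length(unique(timeline$patient_id)) > 1L) {
    abort("`timeline` must contain a single patient.")
  }
  if (is.unsorted(timeline$date)) abort("`timeline` must be sorted by date.")
  pid <- timeline$patient_id[1]
  excl <- function(reason) list(status = "excluded", reason = reason, patient_id = pid)
  if (!nrow(timeline)) return(excl("NO_AD"))

  outcome_codes <- c(spec$psychosis_codes, spec$antipsychotic_codes)
  ad_dates <- timeline$date[timeline$code %in% spec$ad_codes]
  if (!length(ad_dates)) return(excl("NO_AD"))
  first_ad <- min(ad_dates)
  first_event <- min(timeline$date)
  outcome_dates <- sort(timeline$date[timeline$code %in% outcome_codes])

  candidates <- unique(timeline$date)
  candidates <- candidates[candidates > first_ad]
  if (!length(candidates)) return(excl("NO_ELIGIBLE_ENCOUNTER"))
  with_history <- candidates[first_event <= candidates - spec$lookback_days]
  if (!length(with_history)) return(excl("INSUFFICIENT_HISTORY"))

  # prior (< index) or same-day (== index) outcome disqualifies a candidate
  clean <- with_history[!vapply(with_history, function(t) {
    any(outcome_dates <= t)
  }, logical(1))]
  if (!length(clean)) {
    first_outcome <- outcome_dates[1]
    kind <- timeline$code[timeline$date == first_outcome &
                            timeline$code %in% outcome_codes][1]
    reason <- if (kind %in% spec$psychosis_codes) "PRIOR_PSYCHOSIS" else "PRIOR_ANTIPSYCHOTIC"
    return(excl(reason))
  }

  in_window <- vapply(clean, function(t) {
    any(outcome_dates > t & outcome_dates <= t + spec$outcome_window_days)
  }, logical(1))
  if (any(in_window)) {
    anchors <- clean[in_window]
    index_date <- max(anchors)
    label <- "case"
  } else {
    anchors <- as.Date(character())
    index_date <- max(clean)
    label <- "control"
  }
  list(
    status = label,
    sample = make_sample(timeline, pid, index_date, label, "index", spec),
    case_anchors = anchors
  )
}

make_sample <- function(timeline, pid, index_date, label, provenance, spec) {
  events <- timeline |>
    filter(.data$date >= index_date - spec$lookback_days,
           .data$date < index_date) |>
    select("date", "code_type", "code")
  tibble(
    patient_id = pid,
    index_date = index_date,
    label = label,
    provenance = provenance,
    events = list(events)
  )
}

#' Build a labeled cohort from an event stream
#'
#' Applies [mask_delirium_psychosis()] then [label_patient()] per patient and
#' collects samples and exclusions.
#'
#' @param stream Event-stream tibble.
#' @param spec A [cohort_spec()].
#' @return A list of class `ehr_cohort`: `samples` (tibble with events
#'   list-column), `exclusions` (tibble `patient_id, reason`),
#'   `case_anchors` (named list of Date vectors for augmentation), `spec`.
#' @export
build_cohort <- function(stream, spec) {
  assert_stream(stream)
  stream <- mask_delirium_psychosis(stream, spec) |>
    arrange(.data$patient_id, .data$date)
  timelines <- split(stream, stream$patient_id)
  labeled <- purrr::map(timelines, label_patient, spec = spec)
  samples <- purrr::map(labeled, function(x) {
    if (x$status == "excluded") NULL else x$sample
  }) |> purrr::compact() |> bind_rows()
  if (!nrow(samples)) {
    samples <- tibble(patient_id = character(), index_date = as.Date(character()),
                      label = character(), provenance = character(), events = list())
  }
  exclusions <- purrr::map(labeled, function(x) {
    if (x$status == "excluded") tibble(patient_id = x$patient_id, reason = x$reason) else NULL
  }) |> purrr::compact() |> bind_rows()
  if (!nrow(exclusions)) exclusions <- tibble(patient_id = character(), reason = character())
  anchors <- purrr::map(labeled, function(x) {
    if (x$status == "case") x$case_anchors else NULL
  }) |> purrr::compact()
  structure(list(samples = samples, exclusions = exclusions,
                 case_anchors = anchors, spec = spec,
                 n_patients = length(timelines), stream = stream),
            class = "ehr_cohort")
}

#' Augment cases by re-anchoring at earlier eligible encounters
#'
#' For each case patient with more than one eligible case anchor, emits up to
#' `spec$augmentation_max_per_case` additional samples anchored at distinct
#' earlier eligible encounters (sampled without replacement under `seed`).
#' Controls are never augmented and no events are fabricated.
#'
#' @param cohort An `ehr_cohort` from [build_cohort()].
#' @param seed Integer seed for anchor sampling.
#' @return The cohort with augmented samples appended (`provenance =
#'   "augmented"`).
#' @export
augment_cases <- function(cohort, seed = 1L) {
  spec <- cohort$spec
  if (spec$augmentation_max_per_case == 0L) return(cohort)
  extra <- withr::with_seed(seed, {
    purrr::imap(cohort$case_anchors, function(anchors, pid) {
      primary <- max(anchors)
      earlier <- sort(anchors[anchors < primary])
      if (!length(earlier)) return(NULL)
      k <- min(length(earlier), spec$augmentation_max_per_case)
      picked <- sort(sample(earlier, k))
      timeline <- cohort$stream |> filter(.data$patient_id == pid)
      bind_rows(purrr::map(picked, function(t) {
        make_sample(timeline, pid, t, "case", "augmented", spec)
      }))
    }) |> purrr::compact() |> bind_rows()
  })
  if (nrow(extra %||% tibble())) {
    cohort$samples <- bind_rows(cohort$samples, extra) |>
      arrange(.data$patient_id, .data$index_date)
  }
  cohort
}

#' Split a cohort into train/validation/test at the patient level
#'
#' Patients (never individual samples) are partitioned 8:1:1, so all samples
#' of one patient — including augmented re-anchors — land in one partition
#' and no identity leaks across splits.
#'
#' @param samples A samples tibble (from an `ehr_cohort`) or the cohort
#'   itself.
#' @param seed Integer seed for the patient shuffle.
#' @return The samples tibble with a `split` column
#'   (`train`/`validation`/`test`).
#' @export
split_cohort <- function(samples, seed = 1L) {
  if (inherits(samples, "ehr_cohort")) samples <- samples$samples
  patients <- unique(samples$patient_id)
  n <- length(patients)
  if (n < 10L) abort("split_cohort() needs at least 10 distinct patients.")
  assignment <- withr::with_seed(seed, {
    shuffled <- sample(patients)
    n_test <- floor(n / 10)
    n_val <- floor(n / 10)
    tibble(
      patient_id = shuffled,
      split = rep(c("test", "validation", "train"),
                  times = c(n_test, n_val, n - n_test - n_val))
    )
  })
  left_join(samples, assignment, by = "patient_id")
}

#' Cohort manifest
#'
#' One row per sample: patient, index date, label, split (if assigned),
#' number of events in the look-back window, and provenance.
#'
#' @param cohort An `ehr_cohort` or a samples tibble.
#' @return A tibble.
#' @export
cohort_manifest <- function(cohort) {
  samples <- if (inherits(cohort, "ehr_cohort")) cohort$samples else cohort
  samples |>
    mutate(n_events_in_window = purrr::map_int(.data$events, nrow)) |>
    select(dplyr::any_of(c("patient_id", "index_date", "label", "split",
                           "n_events_in_window", "provenance")))
}

#' @export
print.ehr_cohort <- function(x, ...) {
  tab <- table(x$samples$label[x$samples$provenance == "index"])
  cat("<ehr_cohort> ", x$n_patients, " patients: ",
      sum(tab[names(tab) == "case"]), " cases, ",
      sum(tab[names(tab) == "control"]), " controls, ",
      nrow(x$exclusions), " excluded; ",
      nrow(x$samples), " samples total\n", sep = "")
  invisible(x)
}
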