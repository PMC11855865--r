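# Drug -> protein-target layer.
#
# Method 2 (target-focused) swaps medication tokens for their protein-target
# tokens before vocabulary construction, pooling patients across drugs that
# share a target. Method 1 (drug-focused) trains on drug tokens and pools the
# per-patient feature contributions onto targets afterwards. The direction of
# target modulation (agonist vs antagonist) is not modeled.

#' Validate and index a drug-target map
#'
#' @param map Tibble `drug_id, protein_id` (one row per pair).
#' @return The map, deduplicated, with class `drug_target_map`; the inverse
#'   (protein -> drugs) view is derivable by grouping and is guaranteed
#'   consistent because both views are the same relation.
#' @export
as_drug_target_map <- function(map) {
  if (!all(c("drug_id", "protein_id") %in% names(map))) {
    abort("`map` needs columns drug_id and protein_id.")
  }
  if (any(is.na(map$drug_id) | is.na(map$protein_id))) {
    abort("drug-target map contains missing identifiers.")
  }
  out <- distinct(as_tibble(map), .data$drug_id, .data$protein_id)
  class(out) <- c("drug_target_map", class(out))
  out
}

#' Replace medication tokens by their protein-target tokens (Method 2)
#'
#' Every medication event whose code has at least one mapped target is
#' replaced by one event per target protein on the same date (the `code_type`
#' stays `MED`, so medication ablations still remove the substituted
#' tokens). Unmapped medications pass through unchanged; diagnosis and lab
#' events are untouched.
#'
#' @param x An event-stream tibble, or a samples tibble with an `events`
#'   list-column (substitution is applied inside each sample's window).
#' @param map A drug-target map tibble.
#' @return Same shape as `x` with medication codes substituted.
#' @export
substitute_targets <- function(x, map) {
  map <- as_drug_target_map(map)
  if ("events" %in% names(x)) {
    x$events <- purrr::map(x$events, substitute_targets_events, map = map)
    return(x)
  }
  substitute_targets_events(x, map)
}

substitute_targets_events <- function(events, map) {
  med <- events$code_type == "MED" & events$code %in% map$drug_id
  if (!any(med)) return(events)
  swapped <- events[med, ] |>
    left_join(map, by = c("code" = "drug_id"), relationship = "many-to-many") |>
    mutate(code = .data$protein_id) |>
    select(-"protein_id")
  bind_rows(events[!med, ], swapped) |>
    distinct() |>
    arrange(across(dplyr::any_of(c("patient_id", "date", "code_type", "code"))))
}

#' Pool per-patient drug contributions onto protein targets (Method 1)
#'
#' A patient's feature contribution (FC) to a protein is the sum of that
#' patient's FCs over all drugs mapping to the protein — additive, matching
#' FC's definition as a per-patient sum over occurrences, and reducing to the
#' drug-level table under a one-to-one map. Patients with no mapped drug
#' exposure contribute no row.
#'
#' @param fc An FC table (`patient_id, feature, fc_raw, label`) over drug
#'   features.
#' @param map A drug-target map tibble.
#' @return An FC table over protein features.
#' @export
pool_fc_by_target <- function(fc, map) {
  map <- as_drug_target_map(map)
  fc |>
    inner_join(map, by = c("feature" = "drug_id"),
               relationship = "many-to-many") |>
    group_by(.data$patient_id, .data$label, feature = .data$protein_id) |>
    summarise(fc_raw = sum(.data$fc_raw), .groups = "drop") |>
    select("patient_id", "feature", "fc_raw", "label")
}

#' Drugs associated with each protein target
#'
#' @param map A drug-target map tibble.
#' @return A tibble `protein_id, drug_ids` (semicolon-collapsed).
#' @export
target_drug_lists <- function(map) {
  as_drug_target_map(map) |>
    group_by(.data$protein_id) |>
    summarise(drug_ids = paste(sort(.data$drug_id), collapse = ";"),
              .groups = "drop")
}
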