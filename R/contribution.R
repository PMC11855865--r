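# Perturbation-based feature contributions (FC) and the relative
# contribution (RC) statistic.
#
# The perturbation is single-occurrence occlusion: one (visit, code)
# occurrence is removed from the otherwise intact sequence and the drop in
# predicted risk is recorded; a patient's FC for a feature is the sum over
# that feature's occurrences. FCs are normalized within patient (share of
# the total absolute contribution, which levels out visit-frequency
# differences between patients), and RC is the ratio of the median
# normalized FC among event patients to the median among non-event patients:
# RC > 1 flags a risk association, RC < 1 a protective one. Significance is
# a Wilcoxon rank-sum test per feature with Benjamini-Hochberg and
# Bonferroni correction across the analysis family.

#' Occlusion feature contributions for one encoded sample
#'
#' @param model An `ehrisk_model`.
#' @param sample One-row `encoded_cohort` subset.
#' @param features Character vector of feature codes to score (default: all
#'   in-vocabulary codes present in the sample).
#' @return A tibble `feature, fc_raw` (features absent from the sample get
#'   no row; scoring them would cost model calls and return exactly 0).
#' @export
occlusion_fc <- function(model, sample, features = NULL) {
  fc <- compute_fc(model, sample, features = features)
  fc[, c("feature", "fc_raw")]
}

#' Occlusion feature contributions for a cohort
#'
#' For every sample and every occurrence of every requested feature, builds
#' the occluded variant (occurrence removed; emptied visits dropped; day
#' gaps recomputed), predicts it in pooled batches, and sums
#' `p(full) - p(occluded)` per (patient, feature). Only exposed patients get
#' rows: a feature absent from a patient contributes exactly 0 and is not
#' materialized.
#'
#' @param model An `ehrisk_model`.
#' @param samples An `encoded_cohort` (typically one primary sample per
#'   patient).
#' @param features Codes to score; default all vocabulary codes except the
#'   OOV token.
#' @param batch_size Prediction batch size for the occluded variants.
#' @return An FC table: `patient_id, feature, fc_raw, label`.
#' @export
compute_fc <- function(model, samples, features = NULL, batch_size = 2048L) {
  # closed-form shortcut for the binary-bag LR path: occluding one of k >= 2
  # occurrences leaves presence intact (contribution 0); occluding a unique
  # occurrence removes the code from the bag. Verified against the generic
  # occlusion path in the test suite.
  if (model$model_kind == "LR") {
    return(compute_fc_lr(model, samples, features))
  }
  compute_fc_occlude(model, samples, features, batch_size)
}

compute_fc_lr <- function(model, samples, features = NULL) {
  vocab <- model$vocab %||% attr(samples, "vocab")
  if (is.null(vocab)) abort("no vocabulary attached to model or samples.")
  features <- features %||% setdiff(vocab$code, OOV_TOKEN)
  feat_idx <- vocab$index[match(features, vocab$code)]
  if (anyNA(feat_idx)) {
    abort(sprintf("feature(s) not in vocabulary: %s",
                  paste(features[is.na(feat_idx)][1:3], collapse = ", ")))
  }
  feat_of_index <- setNames(features, feat_idx)
  w <- model$params$w
  b <- model$params$b
  rows <- purrr::imap(samples$visits, function(vs, i) {
    if (!length(vs)) return(NULL)
    all_codes <- unlist(vs, use.names = FALSE)
    present <- unique(all_codes)
    z_full <- b + sum(w[present])
    p_full <- sigmoid(z_full)
    hit <- intersect(present, feat_idx)
    if (!length(hit)) return(NULL)
    occ_counts <- table(factor(all_codes[all_codes %in% hit], levels = hit))
    fc <- vapply(hit, function(k) {
      if (occ_counts[[as.character(k)]] >= 2L) return(0)
      if (length(present) == 1L && length(vs) == 1L) {
        return(p_full - model$base_rate)   # removal empties the sequence
      }
      p_full - sigmoid(z_full - w[k])
    }, numeric(1))
    tibble(patient_id = samples$patient_id[i],
           feature = unname(feat_of_index[as.character(hit)]),
           fc_raw = unname(fc),
           label = if (samples$label[i] == 1L) "event" else "non-event")
  })
  out <- bind_rows(purrr::compact(rows))
  if (!nrow(out)) {
    return(tibble(patient_id = character(), feature = character(),
                  fc_raw = numeric(), label = character()))
  }
  arrange(out, .data$patient_id, .data$feature)
}

compute_fc_occlude <- function(model, samples, features = NULL, batch_size = 2048L) {
  vocab <- model$vocab %||% attr(samples, "vocab")
  if (is.null(vocab)) abort("no vocabulary attached to model or samples.")
  features <- features %||% setdiff(vocab$code, OOV_TOKEN)
  feat_idx <- vocab$index[match(features, vocab$code)]
  if (anyNA(feat_idx)) {
    abort(sprintf("feature(s) not in vocabulary: %s",
                  paste(features[is.na(feat_idx)][1:3], collapse = ", ")))
  }
  feat_of_index <- setNames(features, feat_idx)
  p_full <- predict_risk(model, samples)

  # enumerate occurrences: one row per (sample, visit position, feature)
  occ <- purrr::imap(samples$visits, function(vs, i) {
    hits <- purrr::imap(vs, function(v, t) {
      f <- intersect(v, feat_idx)
      if (length(f)) tibble(visit = t, index = f) else NULL
    })
    hits <- purrr::compact(hits)
    if (!length(hits)) return(NULL)
    bind_rows(hits) |> mutate(row = i)
  }) |> purrr::compact()
  if (!length(occ)) {
    return(tibble(patient_id = character(), feature = character(),
                  fc_raw = numeric(), label = character()))
  }
  occ <- bind_rows(occ)

  # occluded variants, predicted in pooled batches
  n_occ <- nrow(occ)
  p_occ <- numeric(n_occ)
  for (start in seq(1L, n_occ, by = batch_size)) {
    sel <- start:min(start + batch_size - 1L, n_occ)
    variants <- purrr::map(sel, function(j) {
      i <- occ$row[j]
      occlude_occurrence(samples$visits[[i]], samples$days[[i]],
                         occ$visit[j], occ$index[j])
    })
    vb <- tibble(
      visits = purrr::map(variants, "visits"),
      delta = purrr::map(variants, "delta"),
      label = 0L
    )
    pr <- predict_scores(model$model_kind, model$params, vb, model$config,
                         model$vocab_size)
    pr <- sigmoid(pr)
    pr[is.na(pr)] <- model$base_rate
    p_occ[sel] <- pr
  }

  occ |>
    mutate(fc_one = p_full[.data$row] - p_occ,
           patient_id = samples$patient_id[.data$row],
           label = if_else(samples$label[.data$row] == 1L, "event", "non-event"),
           feature = feat_of_index[as.character(.data$index)]) |>
    group_by(.data$patient_id, .data$feature, .data$label) |>
    summarise(fc_raw = sum(.data$fc_one), .groups = "drop") |>
    select("patient_id", "feature", "fc_raw", "label")
}

occlude_occurrence <- function(visits, days, visit_pos, index) {
  v <- visits[[visit_pos]]
  v <- v[v != index]
  if (length(v)) {
    visits[[visit_pos]] <- v
  } else {
    visits <- visits[-visit_pos]
    days <- days[-visit_pos]
  }
  delta <- if (length(days)) c(0L, diff(days)) else integer(0)
  list(visits = visits, delta = delta)
}

#' Normalize feature contributions within patient
#'
#' `fc_normalized = fc_raw / sum(|fc_raw|)` over the patient's features, so
#' absolute normalized contributions sum to 1 per patient and patients with
#' many encounters do not dominate. Patients whose contributions are all
#' zero keep zeros and are flagged in the `all_zero` column.
#'
#' @param fc An FC table from [compute_fc()].
#' @return The table with `fc_normalized` and `all_zero` columns.
#' @export
normalize_fc <- function(fc) {
  fc |>
    group_by(.data$patient_id) |>
    mutate(denom = sum(abs(.data$fc_raw)),
           all_zero = .data$denom == 0,
           fc_normalized = if_else(.data$all_zero, 0, .data$fc_raw / .data$denom)) |>
    ungroup() |>
    select(-"denom")
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Exact enumeration when the pooled sample size is at most 12 and there are
#' no ties; tie-corrected normal approximation otherwise.
#'
#' @param x,y Non-empty numeric vectors.
#' @return The two-sided p value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty.")
  pooled <- c(x, y)
  if (all(pooled == pooled[1])) return(1)  # fully degenerate: no evidence
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- (length(x) + length(y) <= 12L) && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                correct = !use_exact)$p.value
  )
}

#' Benjamini-Hochberg adjusted q values
#'
#' Step-up adjustment with enforced monotonicity; input order preserved.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted values, same order.
#' @export
adjust_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Bonferroni adjusted p values
#'
#' `min(1, p * m)` with `m = length(p_values)`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted values, same order.
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "bonferroni")
}

#' Relative contribution of a single feature
#'
#' `rc = median(fc_normalized | event) / median(fc_normalized | non-event)`
#' over patients exposed to the feature. A zero non-event median makes the
#' RC undefined (flag `UNDEFINED`); medians of opposite sign make a negative
#' ratio whose direction is not interpretable on the positive RC scale (flag
#' `INDETERMINATE_SIGN`); groups below `min_support` are skipped (flag
#' `LOW_SUPPORT`). Nothing is silently dropped.
#'
#' @param fc A normalized FC table ([normalize_fc()] output).
#' @param feature Feature code.
#' @param min_support Minimum exposed patients per label group (default 10).
#' @return One-row tibble: `feature, rc, p_wilcoxon, n_event_patients,
#'   n_nonevent_patients, direction, flag`.
#' @export
compute_rc <- function(fc, feature, min_support = 10L) {
  rows <- fc |> filter(.data$feature == !!feature)
  ev <- rows$fc_normalized[rows$label == "event"]
  ne <- rows$fc_normalized[rows$label == "non-event"]
  base <- tibble(feature = feature, rc = NA_real_, p_wilcoxon = NA_real_,
                 n_event_patients = length(ev), n_nonevent_patients = length(ne),
                 direction = NA_character_, flag = "OK")
  if (length(ev) < min_support || length(ne) < min_support) {
    base$flag <- "LOW_SUPPORT"
    return(base)
  }
  m_ev <- median(ev)
  m_ne <- median(ne)
  if (m_ne == 0) {
    base$flag <- "UNDEFINED"
    base$p_wilcoxon <- wilcoxon_rank_sum(ev, ne)
    return(base)
  }
  rc <- m_ev / m_ne
  base$rc <- rc
  base$p_wilcoxon <- wilcoxon_rank_sum(ev, ne)
  if (rc < 0) {
    base$flag <- "INDETERMINATE_SIGN"
  } else {
    base$direction <- if (rc > 1) "risk" else "protective"
  }
  base
}

#' Relative-contribution analysis over all features
#'
#' Runs [compute_rc()] for every feature in the table, then applies
#' Benjamini-Hochberg and Bonferroni correction across the features that
#' were actually tested (the analysis family; low-support features are
#' reported but carry no adjusted values).
#'
#' @param fc An FC table (raw; normalization is applied here if the
#'   `fc_normalized` column is missing).
#' @param min_support Minimum exposed patients per label group.
#' @return A tibble of class `ehrisk_rc`: `feature, rc, p_wilcoxon, q_fdr,
#'   p_bonferroni, n_event_patients, n_nonevent_patients, direction, flag`.
#' @export
rc_analysis <- function(fc, min_support = 10L) {
  if (!"fc_normalized" %in% names(fc)) fc <- normalize_fc(fc)
  feats <- sort(unique(fc$feature))
  res <- bind_rows(purrr::map(feats, compute_rc, fc = fc,
                              min_support = min_support))
  tested <- !is.na(res$p_wilcoxon)
  res$q_fdr <- NA_real_
  res$p_bonferroni <- NA_real_
  if (any(tested)) {
    res$q_fdr[tested] <- adjust_fdr(res$p_wilcoxon[tested])
    res$p_bonferroni[tested] <- bonferroni_adjust(res$p_wilcoxon[tested])
  }
  res <- res |>
    select("feature", "rc", "p_wilcoxon", "q_fdr", "p_bonferroni",
           "n_event_patients", "n_nonevent_patients", "direction", "flag")
  class(res) <- c("ehrisk_rc", class(res))
  res
}

#' Significant-feature report
#'
#' Retains features with `q_fdr <= q_cutoff` (and a defined, sign-consistent
#' RC), sorted ascending by RC so protective features lead, with a stable
#' tie-break on the feature name. With a drug-target map, each protein
#' feature is annotated with its associated drug list.
#'
#' @param results An `ehrisk_rc` table.
#' @param q_cutoff FDR cutoff (default 0.05).
#' @param map Optional drug-target map for target-level reports.
#' @return A tibble in report order.
#' @export
rc_report <- function(results, q_cutoff = 0.05, map = NULL) {
  out <- results |>
    filter(!is.na(.data$q_fdr), .data$q_fdr <= q_cutoff, .data$flag == "OK") |>
    arrange(.data$rc, .data$feature)
  if (!is.null(map)) {
    out <- left_join(out, target_drug_lists(map),
                     by = c("feature" = "protein_id"))
  }
  out
}

#' @exportS3Method generics::tidy
tidy.ehrisk_rc <- function(x, ...) as_tibble(x)

#' @exportS3Method generics::glance
glance.ehrisk_rc <- function(x, ...) {
  tested <- !is.na(x$p_wilcoxon)
  tibble(
    n_features = nrow(x),
    n_tested = sum(tested),
    n_significant = sum(x$q_fdr <= 0.05 & x$flag == "OK", na.rm = TRUE),
    n_risk = sum(x$direction == "risk" & x$q_fdr <= 0.05, na.rm = TRUE),
    n_protective = sum(x$direction == "protective" & x$q_fdr <= 0.05, na.rm = TRUE),
    n_skipped = sum(x$flag == "LOW_SUPPORT")
  )
}
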