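# Cohort rules on hand-constructed timelines. Day numbers are offsets from a
# fixed origin; the look-back is 365 days and the outcome window 90 days.

spec <- cohort_spec(ad_codes = "G30", psychosis_codes = "F29",
                    antipsychotic_codes = "RXANTIPSY", delirium_codes = "F05")

test_that("delirium masking removes only same-day psychosis records", {
  stream <- dplyr::bind_rows(
    ev("A", 10, "DIAG", "F29"), ev("A", 10, "DIAG", "F05"),   # same day: masked
    ev("B", 10, "DIAG", "F29"),                               # no delirium: kept
    ev("C", 10, "DIAG", "F05"), ev("C", 11, "DIAG", "F29")    # next day: kept
  )
  out <- mask_delirium_psychosis(stream, spec)
  expect_false(any(out$patient_id == "A" & out$code == "F29"))
  expect_true(any(out$patient_id == "B" & out$code == "F29"))
  expect_true(any(out$patient_id == "C" & out$code == "F29"))
  expect_true(any(out$patient_id == "C" & out$code == "F05"))
  empty <- stream[0, ]
  expect_identical(nrow(mask_delirium_psychosis(empty, spec)), 0L)
})

test_that("psychosis and delirium code sets may not overlap", {
  expect_error(cohort_spec(psychosis_codes = "F29", delirium_codes = c("F05", "F29")),
               "disjoint")
})

test_that("label_patient applies every inclusion and exclusion rule", {
  tl <- cohort_fixture()
  r <- label_patient(tl$case_plain, spec)
  expect_identical(r$status, "case")
  expect_identical(r$sample$index_date, day0 + 410)  # 450 - 410 = 40 <= 90

  expect_identical(label_patient(tl$case_rx, spec)$status, "case")
  r <- label_patient(tl$control_plain, spec)
  expect_identical(r$status, "control")
  expect_identical(r$sample$index_date, day0 + 500)  # latest encounter

  expect_identical(label_patient(tl$control_far, spec)$status, "control")
  expect_identical(label_patient(tl$no_ad, spec)$reason, "NO_AD")
  expect_identical(label_patient(tl$short_history, spec)$reason, "INSUFFICIENT_HISTORY")
  expect_identical(label_patient(tl$prior_psy, spec)$reason, "PRIOR_PSYCHOSIS")
  expect_identical(label_patient(tl$prior_rx, spec)$reason, "PRIOR_ANTIPSYCHOTIC")
  expect_identical(label_patient(tl$ad_last, spec)$reason, "NO_ELIGIBLE_ENCOUNTER")

  r <- label_patient(tl$same_day, spec)
  expect_identical(r$status, "case")
  expect_identical(r$sample$index_date, day0 + 400)  # day-450 candidate disqualified

  unsorted <- tl$case_plain[c(3, 1, 2, 4, 5), ]
  expect_error(label_patient(unsorted, spec), "sorted")
})

test_that("sample windows never overlap the outcome window", {
  tl <- cohort_fixture()
  for (nm in c("case_plain", "case_rx", "control_plain", "same_day")) {
    r <- label_patient(tl[[nm]], spec)
    ev_dates <- r$sample$events[[1]]$date
    expect_true(all(ev_dates < r$sample$index_date))
    expect_true(all(ev_dates >= r$sample$index_date - 365))
  }
})

test_that("case, control and exclusion counts partition the input patients", {
  stream <- dplyr::bind_rows(cohort_fixture())
  co <- build_cohort(stream, spec)
  expect_identical(
    nrow(dplyr::distinct(co$samples, patient_id)) + nrow(co$exclusions),
    co$n_patients
  )
  expect_identical(sort(co$exclusions$reason),
                   sort(c("NO_AD", "INSUFFICIENT_HISTORY", "PRIOR_PSYCHOSIS",
                          "PRIOR_ANTIPSYCHOTIC", "NO_ELIGIBLE_ENCOUNTER")))
})

test_that("on synthetic data every case outcome is in-window and controls have none", {
  x <- small_encoded()
  samples <- x$cohort$samples |> dplyr::filter(provenance == "index")
  outcome_events <- x$sim$stream |>
    dplyr::filter(code %in% c("F29", "RXANTIPSY"))
  for (i in seq_len(nrow(samples))) {
    pid <- samples$patient_id[i]
    idx <- samples$index_date[i]
    out_dates <- outcome_events$date[outcome_events$patient_id == pid]
    hits <- out_dates > idx & out_dates <= idx + 90
    if (samples$label[i] == "case") expect_true(any(hits)) else expect_false(any(hits))
  }
})

test_that("augmentation re-anchors cases without touching controls", {
  # three eligible case anchors: outcome at day 450 covers encounters 380..430
  tl <- timeline_of("multi", list(
    ev("multi", 0, "DIAG", "G30"), ev("multi", 10, "MED", "DB1"),
    ev("multi", 380, "DIAG", "DX1"), ev("multi", 400, "DIAG", "DX2"),
    ev("multi", 430, "LAB_ABN", "L1"), ev("multi", 450, "DIAG", "F29")))
  ctrl <- cohort_fixture()$control_plain
  stream <- dplyr::bind_rows(tl, ctrl)

  co <- build_cohort(stream, cohort_spec(augmentation_max_per_case = 2))
  aug <- augment_cases(co, seed = 1)
  multi <- aug$samples |> dplyr::filter(patient_id == "multi")
  expect_identical(nrow(multi), 3L)  # primary + 2 augmented
  expect_identical(sum(multi$provenance == "index"), 1L)
  expect_identical(multi$index_date[multi$provenance == "index"], day0 + 430)
  expect_true(all(aug$samples$label[aug$samples$patient_id == "control_plain"] == "control"))
  expect_identical(sum(aug$samples$patient_id == "control_plain"), 1L)

  co1 <- build_cohort(stream, cohort_spec(augmentation_max_per_case = 1))
  expect_identical(nrow(augment_cases(co1, seed = 1)$samples |>
                          dplyr::filter(patient_id == "multi")), 2L)

  co0 <- build_cohort(stream, cohort_spec(augmentation_max_per_case = 0))
  expect_identical(augment_cases(co0, seed = 1)$samples, co0$samples)
})

test_that("splitting is patient-level, 8:1:1, seeded and leakage-free", {
  samples <- tibble::tibble(
    patient_id = rep(sprintf("P%03d", 1:100), times = c(rep(1, 99), 3)),
    index_date = day0 + seq_len(102),
    label = "control", provenance = "index", events = replicate(102, list())
  )
  sp <- split_cohort(samples, seed = 4)
  by_patient <- sp |> dplyr::distinct(patient_id, split)
  expect_identical(nrow(by_patient), 100L)  # each patient in exactly one split
  expect_identical(as.vector(table(by_patient$split)[c("train", "validation", "test")]),
                   c(80L, 10L, 10L))
  expect_identical(dplyr::n_distinct(sp$split[sp$patient_id == "P100"]), 1L)

  expect_identical(split_cohort(samples, seed = 4)$split, sp$split)
  sp2 <- split_cohort(samples, seed = 5)
  expect_false(identical(sp2$split, sp$split))
  expect_identical(table(sp2$split), table(sp$split))

  expect_error(split_cohort(samples[1:5, ], seed = 1), "at least 10")
})
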