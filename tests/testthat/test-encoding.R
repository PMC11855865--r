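lookup <- tibble::tibble(icd9 = c("331.0", "290.20", "295.9"),
                         icd10_group = c("G30", "F05", "F29"))

test_that("ICD-9 codes map through the lookup and ICD-10 codes truncate", {
  expect_identical(map_icd9_to_icd10("331.0", lookup), "G30")
  expect_identical(map_icd9_to_icd10("G30.9", lookup), "G30")
  expect_identical(map_icd9_to_icd10(c("331.0", "295.9", "F20.1"), lookup),
                   c("G30", "F29", "F20"))
  expect_warning(out <- map_icd9_to_icd10("999.99", lookup), "not mappable")
  expect_identical(out, "<OOV>")
  expect_error(map_icd9_to_icd10(c("331.0", ""), lookup), "row")
})

test_that("the bundled synthetic lookup fixture loads and maps", {
  path <- system.file("extdata", "icd9_to_icd10_synthetic.tsv", package = "ehrisk")
  lk <- read_icd_lookup(path)
  expect_true(all(c("icd9", "icd10_group") %in% names(lk)))
  expect_identical(map_icd9_to_icd10("331.0", lk), "G30")
})

make_samples <- function(rows_per_patient) {
  tibble::tibble(
    patient_id = names(rows_per_patient),
    index_date = day0 + 400,
    label = "control", provenance = "index",
    events = unname(rows_per_patient)
  )
}

test_that("vocabulary caps labs at top-K with deterministic tie-breaks", {
  # 100 lab codes with patient-frequencies 100..1
  events <- purrr::map(1:100, function(p) {
    labs <- sprintf("LAB%03d", 1:p)
    tibble::tibble(date = day0 + 1, code_type = "LAB_ABN", code = labs)
  })
  samples <- make_samples(setNames(events, sprintf("P%03d", 1:100)))
  vocab <- build_vocabulary(samples, lab_top_k = 89)
  labs <- vocab$code[vocab$code_type == "LAB_ABN"]
  expect_identical(length(labs), 89L)
  # most frequently tested labs survive: LAB001 tested by all 100 patients
  expect_true("LAB001" %in% labs)
  expect_false("LAB100" %in% labs)

  # equal-frequency codes take lexicographic order; rebuilt vocab identical
  tie_samples <- make_samples(list(
    A = tibble::tibble(date = day0 + 1, code_type = "DIAG", code = c("DXB", "DXA")),
    B = tibble::tibble(date = day0 + 2, code_type = "DIAG", code = c("DXA", "DXB"))
  ))
  v1 <- build_vocabulary(tie_samples)
  expect_lt(v1$index[v1$code == "DXA"], v1$index[v1$code == "DXB"])
  expect_identical(v1, build_vocabulary(tie_samples))

  expect_error(build_vocabulary(samples[0, ]), "empty")
})

test_that("vocabulary honours the overall cap and reserves the OOV slot", {
  samples <- make_samples(list(
    A = tibble::tibble(date = day0 + 1, code_type = "DIAG",
                       code = sprintf("DX%02d", 1:20))
  ))
  v <- build_vocabulary(samples, max_size = 11)
  expect_identical(nrow(v), 11L)
  expect_identical(v$code[v$index == 1L], "<OOV>")
  expect_identical(sort(v$index), 1:11)
})

test_that("encoding produces day gaps, dedup within visit, and OOV indices", {
  vocab <- vocab_of(c("DXA", "DXB", "DB1"), c("DIAG", "DIAG", "MED"))
  samples <- make_samples(list(
    A = tibble::tibble(
      date = day0 + c(0, 0, 7, 37, 37),
      code_type = c("DIAG", "DIAG", "MED", "DIAG", "DIAG"),
      code = c("DXA", "DXA", "DB1", "DXB", "UNSEEN"))
  ))
  enc <- encode_samples(samples, vocab)
  expect_identical(enc$delta[[1]], c(0L, 7L, 30L))
  # duplicate DXA collapses to one index; UNSEEN becomes the OOV index
  expect_identical(enc$visits[[1]][[1]], vocab$index[vocab$code == "DXA"])
  expect_setequal(enc$visits[[1]][[3]],
                  c(vocab$index[vocab$code == "DXB"], 1L))

  single <- make_samples(list(
    B = tibble::tibble(date = day0 + 3, code_type = "DIAG", code = "DXA")))
  enc1 <- encode_samples(single, vocab)
  expect_identical(length(enc1$visits[[1]]), 1L)
  expect_identical(enc1$delta[[1]], 0L)
})

test_that("decoding restores the in-vocabulary code sets per visit", {
  x <- small_encoded()
  dec <- decode_sample(x$enc[1:5, ])
  for (i in 1:5) {
    orig <- x$enc$codes[[i]]
    vocab_codes <- x$vocab$code
    expected <- purrr::map(orig, function(cs) {
      sort(ifelse(cs %in% vocab_codes, cs, "<OOV>"))
    })
    expect_identical(dec[[i]], expected)
  }
})

test_that("ablation removes one code type, drops emptied visits, recomputes gaps", {
  vocab <- vocab_of(c("DXA", "DB1", "L1"), c("DIAG", "MED", "LAB_ABN"))
  i <- function(code) vocab$index[vocab$code == code]
  enc <- encoded_of(
    visits = list(list(i("DXA"), c(i("DB1")), c(i("DXA"), i("DB1")))),
    days = list(c(0L, 10L, 40L)),
    labels = 1, vocab = vocab
  )
  out <- ablate_codes(enc, "MED")
  expect_identical(length(out$visits[[1]]), 2L)     # middle visit emptied
  expect_identical(out$delta[[1]], c(0L, 40L))      # gap recomputed across gap
  expect_identical(out$visits[[1]][[2]], i("DXA"))  # set difference per visit

  # dropping a type the sample lacks is a no-op
  expect_identical(ablate_codes(out, "LAB_ABN")$visits, out$visits)
  expect_error(ablate_codes(enc, "PROCEDURE"), "one of")
})

test_that("ablating events before encoding matches ablating encoded indices", {
  x <- small_encoded()
  samples <- x$cohort$samples
  vocab_all <- build_vocabulary(samples)  # no OOV: every code indexed
  stripped <- samples
  stripped$events <- purrr::map(stripped$events, function(e) {
    dplyr::filter(e, code_type != "MED")
  })
  enc_then_abl <- ablate_codes(encode_samples(samples, vocab_all), "MED", vocab_all)
  abl_then_enc <- encode_samples(stripped, vocab_all)
  expect_identical(purrr::map(enc_then_abl$visits, function(v) purrr::map(v, sort)),
                   purrr::map(abl_then_enc$visits, function(v) purrr::map(v, sort)))
  expect_identical(enc_then_abl$delta, abl_then_enc$delta)
})
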