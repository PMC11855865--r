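test_that("occlusion FC under a logistic bag model equals the closed form", {
  vocab <- vocab_of(c("A", "B", "C", "D"), rep("DIAG", 4))
  i <- function(code) vocab$index[vocab$code == code]
  w <- c(A = 0.9, B = -0.6, C = 0.3)
  m <- lr_model_with_weights(vocab, w, bias = -0.5)
  enc <- encoded_of(
    visits = list(list(c(i("A"), i("B")), i("C"))),
    days = list(c(0L, 20L)), labels = 1, vocab = vocab
  )
  fc <- compute_fc(m, enc)
  z <- -0.5 + 0.9 - 0.6 + 0.3
  for (code in names(w)) {
    expect_equal(fc$fc_raw[fc$feature == code],
                 plogis(z) - plogis(z - w[[code]]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # absent feature: no row materialized
  expect_identical(nrow(compute_fc(m, enc, features = "D")), 0L)
  expect_identical(nrow(compute_fc(m, enc, features = "A")), 1L)
})

test_that("the LR closed-form FC path equals the generic occlusion path", {
  x <- small_encoded()
  m <- train_risk_model(x$train, x$val,
                        model_config("LR", max_epochs = 8, seed = 3))
  prim <- x$enc[1:40, ]
  attr(prim, "vocab") <- x$vocab
  fast <- compute_fc(m, prim)
  slow <- ehrisk:::compute_fc_occlude(m, prim)
  joined <- dplyr::inner_join(fast, slow, by = c("patient_id", "feature", "label"),
                              suffix = c("_fast", "_slow"))
  expect_identical(nrow(joined), nrow(fast))
  expect_identical(nrow(fast), nrow(slow))
  expect_equal(joined$fc_raw_fast, joined$fc_raw_slow, tolerance = 1e-12)
})

test_that("a code present in two visits contributes per-occurrence occlusions", {
  vocab <- vocab_of(c("A", "B"), rep("DIAG", 2))
  i <- function(code) vocab$index[vocab$code == code]
  m <- lr_model_with_weights(vocab, c(A = 1.2, B = 0.4), bias = 0)
  enc <- encoded_of(
    visits = list(list(c(i("A"), i("B")), i("A"))),
    days = list(c(0L, 30L)), labels = 1, vocab = vocab
  )
  fc <- compute_fc(m, enc)
  # binary bag: removing one of two A-occurrences leaves presence intact, so
  # each occlusion contributes zero and the per-patient sum stays zero
  expect_equal(fc$fc_raw[fc$feature == "A"], 0)
  # B occurs once; its occlusion flips presence
  z <- 1.2 + 0.4
  expect_equal(fc$fc_raw[fc$feature == "B"], plogis(z) - plogis(z - 0.4))
})

test_that("normalization yields per-patient absolute shares summing to one", {
  fc <- tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P3"),
    feature = c("A", "B", "A", "A"),
    fc_raw = c(0.3, 0.1, -0.2, 0),
    label = "event"
  )
  out <- normalize_fc(fc)
  expect_equal(out$fc_normalized[out$patient_id == "P1"], c(0.75, 0.25))
  expect_equal(out$fc_normalized[out$patient_id == "P2"], -1)
  expect_identical(out$fc_normalized[out$patient_id == "P3"], 0)
  expect_true(out$all_zero[out$patient_id == "P3"])
  expect_false(any(out$all_zero[out$patient_id != "P3"]))
})

test_that("RC is the ratio of group medians with directional flags", {
  fc <- tibble::tibble(
    patient_id = sprintf("P%d", 1:6),
    feature = "F",
    fc_raw = c(0.2, 0.4, 0.6, 0.1, 0.2, 0.3),
    fc_normalized = c(0.2, 0.4, 0.6, 0.1, 0.2, 0.3),
    label = rep(c("event", "non-event"), each = 3)
  )
  r <- compute_rc(fc, "F", min_support = 3)
  expect_equal(r$rc, 2)       # 0.4 / 0.2
  expect_identical(r$direction, "risk")

  fc$fc_normalized <- c(0.1, 0.1, 0.1, 0.2, 0.2, 0.2)
  r <- compute_rc(fc, "F", min_support = 3)
  expect_equal(r$rc, 0.5)
  expect_identical(r$direction, "protective")

  fc$fc_normalized <- rep(c(0.1, 0.2, 0.3), 2)
  expect_equal(compute_rc(fc, "F", min_support = 3)$rc, 1)

  fc$fc_normalized <- c(0.1, 0.2, 0.3, -0.1, 0, 0.1)
  r <- compute_rc(fc, "F", min_support = 3)
  expect_identical(r$flag, "UNDEFINED")
  expect_true(is.na(r$rc))

  fc$fc_normalized <- c(0.1, 0.2, 0.3, -0.3, -0.2, -0.1)
  expect_identical(compute_rc(fc, "F", min_support = 3)$flag, "INDETERMINATE_SIGN")

  expect_identical(compute_rc(fc, "F", min_support = 10)$flag, "LOW_SUPPORT")
})

test_that("the Wilcoxon wrapper matches full enumeration and handles ties", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)  # 2/20 by enumeration
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  set.seed(5)
  for (rep in 1:25) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    v <- sample(1:100, nx + ny)  # distinct values, exact path
    x <- v[1:nx]; y <- v[(nx + 1):(nx + ny)]
    expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_enum_p(x, y), tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("the approximate Wilcoxon holds its nominal type-I error rate", {
  set.seed(9)
  rejections <- mean(replicate(1000, {
    wilcoxon_rank_sum(rnorm(50), rnorm(50)) < 0.05
  }))
  expect_gte(rejections, 0.03)
  expect_lte(rejections, 0.07)
})

test_that("BH and Bonferroni match brute-force implementations", {
  expect_equal(adjust_fdr(c(0.001, 0.01, 0.02, 0.05)),
               c(0.004, 0.02, 0.02 * 4 / 3, 0.05))
  expect_identical(adjust_fdr(0.03), 0.03)
  expect_identical(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(13)
  for (rep in 1:30) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_fdr(p), bh_brute(p), tolerance = 1e-12)
    expect_equal(bonferroni_adjust(p), pmin(1, p * length(p)), tolerance = 1e-12)
  }
  expect_equal(bonferroni_adjust(c(0.01, 0.2, 0.3, 0.4))[1], 0.04)
  expect_identical(bonferroni_adjust(c(0.5, rep(0.9, 9)))[1], 1)
  expect_identical(bonferroni_adjust(0.42), 0.42)
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("rc_report filters by q, sorts protective-first, ties broken by name", {
  res <- tibble::tibble(
    feature = c("K", "A", "B", "Z", "Q"),
    rc = c(1.96, 0.29, 0.52, 0.52, 3.0),
    p_wilcoxon = c(0.001, 0.001, 0.001, 0.001, 0.2),
    q_fdr = c(0.01, 0.01, 0.01, 0.01, 0.4),
    p_bonferroni = c(0.04, 0.04, 0.04, 0.04, 1),
    n_event_patients = 20L, n_nonevent_patients = 40L,
    direction = c("risk", "protective", "protective", "protective", "risk"),
    flag = "OK"
  )
  class(res) <- c("ehrisk_rc", class(res))
  rep1 <- rc_report(res)
  expect_identical(rep1$feature, c("A", "B", "Z", "K"))
  expect_identical(rep1$rc, c(0.29, 0.52, 0.52, 1.96))

  res$q_fdr <- 0.2
  expect_identical(nrow(rc_report(res)), 0L)
})

test_that("rc_analysis corrects across the tested family only", {
  set.seed(3)
  mkfc <- function(feature, shift, n = 24) {
    tibble::tibble(
      patient_id = paste0(feature, 1:n),
      feature = feature,
      fc_raw = rnorm(n, mean = rep(c(shift, 0), each = n / 2), sd = 0.1),
      label = rep(c("event", "non-event"), each = n / 2)
    )
  }
  fc <- dplyr::bind_rows(mkfc("SIG", 0.8), mkfc("NUL", 0),
                         mkfc("RARE", 0.8, n = 6))
  res <- rc_analysis(fc, min_support = 10)
  expect_identical(res$flag[res$feature == "RARE"], "LOW_SUPPORT")
  expect_true(is.na(res$q_fdr[res$feature == "RARE"]))
  tested <- res[!is.na(res$p_wilcoxon), ]
  expect_equal(tested$q_fdr, bh_brute(tested$p_wilcoxon))
  expect_equal(tested$p_bonferroni, pmin(1, tested$p_wilcoxon * nrow(tested)))
  expect_lt(res$q_fdr[res$feature == "SIG"], 0.05)
})
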