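test_that("time decay is 1 at zero, strictly decreasing, and matches its closed form", {
  expect_identical(tlstm_decay(0), 1)
  d <- tlstm_decay(0:400)
  expect_true(all(diff(d) < 0))
  expect_true(all(d > 0 & d <= 1))
  expect_gt(tlstm_decay(30), tlstm_decay(365))
  expect_equal(tlstm_decay(50), 1 / log(exp(1) + 50))
  expect_error(tlstm_decay(-1), "non-negative")
})

test_that("rank-statistic AUROC agrees with pairwise brute force and null behaviour", {
  brute <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    expect_equal(auroc(s, y), brute(s, y))
  }
  expect_identical(auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auroc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  set.seed(12)
  y <- rep(0:1, each = 5000)
  expect_lt(abs(auroc(runif(10000), y) - 0.5), 0.02)
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("LR predictions follow the logistic closed form on binary bags", {
  vocab <- vocab_of(c("A", "B", "C"), rep("DIAG", 3))
  m <- lr_model_with_weights(vocab, c(A = 0.7, B = -1.2, C = 0.4), bias = -0.3)
  i <- function(code) vocab$index[vocab$code == code]
  enc <- encoded_of(
    visits = list(list(c(i("A"), i("B"))), list(i("C")), list()),
    days = list(0L, 0L, integer(0)),
    labels = c(1, 0, 0), vocab = vocab
  )
  p <- predict_risk(m, enc)
  expect_equal(p[1], plogis(-0.3 + 0.7 - 1.2))
  expect_equal(p[2], plogis(-0.3 + 0.4))
  # empty sequence falls back to the flagged base rate
  expect_equal(p[3], m$base_rate)
  expect_identical(attr(p, "empty_sequence"), 3L)

  # appending a duplicate visit leaves the binary bag unchanged
  enc_dup <- encoded_of(
    visits = list(list(c(i("A"), i("B")), c(i("A"), i("B")))),
    days = list(c(0L, 0L)), labels = 1, vocab = vocab
  )
  expect_equal(predict_risk(m, enc_dup)[1], p[1])
  # all-zero bag gives sigmoid of the bias
  enc0 <- encoded_of(visits = list(list(1L)), days = list(0L), labels = 0,
                     vocab = vocab)
  m0 <- lr_model_with_weights(vocab, c(A = 0, B = 0, C = 0), bias = -0.3)
  expect_equal(predict_risk(m0, enc0)[1], plogis(-0.3))
})

test_that("hand-derived gradients match finite differences for every architecture", {
  set.seed(7)
  ns <- asNamespace("ehrisk")
  V <- 9
  visits <- list(list(c(2L, 3L), 5L, c(4L, 7L)), list(c(8L, 9L)), list(3L, c(2L, 6L)))
  delta <- list(c(0, 7, 30), c(0), c(0, 12))
  for (kind in c("RNN", "TLSTM", "RETAIN")) {
    cfg <- model_config(kind, embedding_dim = 5, hidden_dim = 4, n_layers = 2,
                        dropout = 0)
    batch <- ns$nn_make_batch(visits, delta, c(1, 0, 1), reverse = kind == "RETAIN")
    p <- ns$nn_init_params(kind, V, cfg)
    lg <- ns$nn_loss_and_grads(kind, p, batch, cfg)
    eps <- 1e-5
    for (nm in names(p)) {
      for (j in seq_len(min(length(p[[nm]]), 4))) {
        p2 <- p
        p2[[nm]][j] <- p2[[nm]][j] + eps
        f1 <- ns$nn_loss_and_grads(kind, p2, batch, cfg)$loss
        p2[[nm]][j] <- p2[[nm]][j] - 2 * eps
        f0 <- ns$nn_loss_and_grads(kind, p2, batch, cfg)$loss
        expect_lt(abs((f1 - f0) / (2 * eps) - lg$grads[[nm]][j]), 1e-7)
      }
    }
  }
})

test_that("training is seed-deterministic and stops on stale validation AUROC", {
  x <- small_encoded()
  cfg <- model_config("RNN", embedding_dim = 8, hidden_dim = 8, n_layers = 1,
                      max_epochs = 3, seed = 5)
  m1 <- train_risk_model(x$train, x$val, cfg)
  m2 <- train_risk_model(x$train, x$val, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  # zero learning rate: AUROC can never improve after epoch 1, so training
  # halts exactly patience epochs later
  frozen <- model_config("LR", max_epochs = 10, patience = 3, learning_rate = 0,
                         weight_decay = 0, seed = 5)
  mf <- train_risk_model(x$train, x$val, frozen)
  expect_identical(mf$stopped_epoch, 4L)
  expect_identical(mf$best_epoch, 1L)

  one <- train_risk_model(x$train, x$val,
                          model_config("LR", max_epochs = 1, seed = 5))
  expect_identical(one$stopped_epoch, 1L)
})

test_that("LR separates a label-revealing code and matches a glm oracle", {
  vocab <- vocab_of(c("X", "N1", "N2"), rep("DIAG", 3))
  i <- function(code) vocab$index[vocab$code == code]
  set.seed(42)
  n <- 400
  has_x <- rbinom(n, 1, 0.5)
  visits <- purrr::map(seq_len(n), function(k) {
    idx <- c(if (has_x[k]) i("X"), if (runif(1) < 0.5) i("N1"), i("N2"))
    list(idx)
  })
  enc <- encoded_of(visits, days = purrr::map(seq_len(n), function(k) 0L),
                    labels = has_x, vocab = vocab)
  tr <- enc[1:300, ]; va <- enc[301:400, ]
  attr(tr, "vocab") <- vocab; attr(va, "vocab") <- vocab
  m <- train_risk_model(tr, va, model_config("LR", max_epochs = 60,
                                             learning_rate = 0.05,
                                             weight_decay = 0, seed = 2))
  expect_gt(max(m$history$val_auroc), 0.99)

  # independent oracle: glm on the same design matrix ranks identically
  X <- ehrisk:::lr_features(enc$visits, nrow(vocab))
  fit <- suppressWarnings(glm(has_x ~ X[, 2:4], family = binomial()))
  expect_equal(auroc(predict(fit, type = "response")[301:400], has_x[301:400]),
               auroc(predict_risk(m, va), has_x[301:400]))

  # single-class split is rejected
  bad <- enc[which(has_x == 1)[1:20], ]
  attr(bad, "vocab") <- vocab
  expect_error(train_risk_model(bad, va, model_config("LR")), "single class")
})

test_that("evaluation reports rank AUROC and threshold metrics, rejecting one-class sets", {
  vocab <- vocab_of("A", "DIAG")
  m <- lr_model_with_weights(vocab, c(A = 2), bias = -1)
  m$threshold <- 0.5
  enc <- encoded_of(visits = list(list(2L), list(2L), list(1L), list(1L)),
                    days = rep(list(0L), 4), labels = c(1, 1, 0, 0),
                    vocab = vocab)
  ev <- evaluate_model(m, enc)
  expect_identical(ev$auroc, 1)          # all case scores exceed control scores
  expect_identical(ev$f1, 1)
  expect_identical(ev$n_cases, 2L)
  one_class <- enc[1:2, ]
  expect_error(evaluate_model(m, one_class), "single class")
})
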