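# Shared fixtures, all built in code.

day0 <- as.Date("2018-01-01")

# one event row
ev <- function(pid, day, type, code) {
  tibble::tibble(patient_id = pid, date = day0 + day, code_type = type, code = code)
}

# a hand-built timeline: AD early, configurable extras
timeline_of <- function(pid, rows) {
  dplyr::arrange(dplyr::bind_rows(rows), date)
}

default_spec <- function(...) {
  cohort_spec(ad_codes = "G30", psychosis_codes = "F29",
              antipsychotic_codes = "RXANTIPSY", delirium_codes = "F05", ...)
}

# small simulated cohort, encoded and split; cached per test file run
small_encoded <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_patients = 250, seed = 402,
                      effects = c(DX01 = 2, DB00101 = -2))
    sim <- generate_cohort_stream(cfg)
    co <- build_cohort(sim$stream, default_spec())
    sp <- split_cohort(co$samples, seed = 3)
    vocab <- build_vocabulary(dplyr::filter(sp, split == "train"))
    enc <- encode_samples(sp, vocab)
    cache <<- list(cfg = cfg, sim = sim, cohort = co, enc = enc, vocab = vocab,
                   train = dplyr::filter(enc, split == "train"),
                   val = dplyr::filter(enc, split == "validation"),
                   test = dplyr::filter(enc, split == "test"))
    cache
  }
})

# hand-constructed LR model with known weights over a given vocabulary
lr_model_with_weights <- function(vocab, weights, bias) {
  w <- numeric(nrow(vocab))
  idx <- vocab$index[match(names(weights), vocab$code)]
  stopifnot(!anyNA(idx))
  w[idx] <- weights
  structure(list(
    model_kind = "LR",
    params = list(w = w, b = bias),
    vocab = vocab, vocab_size = nrow(vocab),
    config = model_config("LR"),
    history = tibble::tibble(epoch = 1L, train_loss = 0, val_auroc = NA_real_),
    stopped_epoch = 1L, best_epoch = 1L,
    base_rate = 0.5, threshold = 0.5
  ), class = "ehrisk_model")
}

# a minimal vocabulary over explicit codes
vocab_of <- function(codes, types) {
  v <- tibble::tibble(code = c("<OOV>", codes),
                      code_type = c("OOV", types),
                      index = seq_len(length(codes) + 1L))
  class(v) <- c("ehr_vocab", class(v))
  v
}

# encoded-cohort tibble built by hand from visit index lists
encoded_of <- function(visits, days, labels, vocab,
                       patient_id = NULL) {
  n <- length(visits)
  patient_id <- patient_id %||% sprintf("HP%03d", seq_len(n))
  out <- tibble::tibble(
    sample_id = paste0(patient_id, "@x"),
    patient_id = patient_id,
    label = as.integer(labels),
    visits = visits,
    codes = purrr::map(visits, function(vs) purrr::map(vs, function(v) {
      vocab$code[match(v, vocab$index)]
    })),
    days = days,
    delta = purrr::map(days, function(d) if (length(d)) c(0L, diff(d)) else integer(0))
  )
  attr(out, "vocab") <- vocab
  class(out) <- c("encoded_cohort", class(out))
  out
}

`%||%` <- rlang::`%||%`

# independent oracle: exact two-sided Wilcoxon rank-sum p by full enumeration
wilcoxon_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(x)])
  combos <- utils::combn(n, length(x))
  ws <- apply(combos, 2, function(ix) sum(r[ix]))
  mu <- length(x) * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# independent oracle: BH step-up by direct formula
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

sim_origin <- as.Date("2015-01-01")

# ---- synthetic study protocol ----------------------------------------------
# Training settings for the desk-scale synthetic studies (30-code catalogs,
# 1000-5000 patients): dimensions scaled to the problem, stronger weight
# decay, longer patience. Documented in the methods vignette.
study_model <- function(kind, seed, max_epochs = 40, patience = 15, ...) {
  model_config(kind, embedding_dim = 32, hidden_dim = 32,
               learning_rate = 5e-3, weight_decay = 0.03,
               max_epochs = max_epochs, patience = patience, seed = seed, ...)
}

# simulate -> cohort -> split -> vocabulary -> encode, at one seed
study_encode <- function(cfg, seed) {
  sim <- generate_cohort_stream(cfg)
  co <- build_cohort(sim$stream, cohort_spec())
  sp <- split_cohort(co$samples, seed = seed)
  vocab <- build_vocabulary(dplyr::filter(sp, split == "train"))
  enc <- encode_samples(sp, vocab)
  list(sim = sim, cohort = co, enc = enc, vocab = vocab,
       train = dplyr::filter(enc, split == "train"),
       val = dplyr::filter(enc, split == "validation"),
       test = dplyr::filter(enc, split == "test"),
       primary = dplyr::filter(enc, provenance == "index"))
}

# attribution-stability ensemble: average occlusion FCs over independently
# trained model replicates (spurious single-model weights cancel)
ensemble_fc <- function(x, kind, seed, n_models = 3L, features = NULL, ...) {
  fcs <- purrr::map(seq_len(n_models), function(k) {
    m <- train_risk_model(x$train, x$val, study_model(kind, seed * 100 + k, ...))
    compute_fc(m, x$primary, features = features)
  })
  dplyr::bind_rows(fcs) |>
    dplyr::group_by(patient_id, feature, label) |>
    dplyr::summarise(fc_raw = mean(fc_raw), .groups = "drop")
}

# ten timelines covering every labeling path
cohort_fixture <- function() {
  list(
    # case: AD day 0, encounters through day 410, psychosis day 450
    case_plain = timeline_of("case_plain", list(
      ev("case_plain", 0, "DIAG", "G30"), ev("case_plain", 200, "MED", "DB1"),
      ev("case_plain", 400, "DIAG", "DX1"), ev("case_plain", 410, "LAB_ABN", "L1"),
      ev("case_plain", 450, "DIAG", "F29"))),
    # case via antipsychotic order instead of psychosis diagnosis
    case_rx = timeline_of("case_rx", list(
      ev("case_rx", 0, "DIAG", "G30"), ev("case_rx", 380, "DIAG", "DX1"),
      ev("case_rx", 430, "MED", "RXANTIPSY"))),
    # control: no outcome anywhere, anchored at latest encounter
    control_plain = timeline_of("control_plain", list(
      ev("control_plain", 0, "DIAG", "G30"), ev("control_plain", 100, "MED", "DB1"),
      ev("control_plain", 400, "DIAG", "DX2"), ev("control_plain", 500, "LAB_ABN", "L1"))),
    # control: outcome exists but > 90 d after every eligible encounter
    control_far = timeline_of("control_far", list(
      ev("control_far", 0, "DIAG", "G30"), ev("control_far", 400, "DIAG", "DX1"),
      ev("control_far", 600, "DIAG", "F29"))),
    # excluded: no AD diagnosis at all
    no_ad = timeline_of("no_ad", list(
      ev("no_ad", 0, "DIAG", "DX1"), ev("no_ad", 400, "DIAG", "DX2"))),
    # excluded: AD present but < 365 d of record before any candidate
    short_history = timeline_of("short_history", list(
      ev("short_history", 0, "DIAG", "G30"), ev("short_history", 100, "DIAG", "DX1"))),
    # excluded: psychosis before any eligible index
    prior_psy = timeline_of("prior_psy", list(
      ev("prior_psy", 0, "DIAG", "G30"), ev("prior_psy", 50, "DIAG", "F29"),
      ev("prior_psy", 400, "DIAG", "DX1"))),
    # excluded: antipsychotic order before AD
    prior_rx = timeline_of("prior_rx", list(
      ev("prior_rx", 0, "MED", "RXANTIPSY"), ev("prior_rx", 10, "DIAG", "G30"),
      ev("prior_rx", 400, "DIAG", "DX1"))),
    # excluded: AD only on the final date, nothing after it
    ad_last = timeline_of("ad_last", list(
      ev("ad_last", 0, "DIAG", "DX1"), ev("ad_last", 400, "DIAG", "G30"))),
    # same-day outcome disqualifies the candidate; earlier candidate is a case
    same_day = timeline_of("same_day", list(
      ev("same_day", 0, "DIAG", "G30"), ev("same_day", 400, "DIAG", "DX1"),
      ev("same_day", 450, "DIAG", "DX2"), ev("same_day", 450, "DIAG", "F29")))
  )
}

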