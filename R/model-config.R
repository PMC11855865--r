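# Model configuration shared by all risk-model families.

MODEL_KINDS <- c("LR", "RNN", "TLSTM", "RETAIN")

#' Risk-model configuration
#'
#' Defaults follow the published recipe for this model family: embedding and
#' hidden size 128, dropout 0.2, two recurrent layers, a 30,000-token input
#' cap, and early-stopping patience 3 (epochs without validation-AUROC
#' improvement). Optimizer settings (Adam, learning rate 1e-3, batch 64) are
#' exposed because the source recipe leaves them unstated.
#'
#' @param model_kind One of `"LR"`, `"RNN"`, `"TLSTM"`, `"RETAIN"`.
#' @param embedding_dim,hidden_dim Layer widths (RETAIN's attention networks
#'   are single-layer; `n_layers` applies to RNN/TLSTM stacks).
#' @param dropout Dropout rate in `[0, 1)`, applied to visit embeddings
#'   during training (not used by LR).
#' @param n_layers Recurrent stack depth.
#' @param vocab_cap Maximum vocabulary size the model accepts.
#' @param patience Early-stopping patience in epochs.
#' @param max_epochs,learning_rate,batch_size Optimization settings.
#' @param weight_decay Decoupled L2 penalty applied at each Adam step;
#'   shrinks spurious weights on uninformative codes, which matters for the
#'   downstream contribution analysis (an overfit weight shows up as a false
#'   attribution).
#' @param l1_embedding Group-sparse penalty on per-code parameters, applied
#'   as a proximal step after each update: each code's embedding row (the
#'   code's weight, for LR) is shrunk toward zero and collapses exactly to
#'   zero when its data support is weaker than the penalty. A code with a
#'   zero embedding has occlusion contribution exactly 0 for every patient,
#'   so chance associations drop out of the contribution analysis instead of
#'   surfacing as false attributions. Default 0 (off).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A `model_config` object.
#' @export
model_config <- function(model_kind = "RETAIN",
                         embedding_dim = 128,
                         hidden_dim = 128,
                         dropout = 0.2,
                         n_layers = 2,
                         vocab_cap = 30000,
                         patience = 3,
                         max_epochs = 30,
                         learning_rate = 1e-3,
                         batch_size = 64,
                         weight_decay = 1e-3,
                         l1_embedding = 0,
                         seed = 1L) {
  model_kind <- toupper(model_kind)
  if (!model_kind %in% MODEL_KINDS) {
    abort(sprintf("`model_kind` must be one of %s.", paste(MODEL_KINDS, collapse = ", ")))
  }
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1).")
  structure(list(
    model_kind = model_kind,
    embedding_dim = assert_count(embedding_dim, "embedding_dim", 1L),
    hidden_dim = assert_count(hidden_dim, "hidden_dim", 1L),
    dropout = assert_number(dropout, "dropout"),
    n_layers = assert_count(n_layers, "n_layers", 1L),
    vocab_cap = assert_count(vocab_cap, "vocab_cap", 2L),
    patience = assert_count(patience, "patience", 1L),
    max_epochs = assert_count(max_epochs, "max_epochs", 1L),
    learning_rate = assert_number(learning_rate, "learning_rate"),
    batch_size = assert_count(batch_size, "batch_size", 1L),
    weight_decay = assert_number(weight_decay, "weight_decay"),
    l1_embedding = assert_number(l1_embedding, "l1_embedding"),
    seed = assert_count(seed, "seed")
  ), class = "model_config")
}

#' Time-aware memory decay
#'
#' Discount applied to the long-term memory component of the time-aware
#' LSTM: `g(dt) = 1 / log(e + dt)` with `dt` in days. `g(0) = 1`, strictly
#' decreasing, always positive.
#'
#' @param delta_days Non-negative elapsed days (vectorized).
#' @return Decay factors in `(0, 1]`.
#' @export
#' @examples
#' tlstm_decay(c(0, 30, 365))
tlstm_decay <- function(delta_days) {
  if (any(is.na(delta_days)) || any(delta_days < 0)) {
    abort("`delta_days` must be non-negative.")
  }
  1 / log(exp(1) + delta_days)
}
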