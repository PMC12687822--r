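# Flattened-sequence feedforward neural network.
#
# The classifier is a fully connected ReLU network (hidden sizes 128/64/32)
# on the flattened day-major climate sequence, trained with Adam on the
# numerically stable binary cross-entropy-with-logits objective. Early
# stopping monitors validation AUC: the weights returned are those of the
# best-AUC epoch, not the last one. Everything is base R matrix algebra,
# deterministic given the configured seed.

#' FFNN model configuration
#'
#' @param hidden_sizes Hidden-layer widths (default `c(128, 64, 32)`).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param patience_cv Early-stopping patience (epochs) during
#'   cross-validation (default 10).
#' @param patience_final Patience during final model training (default 100).
#' @param max_epochs Epoch cap (default 1000).
#' @param batch_size Minibatch size (default 256).
#' @param seed Integer seed controlling initialization and shuffling.
#' @param seq_len Sequence length in days the model expects.
#' @param variable_subset Derived-variable names the model uses, in order.
#' @param calibration_fraction Fraction of presences that [train_full()]
#'   carves out (seeded, with an equal number of pseudo-absences) as the
#'   combined early-stopping validation set and FNR calibration reference
#'   population (default 0.4; see [train()] for why the reference must not
#'   be gradient-fit).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment/stability constants
#'   (standard defaults).
#' @return A `model_config` object.
#' @export
model_config <- function(hidden_sizes = c(128L, 64L, 32L),
                         learning_rate = 0.001,
                         patience_cv = 10L, patience_final = 100L,
                         max_epochs = 1000L, batch_size = 256L,
                         seed = 1L, seq_len = 365L,
                         variable_subset = derived_variables(),
                         calibration_fraction = 0.4,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  stopifnot(all(hidden_sizes > 0), patience_cv >= 1, patience_final >= 1,
            max_epochs >= 1, batch_size >= 1, seq_len >= 1,
            length(variable_subset) >= 1,
            calibration_fraction >= 0, calibration_fraction < 1)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate,
                 patience_cv = as.integer(patience_cv),
                 patience_final = as.integer(patience_final),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), seq_len = as.integer(seq_len),
                 variable_subset = variable_subset,
                 calibration_fraction = calibration_fraction,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps),
            class = "model_config")
}

#' Binary cross-entropy with logits
#'
#' The fused, numerically stable form
#' `max(z, 0) - z * y + log(1 + exp(-|z|))`, identical to
#' `-(y log sigma(z) + (1 - y) log(1 - sigma(z)))` but safe for large `|z|`.
#'
#' @param logit Real-valued logit(s).
#' @param label Label(s) in `{0, 1}`.
#' @return Elementwise loss, nonnegative.
#' @examples
#' bce_with_logits(0, 1)   # log(2)
#' bce_with_logits(-3, 0)  # softplus(-3) ~ 0.0486
#' @export
bce_with_logits <- function(logit, label) {
  pmax(logit, 0) - logit * label + log1p(exp(-abs(logit)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# run a function under a temporary RNG state so training does not disturb
# the caller's random stream
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# seeded uniform fan-in ("Kaiming uniform"-style) initialization
init_weights <- function(sizes) {
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    bound <- 1 / sqrt(sizes[l])
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -bound, bound),
                     sizes[l], sizes[l + 1])
    b[[l]] <- stats::runif(sizes[l + 1], -bound, bound)
  }
  list(W = W, b = b)
}

forward_logits <- function(weights, X) {
  A <- X
  L <- length(weights$W)
  for (l in seq_len(L - 1)) {
    A <- A %*% weights$W[[l]]
    A <- sweep(A, 2, weights$b[[l]], "+")
    A[A < 0] <- 0
  }
  drop(sweep(A %*% weights$W[[L]], 2, weights$b[[L]], "+"))
}

# forward pass keeping activations, then backprop of mean BCE loss
backprop <- function(weights, X, y) {
  L <- length(weights$W)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% weights$W[[l]], 2, weights$b[[l]], "+")
    acts[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
  }
  z <- drop(acts[[L + 1]])
  n <- nrow(X)
  delta <- matrix((sigmoid(z) - y) / n, ncol = 1)  # dL/dz for fused BCE
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(acts[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(weights$W[[l]])
      delta[acts[[l]] <= 0] <- 0  # ReLU gate
    }
  }
  list(gW = gW, gb = gb, loss = mean(bce_with_logits(z, y)))
}

adam_init <- function(weights) {
  list(mW = lapply(weights$W, function(w) w * 0),
       vW = lapply(weights$W, function(w) w * 0),
       mb = lapply(weights$b, function(b) b * 0),
       vb = lapply(weights$b, function(b) b * 0), t = 0L)
}

adam_step <- function(weights, grads, state, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  lr_t <- cfg$learning_rate * sqrt(1 - b2^state$t) / (1 - b1^state$t)
  for (l in seq_along(weights$W)) {
    state$mW[[l]] <- b1 * state$mW[[l]] + (1 - b1) * grads$gW[[l]]
    state$vW[[l]] <- b2 * state$vW[[l]] + (1 - b2) * grads$gW[[l]]^2
    weights$W[[l]] <- weights$W[[l]] -
      lr_t * state$mW[[l]] / (sqrt(state$vW[[l]]) + cfg$adam_eps)
    state$mb[[l]] <- b1 * state$mb[[l]] + (1 - b1) * grads$gb[[l]]
    state$vb[[l]] <- b2 * state$vb[[l]] + (1 - b2) * grads$gb[[l]]^2
    weights$b[[l]] <- weights$b[[l]] -
      lr_t * state$mb[[l]] / (sqrt(state$vb[[l]]) + cfg$adam_eps)
  }
  list(weights = weights, state = state)
}

#' Train the FFNN with AUC-based early stopping
#'
#' Fits the z-score scaler on the training features, trains with Adam on
#' minibatches, evaluates validation AUC after every epoch, and returns the
#' weights of the best-AUC epoch once `patience` epochs pass without
#' improvement. By default the FNR calibration reference is the validation
#' presences scored by the returned weights: presences the optimizer has
#' fit score systematically high, which would bias the empirical-CDF
#' transform, whereas validation presences stay exchangeable with
#' genuinely new presences -- the property that makes the FNR a "risk
#' percentile". `calibration_on = "training"` reproduces the naive
#' gradient-presence reference.
#'
#' @param train_set,val_set `labeled_dataset`s (both classes required in
#'   each).
#' @param config A [model_config()].
#' @param patience Patience in epochs; defaults to `config$patience_final`.
#' @param calibration_on `"validation"` (default) or `"training"`:
#'   presence population used for the calibration reference.
#' @return A `trained_model`: list with `weights`, `scaler`, `config`,
#'   `calibration` (see [calibration_reference()]), `log` (per-epoch
#'   data frame of training loss and validation AUC), `best_epoch`.
#' @export
train <- function(train_set, val_set, config = model_config(),
                  patience = config$patience_final,
                  calibration_on = c("validation", "training")) {
  calibration_on <- match.arg(calibration_on)
  for (s in list(train_set, val_set))
    if (length(unique(s$labels)) < 2)
      stop("both classes must be present in the training and validation sets")
  scaler <- fit_scaler(train_set$features)
  Xtr <- apply_scaler(scaler, train_set$features)
  ytr <- as.numeric(train_set$labels)
  Xval <- apply_scaler(scaler, val_set$features)
  yval <- as.numeric(val_set$labels)
  n <- nrow(Xtr)
  sizes <- c(ncol(Xtr), config$hidden_sizes, 1L)

  with_seed(config$seed, {
    weights <- init_weights(sizes)
    state <- adam_init(weights)
    best <- list(auc = -Inf, weights = weights, epoch = 0L)
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_auc = numeric(0))
    stall <- 0L
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        g <- backprop(weights, Xtr[idx, , drop = FALSE], ytr[idx])
        if (!is.finite(g$loss))
          stop("non-finite training loss at epoch ", epoch,
               "; check inputs/learning rate")
        upd <- adam_step(weights, g, state, config)
        weights <- upd$weights; state <- upd$state
        losses <- c(losses, g$loss)
      }
      val_auc <- roc_auc(forward_logits(weights, Xval), yval)
      log <- rbind(log, data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_auc = val_auc))
      if (val_auc > best$auc + 1e-12) {
        best <- list(auc = val_auc, weights = weights, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    ref_features <- if (identical(calibration_on, "validation") &&
                        sum(yval == 1) >= 2)
      Xval[yval == 1, , drop = FALSE] else Xtr[ytr == 1, , drop = FALSE]
    pres_scores <- sigmoid(forward_logits(best$weights, ref_features))
    pres_scores <- pmin(pmax(pres_scores, 1e-12), 1 - 1e-12)
    structure(list(weights = best$weights, scaler = scaler, config = config,
                   calibration = calibration_reference(pres_scores),
                   log = log, best_epoch = best$epoch,
                   best_val_auc = best$auc,
                   feature_layout = list(order = "day_major_oldest_first",
                                         seq_len = config$seq_len,
                                         vars = config$variable_subset)),
              class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> input %d, hidden %s; best epoch %d (val AUC %.3f)\n",
              nrow(x$weights$W[[1]]),
              paste(x$config$hidden_sizes, collapse = "/"),
              x$best_epoch, x$best_val_auc))
  invisible(x)
}

#' Train on a dataset with an internal validation/calibration carve-out
#'
#' Final-model training: a seeded carve of `calibration_fraction` of the
#' presences, paired with an equal number of pseudo-absences, is held out
#' as the early-stopping validation set and doubles as the FNR calibration
#' reference population (see [train()]); everything else feeds gradient
#' descent. Weights from the best validation-AUC epoch are returned (no
#' retraining on the union).
#'
#' @param ds A `labeled_dataset`.
#' @param config A [model_config()]; `config$calibration_fraction` sets
#'   the carve size (a value below 0.05 is raised to 0.1 so early stopping
#'   still has a usable validation set).
#' @export
train_full <- function(ds, config = model_config()) {
  frac <- max(config$calibration_fraction, 0.1)
  idx <- with_seed(config$seed + 1L, {
    pres <- which(ds$labels == 1L); abs <- which(ds$labels == 0L)
    n_vp <- max(1, round(length(pres) * frac))
    c(sample(pres, n_vp), sample(abs, min(length(abs), n_vp)))
  })
  train(subset_dataset(ds, setdiff(seq_along(ds$labels), idx)),
        subset_dataset(ds, idx), config,
        patience = config$patience_final)
}

#' k-fold cross-validation of the FFNN
#'
#' Trains one model per fold (the fold is the validation set, with
#' `patience_cv` early stopping) and reports per-fold validation AUCs.
#'
#' @param ds A `labeled_dataset` (the training split).
#' @param config A [model_config()].
#' @param k Number of folds (default 5).
#' @return List with `fold_auc` (length-k numeric), `mean_auc`, `sd_auc`.
#' @export
cross_validate <- function(ds, config = model_config(), k = 5L) {
  fold <- make_folds(ds$labels, k = k, seed = config$seed)
  aucs <- vapply(seq_len(k), function(f) {
    m <- train(subset_dataset(ds, which(fold != f)),
               subset_dataset(ds, which(fold == f)),
               config, patience = config$patience_cv)
    m$best_val_auc
  }, numeric(1))
  list(fold_auc = aucs, mean_auc = mean(aucs), sd_auc = stats::sd(aucs))
}

#' Predict raw presence scores
#'
#' Applies the frozen scaler and network; scores are `sigmoid(logit)`,
#' strictly inside `(0, 1)`, and batch-order invariant.
#'
#' @param model A `trained_model`.
#' @param features Raw (unscaled) feature matrix or vector.
#' @return Numeric score vector.
#' @export
predict_scores <- function(model, features) {
  X <- apply_scaler(model$scaler, features)
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  if (any(ok)) out[ok] <- sigmoid(forward_logits(model$weights, X[ok, , drop = FALSE]))
  out
}

#' Predict a raw-score map for one date
#'
#' Assembles, for every grid cell, the flattened sequence ending the day
#' before `date`, and applies the model. Cells with missing climate in the
#' window give `NA`.
#'
#' @param model A `trained_model`.
#' @param derived A `derived_cube`.
#' @param date Prediction date.
#' @return `[n_lat, n_lon]` matrix of raw scores in `(0, 1)`.
#' @export
predict_map <- function(model, derived, date) {
  X <- assemble_date_matrix(derived, date, model$config$seq_len,
                            model$config$variable_subset)
  matrix(predict_scores(model, X), derived$grid$n_lat, derived$grid$n_lon)
}

#' Predict raw-score maps for a run of dates
#'
#' @inheritParams predict_map
#' @param dates `Date` vector (contiguous for a valid stack).
#' @return `[n_lat, n_lon, n_dates]` array of raw scores.
#' @export
predict_stack <- function(model, derived, dates) {
  dates <- as.Date(dates)
  out <- array(NA_real_, c(derived$grid$n_lat, derived$grid$n_lon, length(dates)))
  for (i in seq_along(dates)) out[, , i] <- predict_map(model, derived, dates[i])
  out
}

#' Save / load a trained model
#'
#' The checkpoint is a single RDS archive carrying weights, scaler,
#' calibration reference, config, and the training log; reload is
#' bit-exact.
#'
#' @param model A `trained_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "trained_model"))
  m
}
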