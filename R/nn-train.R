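#' Training configuration
#'
#' Bundles the optimizer and schedule settings: Adam with a delayed
#' reduce-on-plateau learning-rate schedule (reductions are suspended for
#' the first `delay_epochs` epochs, then the rate is multiplied by `factor`
#' whenever the validation loss fails to improve for `patience` epochs) and
#' early stopping after `early_stop_patience` epochs without improvement.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param delay_epochs Epochs during which plateau reductions are
#'   suspended.
#' @param patience Plateau length (epochs without validation improvement)
#'   that triggers a reduction.
#' @param factor Multiplicative learning-rate reduction factor in (0, 1).
#' @param early_stop_patience Epochs without validation improvement before
#'   training halts.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch budget.
#' @param val_fraction Fraction of the data held out for validation.
#' @param min_delta Minimum decrease counted as an improvement.
#' @param seed Seed for shuffling and the validation split.
#'
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, delay_epochs = 5,
                         patience = 3, factor = 0.5,
                         early_stop_patience = 8, batch_size = 16,
                         max_epochs = 30, val_fraction = 0.2,
                         min_delta = 0, seed = 42L) {
  stopifnot(delay_epochs >= 0, patience >= 1, factor > 0, factor < 1,
            early_stop_patience >= 1, batch_size >= 1, max_epochs >= 1,
            val_fraction >= 0, val_fraction < 1)
  structure(
    list(learning_rate = learning_rate, delay_epochs = delay_epochs,
         patience = patience, factor = factor,
         early_stop_patience = early_stop_patience,
         batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs),
         val_fraction = val_fraction, min_delta = min_delta,
         seed = as.integer(seed)),
    class = "train_config"
  )
}

# Batch KL loss: mean over rows of KL(target || predicted).
kl_batch_loss <- function(target, probs, eps = 1e-12) {
  p <- pmax(probs, eps)
  pos <- target > 0
  terms <- matrix(0, nrow(target), ncol(target))
  terms[pos] <- target[pos] * log(target[pos] / p[pos])
  mean(rowSums(terms))
}

new_plateau_state <- function(cfg) {
  list(lr = cfg$learning_rate, best = Inf, plateau_wait = 0L,
       stop_wait = 0L, epoch = 0L, reduced = FALSE, stop = FALSE, cfg = cfg)
}

# One schedule step per epoch: plateau counting runs from the start but
# learning-rate reductions are suspended while epoch <= delay_epochs.
plateau_step <- function(state, val_loss) {
  cfg <- state$cfg
  state$epoch <- state$epoch + 1L
  state$reduced <- FALSE
  if (val_loss < state$best - cfg$min_delta) {
    state$best <- val_loss
    state$plateau_wait <- 0L
    state$stop_wait <- 0L
  } else {
    state$plateau_wait <- state$plateau_wait + 1L
    state$stop_wait <- state$stop_wait + 1L
  }
  if (state$epoch > cfg$delay_epochs && state$plateau_wait >= cfg$patience) {
    state$lr <- state$lr * cfg$factor
    state$plateau_wait <- 0L
    state$reduced <- TRUE
  }
  if (state$stop_wait >= cfg$early_stop_patience) state$stop <- TRUE
  state
}

#' Trace the delayed-plateau schedule over a scripted loss curve
#'
#' Applies the schedule used by [train_model()] to a given sequence of
#' validation losses, without any training, so its semantics can be
#' inspected directly: the learning rate applied at each epoch, whether a
#' reduction fired, and when early stopping would halt.
#'
#' @param val_losses Numeric vector of per-epoch validation losses.
#' @param cfg A [train_config()].
#' @return A tibble: `epoch`, `val_loss`, `lr` (rate in force during the
#'   epoch), `reduced`, `stopped`. Rows stop at the early-stop epoch.
#' @export
#' @examples
#' plateau_trace(c(1, .9, .9, .9, .9, .9, .9), train_config(delay_epochs = 2))
plateau_trace <- function(val_losses, cfg = train_config()) {
  st <- new_plateau_state(cfg)
  rows <- vector("list", length(val_losses))
  for (e in seq_along(val_losses)) {
    lr_in_force <- st$lr
    st <- plateau_step(st, val_losses[e])
    rows[[e]] <- tibble::tibble(
      epoch = e, val_loss = val_losses[e], lr = lr_in_force,
      reduced = st$reduced, stopped = st$stop
    )
    if (st$stop) {
      rows <- rows[seq_len(e)]
      break
    }
  }
  dplyr::bind_rows(rows)
}

adam_init <- function(params) {
  zeros <- function(x) array(0, dim(x) %||% length(x))
  list(m = tree_map(zeros, params), v = tree_map(zeros, params), t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, opt$v, grads)
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  params <- tree_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, opt$m, opt$v)
  list(params = params, opt = opt)
}

eval_loss <- function(model, x, aux, soft, batch = 64L) {
  n <- nrow(x)
  total <- 0
  for (lo in seq(1, n, by = batch)) {
    hi <- min(n, lo + batch - 1)
    fw <- model_forward(model, x[lo:hi, , drop = FALSE],
                        aux[lo:hi, , drop = FALSE], training = FALSE)
    total <- total + kl_batch_loss(soft[lo:hi, , drop = FALSE], fw$probs) *
      (hi - lo + 1)
  }
  total / n
}

#' Train the glucose model
#'
#' Minibatch Adam on the Kullback-Leibler divergence between the soft label
#' distribution and the softmax output, with the delayed reduce-on-plateau
#' schedule and early stopping of [train_config()]. The best-validation
#' weights are restored at the end.
#'
#' @param model A `glucose_model` from [build_model()].
#' @param data A list with `x` (n x input_length waveform matrix), `aux`
#'   (n x 6 scaled auxiliary features) and `soft` (n x n_classes soft label
#'   matrix), e.g. from [build_training_data()].
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `glucose_fit`: list with `model` (trained), `log` (per-epoch
#'   tibble: `epoch`, `train_loss`, `val_loss`, `lr`, `reduced`),
#'   `stopped_early`, `best_val_loss`, `train_cfg`.
#' @export
train_model <- function(model, data, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "glucose_model"), inherits(cfg, "train_config"))
  x <- data$x
  aux <- data$aux
  soft <- data$soft
  n <- nrow(x)
  if (is.null(n) || n < 1) stop("empty training dataset")
  stopifnot(nrow(aux) == n, nrow(soft) == n)

  with_seed(cfg$seed, {
    n_val <- floor(cfg$val_fraction * n)
    idx <- sample.int(n)
    val_idx <- if (n_val >= 1) idx[seq_len(n_val)] else integer(0)
    tr_idx <- setdiff(idx, val_idx)

    opt <- adam_init(model$params)
    sched <- new_plateau_state(cfg)
    best_params <- model$params
    best_state <- model$state
    best_val <- Inf
    logs <- vector("list", cfg$max_epochs)
    stopped <- FALSE

    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(tr_idx)
      epoch_loss <- 0
      for (lo in seq(1, length(ord), by = cfg$batch_size)) {
        hi <- min(length(ord), lo + cfg$batch_size - 1)
        rows <- ord[lo:hi]
        fw <- model_forward(model, x[rows, , drop = FALSE],
                            aux[rows, , drop = FALSE], training = TRUE)
        model$state <- fw$state
        target <- soft[rows, , drop = FALSE]
        loss <- kl_batch_loss(target, fw$probs)
        epoch_loss <- epoch_loss + loss * length(rows)
        dlogits <- (fw$probs - target) / length(rows)
        bw <- model_backward(model, fw$cache, dlogits)
        upd <- adam_update(model$params, bw$grads, opt, sched$lr)
        model$params <- upd$params
        opt <- upd$opt
      }
      train_loss <- epoch_loss / length(ord)
      val_loss <- if (length(val_idx) > 0) {
        eval_loss(model, x[val_idx, , drop = FALSE],
                  aux[val_idx, , drop = FALSE],
                  soft[val_idx, , drop = FALSE])
      } else {
        train_loss
      }
      lr_in_force <- sched$lr
      sched <- plateau_step(sched, val_loss)
      logs[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = train_loss, val_loss = val_loss,
        lr = lr_in_force, reduced = sched$reduced
      )
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                        epoch, train_loss, val_loss, lr_in_force))
      }
      if (val_loss < best_val) {
        best_val <- val_loss
        best_params <- model$params
        best_state <- model$state
      }
      if (sched$stop) {
        stopped <- TRUE
        logs <- logs[seq_len(epoch)]
        break
      }
    }

    model$params <- best_params
    model$state <- best_state
    structure(
      list(model = model, log = dplyr::bind_rows(logs),
           stopped_early = stopped, best_val_loss = best_val,
           train_cfg = cfg),
      class = "glucose_fit"
    )
  })
}

#' Assemble training arrays from a labeled segment table
#'
#' Converts a pipeline table (preprocessed `segment` list-column,
#' `glucose_mgdl`, and the six auxiliary-feature columns from
#' [aux_features()]) into the `x` / `aux` / `soft` arrays consumed by
#' [train_model()].
#'
#' @param labeled Tibble with `segment`, `glucose_mgdl` and auxiliary
#'   feature columns.
#' @param radius Soft-label radius (default 2).
#' @param n_classes Number of glucose classes.
#' @return A list `x`, `aux`, `soft`, `class`, `glucose`.
#' @export
build_training_data <- function(labeled, radius = 2,
                                n_classes = N_GLUCOSE_CLASSES) {
  stopifnot(nrow(labeled) >= 1)
  x <- do.call(rbind, purrr::map(labeled$segment, "samples"))
  cls <- suppressWarnings(discretize_glucose(labeled$glucose_mgdl))
  soft <- do.call(rbind, purrr::map(cls, soft_label, radius = radius,
                                    n_classes = n_classes))
  list(x = x, aux = scale_aux(labeled), soft = soft, class = cls,
       glucose = labeled$glucose_mgdl)
}

#' @export
print.glucose_fit <- function(x, ...) {
  cat(sprintf(
    "<glucose_fit> %d epochs, best val KL %.4f%s\n",
    nrow(x$log), x$best_val_loss,
    if (x$stopped_early) " (early stop)" else ""
  ))
  invisible(x)
}

#' Tidy the per-epoch training log
#'
#' @param x A `glucose_fit`.
#' @param ... Unused.
#' @return Tibble with one row per epoch: `epoch`, `train_loss`,
#'   `val_loss`, `lr`, `reduced`.
#' @export
tidy.glucose_fit <- function(x, ...) {
  x$log
}

#' One-row summary of a model fit
#'
#' @param x A `glucose_fit`.
#' @param ... Unused.
#' @return Tibble: `epochs`, `best_val_loss`, `final_train_loss`,
#'   `final_lr`, `stopped_early`, `n_parameters`.
#' @export
glance.glucose_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$log),
    best_val_loss = x$best_val_loss,
    final_train_loss = x$log$train_loss[nrow(x$log)],
    final_lr = x$log$lr[nrow(x$log)],
    stopped_early = x$stopped_early,
    n_parameters = n_parameters(x$model)
  )
}
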