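#' Architecture and training specification of the sequence CNN
#'
#' The network maps a one-hot encoded 150-bp sequence to a scalar
#' binding change: four 1-D convolutional layers (filters 128, 128, 128,
#' 64; kernel sizes 5, 3, 5, 3), each followed by ReLU and max-pooling
#' of size 2, then two fully connected ReLU layers of 128 and 64 units
#' with dropout 0.4 after each, and a single linear output unit.
#' Training minimizes mean squared error with Adam (learning rate 0.001,
#' batch size 64) and early stopping on validation loss (20 percent of
#' the training set) with patience 15.  Convolutions are same-padded, so
#' the length trace through the pools is 150 - 75 - 37 - 18 - 9, giving
#' a flattened feature size of 9 x 64 = 576.
#'
#' @param input_length sequence length in bp (default 150).
#' @param conv_filters,conv_kernels per-layer filter counts and kernel
#'   sizes.
#' @param dense_units fully connected layer widths.
#' @param dropout dropout rate after each dense layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience in epochs.
#' @param val_fraction fraction of the training set held out for
#'   validation.
#' @param max_epochs epoch cap.
#' @return A `cnn_spec` list.
#' @export
cnn_spec <- function(input_length = 150L,
                     conv_filters = c(128L, 128L, 128L, 64L),
                     conv_kernels = c(5L, 3L, 5L, 3L),
                     dense_units = c(128L, 64L), dropout = 0.4,
                     learning_rate = 0.001, batch_size = 64L,
                     patience = 15L, val_fraction = 0.2,
                     max_epochs = 100L) {
  stopifnot(length(conv_filters) == length(conv_kernels))
  len <- input_length
  for (i in seq_along(conv_filters)) len <- len %/% 2L
  structure(list(input_length = as.integer(input_length),
                 conv_filters = as.integer(conv_filters),
                 conv_kernels = as.integer(conv_kernels),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 val_fraction = val_fraction,
                 max_epochs = as.integer(max_epochs),
                 flat_size = len * conv_filters[length(conv_filters)]),
            class = "cnn_spec")
}

#' One-hot encode a DNA sequence
#'
#' @param sequence a string over `ACGTN` of the model's input length.
#' @param input_length expected length (default 150).
#' @return 4 x length numeric matrix (rows A, C, G, T); `N` columns are
#'   all zero.
#' @export
one_hot <- function(sequence, input_length = 150L) {
  if (nchar(sequence) != input_length)
    stop_("sequence length %d != expected %d", nchar(sequence),
          input_length)
  iv <- seq_to_int(sequence)
  m <- matrix(0, 4L, input_length, dimnames = list(DNA_BASES, NULL))
  ok <- !is.na(iv)
  m[cbind(iv[ok], which(ok))] <- 1
  m
}

#' Decode a one-hot matrix back to sequence
#' @param m 4 x length one-hot matrix; all-zero columns decode to `N`.
#' @return Character sequence.
#' @export
one_hot_decode <- function(m) {
  idx <- apply(m, 2L, function(col)
    if (all(col == 0)) NA_integer_ else which.max(col))
  paste(ifelse(is.na(idx), "N", DNA_BASES[idx]), collapse = "")
}

# stack sequences into the (length, 4, batch) array the kernels expect
one_hot_batch <- function(sequences, input_length) {
  n <- length(sequences)
  arr <- array(0, c(input_length, 4L, n))
  for (i in seq_len(n)) arr[, , i] <- t(one_hot(sequences[i], input_length))
  arr
}

# ---- parameter initialization (He for ReLU layers) ----
init_params <- function(spec) {
  ps <- list()
  cin <- 4L
  for (l in seq_along(spec$conv_filters)) {
    k <- spec$conv_kernels[l]; cout <- spec$conv_filters[l]
    fan_in <- k * cin
    ps[[paste0("convW", l)]] <- matrix(rnorm(fan_in * cout, 0,
                                             sqrt(2 / fan_in)), fan_in)
    ps[[paste0("convb", l)]] <- numeric(cout)
    cin <- cout
  }
  sizes <- c(spec$flat_size, spec$dense_units, 1L)
  for (l in seq_len(length(sizes) - 1L)) {
    fan_in <- sizes[l]
    ps[[paste0("denseW", l)]] <- matrix(rnorm(fan_in * sizes[l + 1L], 0,
                                              sqrt(2 / fan_in)), fan_in)
    ps[[paste0("denseb", l)]] <- numeric(sizes[l + 1L])
  }
  ps
}

# One fused compiled call runs the forward (and optionally backward)
# pass for a minibatch; activations stay on the compiled side in single
# precision.  drop_masks: list of dense dropout masks or NULL.
cnn_batch <- function(params, X, spec, masks = NULL, y = NULL,
                      dout = NULL, want_grads = FALSE,
                      input_grad = FALSE) {
  cnn_fused(params, X, spec$conv_kernels, masks, y, dout, want_grads,
            input_grad)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t; corr2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] - lr * (state$m[[nm]] / corr1) /
      (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

#' Train the sequence CNN on site sequences and binding-change labels
#'
#' Sites on the holdout chromosomes form the test set; of the remaining
#' sites, a validation fraction is split off (seeded) and the rest is
#' trained on per the specification, with early stopping on validation
#' loss and restoration of the best weights.
#'
#' @param sites data.frame with columns `chrom`, `sequence` (oriented,
#'   `input_length` bp) and `delta` (finite labels).
#' @param spec a [cnn_spec()].
#' @param holdout_chroms chromosomes excluded from training and kept as
#'   the test set.
#' @param seed integer seed governing the split, initialization,
#'   shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return A `ctcf_cnn` object: `params`, `spec`, `report` (per-epoch
#'   train/val loss, stopped epoch, test Pearson r, split sizes), and
#'   the test-set predictions.
#' @export
train_cnn <- function(sites, spec = cnn_spec(),
                      holdout_chroms = c("chr16", "chr17", "chr18", "chr19"),
                      seed = 1L, verbose = FALSE) {
  stopifnot(all(c("chrom", "sequence", "delta") %in% names(sites)))
  if (!all(is.finite(sites$delta))) stop_("labels must be finite")
  test_idx <- which(sites$chrom %in% holdout_chroms)
  if (!length(test_idx)) stop_("holdout set is empty")
  trainval <- setdiff(seq_len(nrow(sites)), test_idx)
  label_var <- stats::var(sites$delta[trainval])
  with_seed(seed, {
    nval <- max(1L, round(spec$val_fraction * length(trainval)))
    val_idx <- sample(trainval, nval)
    tr_idx <- setdiff(trainval, val_idx)
    Xtr <- one_hot_batch(sites$sequence[tr_idx], spec$input_length)
    ytr <- sites$delta[tr_idx]
    Xval <- one_hot_batch(sites$sequence[val_idx], spec$input_length)
    yval <- sites$delta[val_idx]
    params <- init_params(spec)
    st <- adam_init(params)
    keep <- 1 - spec$dropout
    ntr <- length(ytr)
    best <- list(loss = Inf, params = params, epoch = 0L)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    for (ep in seq_len(spec$max_epochs)) {
      ord <- sample.int(ntr)
      ep_loss <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / spec$batch_size))) {
        Xb <- Xtr[, , bs, drop = FALSE]
        yb <- ytr[bs]
        masks <- lapply(spec$dense_units, function(u)
          matrix(rbinom(length(bs) * u, 1L, keep) / keep, length(bs)))
        fw <- cnn_batch(params, Xb, spec, masks = masks, y = yb,
                        want_grads = TRUE)
        ep_loss <- ep_loss + fw$loss * length(bs)
        upd <- adam_step(params, fw$grads, st, spec$learning_rate)
        params <- upd$params; st <- upd$state
      }
      vl <- cnn_loss(params, Xval, yval, spec)
      hist <- rbind(hist, data.frame(epoch = ep,
                                     train_loss = ep_loss / ntr,
                                     val_loss = vl))
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep,
                        ep_loss / ntr, vl))
      if (vl < best$loss) best <- list(loss = vl, params = params,
                                       epoch = ep)
      if (ep - best$epoch >= spec$patience) break
    }
    params <- best$params
    Xte <- one_hot_batch(sites$sequence[test_idx], spec$input_length)
    yte <- sites$delta[test_idx]
    pred <- cnn_predict_arr(params, Xte, spec)
    r <- if (stats::sd(pred) > 0 && stats::sd(yte) > 0)
      stats::cor(pred, yte) else NA_real_
    structure(list(
      params = params, spec = spec,
      report = list(history = hist, stopped_epoch = best$epoch,
                    test_r = r, n_train = length(tr_idx),
                    n_val = nval, n_test = length(test_idx),
                    zero_label_variance = label_var == 0,
                    holdout_chroms = holdout_chroms, seed = seed),
      test = data.frame(observed = yte, predicted = pred,
                        chrom = sites$chrom[test_idx])),
      class = "ctcf_cnn")
  })
}

cnn_loss <- function(params, X, y, spec, chunk = 256L) {
  mean((cnn_predict_arr(params, X, spec, chunk) - y)^2)
}

cnn_predict_arr <- function(params, X, spec, chunk = 256L) {
  n <- dim(X)[3]
  out <- numeric(n)
  for (bs in split(seq_len(n), ceiling(seq_len(n) / chunk)))
    out[bs] <- cnn_batch(params, X[, , bs, drop = FALSE], spec)$pred
  out
}

#' @export
print.ctcf_cnn <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "ctcf_cnn: trained %d epochs (best %d), test r = %.3f (n=%d/%d/%d train/val/test)\n",
    nrow(r$history), r$stopped_epoch, r$test_r, r$n_train, r$n_val,
    r$n_test))
  if (isTRUE(r$zero_label_variance))
    cat("  note: training labels had zero variance\n")
  invisible(x)
}

#' Predict binding change for sequences
#' @param object a trained `ctcf_cnn`.
#' @param sequences character vector of oriented input-length sequences.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.ctcf_cnn <- function(object, sequences, ...) {
  X <- one_hot_batch(sequences, object$spec$input_length)
  cnn_predict_arr(object$params, X, object$spec)
}

# gradient of the scalar output w.r.t. the one-hot input, per sample
cnn_input_gradient <- function(model, X, chunk = 256L) {
  n <- dim(X)[3]
  out <- array(0, dim(X))
  for (bs in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    fw <- cnn_batch(model$params, X[, , bs, drop = FALSE], model$spec,
                    dout = rep(1, length(bs)), want_grads = TRUE,
                    input_grad = TRUE)
    out[, , bs] <- fw$dX
  }
  out
}

# audit helper: parameter tensor dimensions implied by a spec
cnn_param_shapes <- function(spec) {
  shp <- list()
  cin <- 4L
  for (l in seq_along(spec$conv_filters)) {
    shp[[paste0("convW", l)]] <- c(spec$conv_kernels[l] * cin,
                                   spec$conv_filters[l])
    shp[[paste0("convb", l)]] <- spec$conv_filters[l]
    cin <- spec$conv_filters[l]
  }
  sizes <- c(spec$flat_size, spec$dense_units, 1L)
  for (l in seq_len(length(sizes) - 1L)) {
    shp[[paste0("denseW", l)]] <- c(sizes[l], sizes[l + 1L])
    shp[[paste0("denseb", l)]] <- sizes[l + 1L]
  }
  shp
}
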