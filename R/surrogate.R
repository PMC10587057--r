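# Twin 3D-CNN property surrogates over binary voxel grids, with
# gradient-weighted regression activation maps for interpretation.

#' Surrogate model specification
#'
#' A 3D convolutional regressor: three conv stages (3x3x3 kernels, 'same'
#' padding, ELU, max-pool 2) with the given filter counts, flattened into a
#' dense ELU stack and a single linear output. Labels are standardised
#' internally during training. Loss is mean squared error (Adam).
#'
#' @param filters Conv filter counts per stage.
#' @param dense Dense layer widths.
#' @param target Which property the model predicts: "E" or "Y" (metadata).
#' @param epochs,batch,lr Training schedule.
#' @param lr_decay Multiplicative learning-rate decay per epoch.
#' @param seed Integer seed for weight init and shuffling.
#' @param val_frac Held-out fraction used for early stopping.
#' @param patience Early-stopping patience in epochs.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(filters = c(8, 4, 2), dense = c(128, 64, 32),
                           target = c("E", "Y"), epochs = 12, batch = 8,
                           lr = 1e-3, lr_decay = 0.93, seed = 42,
                           val_frac = 0.1, patience = 20) {
  target <- match.arg(target)
  stopifnot(length(filters) >= 1, all(filters >= 1), all(dense >= 1),
            epochs >= 1, batch >= 1, lr > 0, val_frac >= 0, val_frac < 1)
  structure(list(filters = as.integer(filters), dense = as.integer(dense),
                 target = target, epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr, lr_decay = lr_decay,
                 seed = as.integer(seed),
                 val_frac = val_frac, patience = as.integer(patience)),
            class = "surrogate_spec")
}

# accepts a V x n matrix, a list of voxel grids, or one grid
.as_grid_matrix <- function(grids) {
  if (is.array(grids) && length(dim(grids)) == 3)
    grids <- list(grids)
  if (is.list(grids)) {
    v <- length(grids[[1]])
    grids <- vapply(grids, function(g) as.numeric(g), numeric(v))
  }
  if (!is.matrix(grids)) stop("grids must be a matrix or list of voxel grids")
  if (!all(grids %in% c(0, 1))) stop("surrogate inputs must be binary voxel grids")
  grids
}

#' Train a property surrogate on labeled voxel grids
#'
#' @param grids Binary voxel grids: a V x n matrix (one flattened grid per
#'   column) or a list of `voxel_grid` arrays, all with the same cubic edge.
#' @param y Numeric labels (one per grid), e.g. E or Y in MPa.
#' @param spec A [surrogate_spec()].
#' @return An object of class `surrogate_model` (weights, label scaling,
#'   grid edge, training history).
#' @export
train_surrogate <- function(grids, y, spec = surrogate_spec()) {
  X <- .as_grid_matrix(grids)
  n <- ncol(X)
  if (n < 50) stop("surrogate training needs at least 50 labeled grids")
  if (length(y) != n) stop("label length does not match number of grids")
  if (any(!is.finite(y))) stop("labels must be finite")
  D <- round(nrow(X)^(1 / 3))
  if (D^3 != nrow(X)) stop("grids must be cubic")
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (y_sd == 0) {
    # constant labels: the least-squares fit is exactly the constant
    return(structure(list(weights = NULL, spec = spec, D = D,
                          y_mean = y_mean, y_sd = 1,
                          train_mse = 0, val_mse = 0, best_epoch = 0L,
                          constant = TRUE),
                     class = "surrogate_model"))
  }
  ys <- (y - y_mean) / y_sd
  set.seed(spec$seed)
  n_val <- floor(spec$val_frac * n)
  if (n_val > 0) {
    val_idx <- sample.int(n, n_val)
    Xtr <- X[, -val_idx, drop = FALSE]
    ytr <- ys[-val_idx]
    Xva <- X[, val_idx, drop = FALSE]
    yva <- ys[val_idx]
  } else {
    # no held-out split: training loss drives best-weight selection
    Xtr <- X
    ytr <- ys
    Xva <- X[, integer(0), drop = FALSE]
    yva <- numeric(0)
  }
  fit <- cpp_cnn_train(Xtr, ytr, Xva, yva,
                       D, spec$filters, spec$dense, spec$epochs, spec$batch,
                       spec$lr, spec$seed, spec$patience, spec$lr_decay)
  structure(list(weights = fit$weights, spec = spec, D = D,
                 y_mean = y_mean, y_sd = y_sd,
                 train_mse = fit$train_mse, val_mse = fit$val_mse,
                 best_epoch = fit$best_epoch),
            class = "surrogate_model")
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("3D-CNN %s surrogate: %d^3 input, filters %s, dense %s (best epoch %d)\n",
              x$spec$target, x$D, paste(x$spec$filters, collapse = "/"),
              paste(x$spec$dense, collapse = "/"), x$best_epoch))
  invisible(x)
}

#' Predict properties for voxel grids
#'
#' @param object A trained [train_surrogate()] model.
#' @param grids Voxel grids (matrix, list, or single array).
#' @param ... Unused.
#' @return Numeric vector of predictions on the label scale.
#' @export
predict.surrogate_model <- function(object, grids, ...) {
  X <- .as_grid_matrix(grids)
  if (nrow(X) != object$D^3)
    stop(sprintf("grid edge mismatch: model expects %d^3 voxels", object$D))
  if (isTRUE(object$constant)) return(rep(object$y_mean, ncol(X)))
  raw <- cpp_cnn_predict(object$weights, X, object$D, object$spec$filters,
                         object$spec$dense)
  raw * object$y_sd + object$y_mean
}

#' Regression metrics: mean absolute error and coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` about the test-label mean.
#'
#' @param y Observed labels.
#' @param y_hat Predictions.
#' @return List with `mae`, `r2` and `n_test`; `r2` is `NA` (flagged with a
#'   warning) when the test labels have zero variance.
#' @export
regression_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 1)
  mae <- mean(abs(y_hat - y))
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("test labels have zero variance: R^2 is undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sum((y - y_hat)^2) / ss_tot
  }
  list(mae = mae, r2 = r2, n_test = length(y))
}

#' Evaluate a surrogate on a labeled test set
#'
#' @param model A trained [train_surrogate()] model.
#' @param grids Test voxel grids.
#' @param y Test labels.
#' @return [regression_metrics()] of the predictions.
#' @export
evaluate_surrogate <- function(model, grids, y) {
  regression_metrics(y, predict(model, grids))
}

#' Regression activation map of a surrogate prediction
#'
#' Gradient-weighted activation mapping on the last convolution stage: the
#' map is the rectified per-voxel sum over channels of gradient times
#' activation (the first-order estimate of each location's contribution to
#' the prediction), trilinearly upsampled to the input grid and min-max
#' normalised to \[0, 1\]. The weighting is per voxel rather than the
#' per-channel spatial average of classification activation maps because
#' the exponential-linear activations take both signs, and a global channel
#' weight misattributes locally negative evidence. Highlights the spatial
#' regions driving the prediction.
#'
#' @param model A trained [train_surrogate()] model.
#' @param grid One voxel grid (array or flattened vector).
#' @return An object of class `ram_volume`: a D^3 array in \[0, 1\] with
#'   attribute `prediction`.
#' @export
compute_ram <- function(model, grid) {
  stopifnot(inherits(model, "surrogate_model"))
  if (isTRUE(model$constant))
    stop("activation map undefined for a constant-label model")
  x <- matrix(as.numeric(grid), ncol = 1)
  if (nrow(x) != model$D^3) stop("grid size mismatch")
  res <- cpp_cnn_ram(model$weights, x, model$D, model$spec$filters,
                     model$spec$dense)
  A <- res$activations
  dA <- res$gradients
  dlast <- res$resolution
  map <- array(pmax(rowSums(dA * A), 0), c(dlast, dlast, dlast))
  up <- .interp_blocks(map, model$D, model$D / dlast)
  rng <- range(up)
  if (rng[2] > rng[1]) up <- (up - rng[1]) / (rng[2] - rng[1]) else up[] <- 0
  structure(up, class = "ram_volume",
            prediction = res$prediction * model$y_sd + model$y_mean)
}

#' @export
print.ram_volume <- function(x, ...) {
  cat(sprintf("regression activation map %s (prediction %.4g)\n",
              paste(dim(x), collapse = " x "), attr(x, "prediction")))
  invisible(x)
}
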