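# Latent design space: 3D convolutional autoencoder over expanded porosity
# arrays plus a Gaussian mixture model of the embeddings for sampling.

#' Autoencoder training specification
#'
#' Three convolutional stages (3x3x3 kernels, ELU, max-pool 2) with the
#' given filter counts map 12^3 inputs to 6^3 then 3^3 feature maps; a final
#' convolution and global average pooling produce the latent code. The
#' decoder mirrors the spatial path (broadcast, convolve, upsample) with a
#' linear single-channel reconstruction. Loss is the mean squared
#' reconstruction error in porosity units squared.
#'
#' @param latent_dim Latent dimensionality (default 8).
#' @param filters Encoder filter counts per stage.
#' @param epochs,batch,lr Training schedule (Adam).
#' @param lr_decay Multiplicative learning-rate decay per epoch.
#' @param seed Integer seed for weight init and shuffling.
#' @param val_frac Held-out fraction for the validation split.
#' @param mse_threshold Acceptable held-out reconstruction MSE.
#' @param patience Early-stopping patience in epochs.
#' @return An object of class `cae_spec`.
#' @export
cae_spec <- function(latent_dim = 8, filters = c(60, 30, 15), epochs = 60,
                     batch = 8, lr = 1e-3, lr_decay = 0.97, seed = 42,
                     val_frac = 0.1, mse_threshold = 0.004, patience = 20) {
  stopifnot(latent_dim >= 1, length(filters) == 3, all(filters >= 1),
            epochs >= 1, batch >= 1, lr > 0, val_frac >= 0, val_frac < 1)
  structure(list(latent_dim = as.integer(latent_dim),
                 filters = as.integer(filters), epochs = as.integer(epochs),
                 batch = as.integer(batch), lr = lr, lr_decay = lr_decay,
                 seed = as.integer(seed),
                 val_frac = val_frac, mse_threshold = mse_threshold,
                 patience = as.integer(patience)),
            class = "cae_spec")
}

# accepts a 1728 x n matrix, a list of 12^3 arrays, or a corpus list
.as_corpus_matrix <- function(corpus) {
  if (is.list(corpus) && !is.null(corpus$arrays)) corpus <- corpus$arrays
  if (is.list(corpus)) corpus <- vapply(corpus, as.vector, numeric(1728))
  if (!is.matrix(corpus) || nrow(corpus) != 1728)
    stop("corpus must be 12^3 arrays (1728 rows per column)")
  corpus
}

#' Train the 3D convolutional autoencoder
#'
#' @param corpus Corpus of expanded 12^3 porosity arrays: the result of
#'   [generate_corpus()], a 1728 x n matrix, or a list of arrays.
#' @param spec A [cae_spec()].
#' @return An object of class `cae_model` with weights, the training
#'   history, and the held-out reconstruction MSE.
#' @export
train_cae <- function(corpus, spec = cae_spec()) {
  X <- .as_corpus_matrix(corpus)
  n <- ncol(X)
  if (n < 100) stop("autoencoder training needs at least 100 corpus arrays")
  set.seed(spec$seed)
  n_val <- floor(spec$val_frac * n)
  if (n_val > 0) {
    val_idx <- sample.int(n, n_val)
    Xval <- X[, val_idx, drop = FALSE]
    Xtr <- X[, -val_idx, drop = FALSE]
  } else {
    Xval <- X[, integer(0), drop = FALSE]
    Xtr <- X
  }
  fit <- cpp_cae_train(Xtr, Xval, spec$latent_dim, spec$filters, spec$epochs,
                       spec$batch, spec$lr, spec$seed, spec$patience,
                       spec$lr_decay)
  model <- structure(list(weights = fit$weights, spec = spec,
                          train_mse = fit$train_mse, val_mse = fit$val_mse,
                          best_epoch = fit$best_epoch,
                          held_out_mse = fit$best_val_mse),
                     class = "cae_model")
  if (model$held_out_mse > spec$mse_threshold)
    warning(sprintf("held-out reconstruction MSE %.4g exceeds threshold %.4g",
                    model$held_out_mse, spec$mse_threshold))
  model
}

#' @export
print.cae_model <- function(x, ...) {
  cat(sprintf("3D convolutional autoencoder: latent %d, filters %s, held-out MSE %.4g (best epoch %d)\n",
              x$spec$latent_dim, paste(x$spec$filters, collapse = "/"),
              x$held_out_mse, x$best_epoch))
  invisible(x)
}

#' Encode porosity arrays into latent codes
#'
#' @param model A trained [train_cae()] model.
#' @param x A 12^3 array, 1728-vector, 1728 x n matrix, or list of arrays.
#' @return Matrix of latent codes, one row per input (n x latent_dim).
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "cae_model"))
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.array(x) && length(dim(x)) == 3) x <- matrix(as.vector(x), ncol = 1)
  X <- .as_corpus_matrix(x)
  t(cpp_cae_encode(model$weights, X, model$spec$latent_dim, model$spec$filters))
}

#' Decode latent codes into 12^3 reconstruction arrays
#'
#' @param model A trained [train_cae()] model.
#' @param z A latent vector or n x latent_dim matrix.
#' @return A list of 12^3 arrays.
#' @export
decode <- function(model, z) {
  stopifnot(inherits(model, "cae_model"))
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$spec$latent_dim)
    stop(sprintf("latent dimension mismatch: expected %d, got %d",
                 model$spec$latent_dim, ncol(z)))
  X <- cpp_cae_decode(model$weights, t(z), model$spec$latent_dim,
                      model$spec$filters)
  lapply(seq_len(ncol(X)), function(i) array(X[, i], c(12, 12, 12)))
}

#' Decode a latent point to a valid subunit-level porosity matrix
#'
#' The 12^3 decoder output is contracted to the target shape by block means
#' (the inverse of [expand_matrix()] on block-constant arrays), clipped to
#' the admissible porosity range, and optionally snapped to the discrete
#' ladder.
#'
#' @param z A latent vector (or n x latent_dim matrix).
#' @param model A trained [train_cae()] model.
#' @param snap Snap entries to the nearest ladder value.
#' @param shape Target matrix edge (default 3).
#' @param ladder Ladder used for snapping.
#' @return A [porosity_matrix()] (or list of them for matrix input).
#' @export
decode_to_matrix <- function(z, model, snap = TRUE, shape = 3,
                             ladder = porosity_ladder()) {
  single <- is.null(dim(z))
  if (single) z <- matrix(z, nrow = 1)
  if (ncol(z) != model$spec$latent_dim)
    stop(sprintf("latent dimension mismatch: expected %d, got %d",
                 model$spec$latent_dim, ncol(z)))
  X <- cpp_cae_decode(model$weights, t(z), model$spec$latent_dim,
                      model$spec$filters)
  # batched contraction by block means: group the 12^3 voxel rows by subunit
  f <- 12L %/% as.integer(shape)
  idx <- rep(seq_len(shape), each = f)
  grp <- rep(idx, times = 144) +
    shape * (rep(rep(idx, each = 12L), times = 12L) - 1L) +
    shape^2 * (rep(idx, each = 144L) - 1L)
  M <- rowsum(X, grp) / f^3
  M <- pmin(pmax(M, min(ladder)), max(ladder))
  if (snap) {
    nearest <- max.col(-abs(outer(as.vector(M), ladder, "-")),
                       ties.method = "first")
    M <- matrix(ladder[nearest], nrow(M), ncol(M))
  }
  out <- lapply(seq_len(ncol(M)), function(i)
    porosity_matrix(array(M[, i], rep(shape, 3)), discrete = snap))
  if (single) out[[1]] else out
}

#' Fit a Gaussian mixture model to latent embeddings
#'
#' The number of components is chosen to minimise the held-out average
#' negative log-likelihood over `K_range`; the selected K is refitted on all
#' embeddings. Fitting uses full-covariance EM (package mclust).
#'
#' @param embeddings n x latent_dim matrix of latent codes.
#' @param K_range Candidate component counts (default 1:10).
#' @param seed Seed for the split and EM initialisation.
#' @param val_frac Held-out fraction used for model selection.
#' @return An object of class `latent_gmm` with weights, means (d x K),
#'   covariances (d x d x K) and the per-K score table.
#' @export
fit_latent_gmm <- function(embeddings, K_range = 1:10, seed = 1,
                           val_frac = 0.2) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  K_range <- K_range[K_range * 10 <= n]
  if (length(K_range) == 0) stop("too few embeddings for the requested K range")
  if (any(apply(embeddings, 2, stats::var) == 0))
    stop("degenerate embeddings: a latent dimension has zero variance")
  set.seed(seed)
  n_val <- max(2L, floor(val_frac * n))
  val_idx <- sample.int(n, n_val)
  tr <- embeddings[-val_idx, , drop = FALSE]
  va <- embeddings[val_idx, , drop = FALSE]
  score <- rep(NA_real_, length(K_range))
  fits <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    fit <- .fit_gmm_K(tr, K_range[i])
    if (is.null(fit)) next
    ld <- .gmm_logdens(fit, va)
    if (any(!is.finite(ld))) next
    fits[[i]] <- fit
    score[i] <- -mean(ld)
  }
  if (all(is.na(score))) stop("no Gaussian mixture could be fitted")
  best <- which.min(score)
  K <- K_range[best]
  full <- .fit_gmm_K(embeddings, K)
  if (is.null(full)) full <- fits[[best]]
  structure(c(full,
              list(score_table = data.frame(K = K_range, avg_nll = score))),
            class = "latent_gmm")
}

# fit a K-component full-covariance mixture; K = 1 in closed form, K >= 2
# via EM (mclust, "VVV"); returns NULL when the fit degenerates
.fit_gmm_K <- function(X, K) {
  d <- ncol(X)
  if (K == 1) {
    S <- stats::cov(X)
    if (any(!is.finite(S)) || det(S) <= 0) return(NULL)
    return(list(K = 1L, weights = 1,
                means = matrix(colMeans(X), ncol = 1),
                covariances = array(S, c(d, d, 1))))
  }
  # unqualified call: Mclust resolves helpers (mclustBIC, hc*) through this
  # package's imports
  fit <- tryCatch(Mclust(X, G = K, modelNames = "VVV", verbose = FALSE),
                  error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters)) return(NULL)
  par <- fit$parameters
  sigma <- par$variance$sigma
  if (is.null(dim(sigma)) || length(dim(sigma)) != 3)
    sigma <- array(sigma, c(d, d, K))
  out <- list(K = as.integer(K), weights = as.vector(par$pro),
              means = matrix(par$mean, nrow = d), covariances = sigma)
  ok <- tryCatch({
    for (k in seq_len(K)) chol(out$covariances[, , k])
    TRUE
  }, error = function(e) FALSE)
  if (!ok) return(NULL)
  out
}

# log mixture density of rows of X under a fitted latent mixture
.gmm_logdens <- function(gmm, X) {
  X <- as.matrix(X)
  d <- ncol(X)
  comp <- matrix(0, nrow(X), gmm$K)
  for (k in seq_len(gmm$K)) {
    L <- chol(gmm$covariances[, , k])
    ctr <- sweep(X, 2, gmm$means[, k])
    q <- colSums(backsolve(L, t(ctr), transpose = TRUE)^2)
    comp[, k] <- log(gmm$weights[k]) - 0.5 * q -
      sum(log(diag(L))) - 0.5 * d * log(2 * pi)
  }
  mx <- apply(comp, 1, max)
  mx + log(rowSums(exp(comp - mx)))
}

#' @export
print.latent_gmm <- function(x, ...) {
  cat(sprintf("latent Gaussian mixture: K = %d components in %d dimensions\n",
              x$K, nrow(x$means)))
  invisible(x)
}

#' Sample latent points from a fitted mixture
#'
#' @param gmm A [fit_latent_gmm()] model.
#' @param n Number of points.
#' @param seed Integer seed.
#' @return An n x latent_dim matrix of latent points.
#' @export
sample_latent <- function(gmm, n, seed = 1) {
  stopifnot(inherits(gmm, "latent_gmm"), n >= 1)
  set.seed(seed)
  d <- nrow(gmm$means)
  comp <- sample.int(gmm$K, n, replace = TRUE, prob = gmm$weights)
  out <- matrix(0, n, d)
  for (k in seq_len(gmm$K)) {
    idx <- which(comp == k)
    if (length(idx) == 0) next
    L <- chol(gmm$covariances[, , k])
    eps <- matrix(stats::rnorm(length(idx) * d), length(idx), d)
    out[idx, ] <- eps %*% L + matrix(gmm$means[, k], length(idx), d,
                                     byrow = TRUE)
  }
  out
}

#' Mixture mean of a latent GMM
#'
#' @param gmm A [fit_latent_gmm()] model.
#' @return The weighted mean vector of the mixture.
#' @export
gmm_mean <- function(gmm) {
  as.vector(gmm$means %*% gmm$weights)
}
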