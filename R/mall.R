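# Multi-objective active-learning loop: sample the latent space, decode to
# designs, screen with the surrogates, select under the modulus band and
# mass cap with an epsilon-greedy rule, query the oracle, retrain, repeat.
# Includes random-search and Bayesian-optimisation baselines.

#' Selection constraints for the active-learning loop
#'
#' @param E_target Target elastic modulus in MPa.
#' @param E_band Relative half-width of the admissible modulus band
#'   (default 0.05, i.e. target +- 5%).
#' @param mass_criterion Reference mass fraction (typically the uniform
#'   design's); candidates more than `mass_slack` above it are rejected.
#' @param mass_slack Relative mass allowance (default 0.15).
#' @param epsilon Exploration probability of the epsilon-greedy selector.
#' @return An object of class `mall_constraints`.
#' @export
mall_constraints <- function(E_target, E_band = 0.05, mass_criterion,
                             mass_slack = 0.15, epsilon = 0.05) {
  stopifnot(E_target > 0, E_band > 0, E_band < 1, mass_criterion > 0,
            mass_criterion < 1, mass_slack > 0, mass_slack < 1,
            epsilon >= 0, epsilon < 1)
  structure(list(E_target = E_target, E_band = E_band,
                 mass_criterion = mass_criterion, mass_slack = mass_slack,
                 epsilon = epsilon),
            class = "mall_constraints")
}

#' Stopping rule for the active-learning loop
#'
#' The loop stops on success when the best in-band oracle strength exceeds
#' the golden-criterion strength by `margin`, on stagnation after
#' `patience` rounds without improvement, or at `max_rounds`.
#'
#' @param margin Relative success margin over the golden criterion.
#' @param patience Rounds without improvement tolerated.
#' @param max_rounds Hard round cap.
#' @return An object of class `stopping_rule`.
#' @export
stopping_rule <- function(margin = 0.10, patience = 3, max_rounds = 6) {
  stopifnot(margin >= 0, patience >= 1, max_rounds >= 1)
  structure(list(margin = margin, patience = as.integer(patience),
                 max_rounds = as.integer(max_rounds)),
            class = "stopping_rule")
}

#' Golden criterion: the uniform design matching the target modulus
#'
#' Bisection on the uniform porosity so that the oracle modulus of the
#' uniform design equals `E_target` within 0.5%. The returned strength and
#' mass fraction are the benchmark heterogeneous designs must beat and the
#' default mass criterion.
#'
#' @param E_target Target modulus in MPa.
#' @param ospec An [oracle_spec()].
#' @param shape Design matrix edge.
#' @param p_range Admissible uniform porosity range.
#' @return List with `p_uniform`, `E`, `Y`, `mass_fraction`.
#' @export
golden_criterion <- function(E_target, ospec = oracle_spec(), shape = 3,
                             p_range = c(0.2, 0.9)) {
  uniform_E <- function(p)
    synthetic_oracle(porosity_matrix(array(p, rep(shape, 3))), ospec)$E
  E_hi <- uniform_E(p_range[1])
  E_lo <- uniform_E(p_range[2])
  if (E_target > E_hi || E_target < E_lo)
    stop(sprintf("E_target %.4g outside achievable uniform range [%.4g, %.4g]",
                 E_target, E_lo, E_hi))
  lo <- p_range[1]
  hi <- p_range[2]
  for (it in seq_len(60)) {
    mid <- (lo + hi) / 2
    E <- uniform_E(mid)
    if (abs(E - E_target) / E_target <= 0.005) break
    if (E > E_target) lo <- mid else hi <- mid
  }
  res <- synthetic_oracle(porosity_matrix(array(mid, rep(shape, 3))), ospec)
  list(p_uniform = mid, E = res$E, Y = res$Y,
       mass_fraction = res$mass_fraction)
}

.matrix_key <- function(m) paste(sprintf("%.4f", as.vector(m)), collapse = ",")

#' Epsilon-greedy constrained candidate selection
#'
#' Applies the mass cap, then the predicted-modulus band; band survivors are
#' ranked by predicted strength and the top `k` strictly improving on
#' `best_Y` are taken, each pick being replaced with probability `epsilon`
#' by a uniformly random non-improving band survivor. Candidates equal to
#' an already labeled design (or to an earlier pick) are skipped. Uses the
#' R random number generator.
#'
#' @param pool List with parallel fields `matrices` (list of porosity
#'   matrices), `pred_E`, `pred_Y`, `mass` (numeric vectors).
#' @param constraints A [mall_constraints()].
#' @param best_Y Best labeled in-band strength so far.
#' @param k Maximum number of picks.
#' @param labeled_keys Character keys of already labeled designs.
#' @return Integer indices into the pool (possibly empty).
#' @export
select_candidates <- function(pool, constraints, best_Y, k,
                              labeled_keys = character(0)) {
  n <- length(pool$pred_Y)
  if (n == 0) return(integer(0))
  keys <- vapply(pool$matrices, .matrix_key, character(1))
  mass_ok <- pool$mass <= constraints$mass_criterion * (1 + constraints$mass_slack)
  band_ok <- abs(pool$pred_E - constraints$E_target) <=
    constraints$E_band * constraints$E_target
  fresh <- !keys %in% labeled_keys & !duplicated(keys)
  surv <- which(mass_ok & band_ok & fresh)
  if (length(surv) == 0) return(integer(0))
  exploit <- surv[pool$pred_Y[surv] > best_Y]
  exploit <- exploit[order(pool$pred_Y[exploit], decreasing = TRUE)]
  explore <- surv[pool$pred_Y[surv] <= best_Y]
  picks <- integer(0)
  ei <- 1L
  for (slot in seq_len(k)) {
    explore_now <- constraints$epsilon > 0 && length(explore) > 0 &&
      stats::runif(1) < constraints$epsilon
    if (explore_now) {
      j <- explore[sample.int(length(explore), 1)]
      explore <- setdiff(explore, j)
      picks <- c(picks, j)
    } else if (ei <= length(exploit)) {
      picks <- c(picks, exploit[ei])
      ei <- ei + 1L
    }
    # neither an improving candidate left nor an exploration draw: the
    # slot stays empty
  }
  unique(picks)
}

#' Configuration of an active-learning run
#'
#' Bundles every specification the loop needs. `cae` and `gmm` may be
#' pre-trained models (so several seeded runs can share one generative
#' model, as the generative model is trained once per corpus); otherwise
#' they are fitted from `corpus` inside [run_mall()].
#'
#' @param shape Design matrix edge (2, 3 or 4).
#' @param ladder Admissible porosity ladder.
#' @param geometry A [unit_cell_spec()]; `cells_per_axis` must equal `shape`.
#' @param oracle_spec_ An [oracle_spec()] for the analytic oracle.
#' @param oracle Optional oracle function overriding the analytic one.
#' @param constraints A [mall_constraints()]; if `mass_criterion` is `NA`
#'   it is filled from the golden criterion.
#' @param stopping A [stopping_rule()].
#' @param cae_spec_ A [cae_spec()]; used when `cae` is not supplied.
#' @param surrogate_spec_ A [surrogate_spec()] template for both surrogates.
#' @param corpus_spec_ A [corpus_spec()]; used when `cae` is not supplied.
#' @param cae,gmm Optional pre-trained generative models.
#' @param n_samples Latent samples per round (default 2000).
#' @param k Oracle queries per round (default 6).
#' @param n_initial Initial labeled designs (default 95).
#' @param seed Master seed of the run.
#' @param grid_cache Optional environment caching voxelised designs, so
#'   repeated runs over one landscape (e.g. seed sweeps) share geometry
#'   work. Caching is by design content; results are unaffected.
#' @return An object of class `mall_config`.
#' @export
mall_config <- function(shape = 3, ladder = porosity_ladder(),
                        geometry = NULL, oracle_spec_ = oracle_spec(),
                        oracle = NULL, constraints, stopping = stopping_rule(),
                        cae_spec_ = cae_spec(), surrogate_spec_ = surrogate_spec(),
                        corpus_spec_ = NULL, cae = NULL, gmm = NULL,
                        n_samples = 2000, k = 6, n_initial = 95, seed = 1,
                        grid_cache = NULL) {
  if (is.null(geometry)) geometry <- unit_cell_spec(cells_per_axis = shape)
  stopifnot(geometry$cells_per_axis == shape)
  if (is.null(corpus_spec_))
    corpus_spec_ <- corpus_spec(n_per_interval = 120, shapes = shape,
                                ladder = ladder, seed = seed)
  structure(list(shape = as.integer(shape), ladder = ladder,
                 geometry = geometry, oracle_spec = oracle_spec_,
                 oracle = oracle, constraints = constraints,
                 stopping = stopping, cae_spec = cae_spec_,
                 surrogate_spec = surrogate_spec_, corpus_spec = corpus_spec_,
                 cae = cae, gmm = gmm, n_samples = as.integer(n_samples),
                 k = as.integer(k), n_initial = as.integer(n_initial),
                 seed = as.integer(seed), grid_cache = grid_cache),
            class = "mall_config")
}

.get_oracle <- function(config) {
  if (!is.null(config$oracle)) config$oracle
  else analytic_oracle(config$oracle_spec)
}

#' Fit the generative models for a configuration
#'
#' Generates the corpus, trains the autoencoder, embeds the corpus and fits
#' the latent Gaussian mixture.
#'
#' @param config A [mall_config()].
#' @param K_range Component counts tried for the mixture.
#' @return The config with `cae` and `gmm` filled in.
#' @export
prepare_generative <- function(config, K_range = 1:6) {
  if (!is.null(config$cae) && !is.null(config$gmm)) return(config)
  corpus <- generate_corpus(config$corpus_spec)
  config$cae <- train_cae(corpus, config$cae_spec)
  emb <- encode(config$cae, corpus$arrays)
  config$gmm <- fit_latent_gmm(emb, K_range = K_range, seed = config$seed)
  config
}

# voxelize a list of matrices and return V x n matrix of occupancies;
# an optional cache environment (keyed by matrix) avoids re-voxelising
# designs that reappear across rounds, up to ~400 MB of cached grids
.voxelize_many <- function(mats, geometry, cache = NULL) {
  V <- grid_edge(geometry)^3
  cap <- floor(4e8 / (8 * V))
  out <- matrix(0, V, length(mats))
  for (i in seq_along(mats)) {
    key <- if (!is.null(cache)) .matrix_key(mats[[i]]) else NULL
    hit <- if (!is.null(key)) cache[[key]] else NULL
    if (!is.null(hit)) {
      out[, i] <- hit
    } else {
      g <- as.numeric(voxelize(mats[[i]], geometry))
      out[, i] <- g
      if (!is.null(key) && length(ls(cache)) < cap) cache[[key]] <- g
    }
  }
  out
}

.new_state <- function(seed) {
  structure(list(matrices = list(), keys = character(0),
                 E = numeric(0), Y = numeric(0), mass = numeric(0),
                 grids = NULL, round = 0L, best_inband_Y = -Inf,
                 oracle_calls = 0L, seed = as.integer(seed),
                 grid_cache = new.env(parent = emptyenv()),
                 history = NULL),
            class = "loop_state")
}

.inband <- function(E, constraints)
  abs(E - constraints$E_target) <= constraints$E_band * constraints$E_target

.label_designs <- function(state, mats, grids, oracle, constraints,
                           pred_E = rep(NA_real_, length(mats)),
                           pred_Y = rep(NA_real_, length(mats))) {
  for (i in seq_along(mats)) {
    lab <- oracle(mats[[i]])
    state$matrices[[length(state$matrices) + 1L]] <- mats[[i]]
    state$keys <- c(state$keys, .matrix_key(mats[[i]]))
    state$E <- c(state$E, lab$E)
    state$Y <- c(state$Y, lab$Y)
    state$mass <- c(state$mass, mean(grids[, i]))
    state$oracle_calls <- state$oracle_calls + 1L
  }
  state$grids <- if (is.null(state$grids)) grids else cbind(state$grids, grids)
  inb <- .inband(state$E, constraints)
  if (any(inb)) state$best_inband_Y <- max(state$Y[inb])
  state
}

.train_surrogates <- function(state, spec_template, round_seed) {
  specE <- spec_template
  specE$target <- "E"
  specE$seed <- round_seed
  specY <- spec_template
  specY$target <- "Y"
  specY$seed <- round_seed + 1L
  list(E = train_surrogate(state$grids, state$E, specE),
       Y = train_surrogate(state$grids, state$Y, specY))
}

#' Run one active-learning round
#'
#' Samples `n_samples` latent points, decodes them to snapped porosity
#' matrices, voxelises the distinct designs, predicts E and Y with the
#' surrogates, selects up to `k` candidates under the constraints, labels
#' them with the oracle, and retrains both surrogates from scratch on the
#' augmented set.
#'
#' @param state A `loop_state`.
#' @param surrogates List with elements `E` and `Y` (trained models).
#' @param config A [mall_config()] with `cae` and `gmm` present.
#' @return List with the updated `state`, `surrogates`, and the round's
#'   history row.
#' @export
run_round <- function(state, surrogates, config) {
  round <- state$round + 1L
  round_seed <- config$seed + 7919L * round
  set.seed(round_seed)
  z <- sample_latent(config$gmm, config$n_samples, seed = round_seed)
  mats <- decode_to_matrix(z, config$cae, snap = TRUE, shape = config$shape,
                           ladder = config$ladder)
  keys <- vapply(mats, .matrix_key, character(1))
  uniq <- !duplicated(keys)
  mats <- mats[uniq]
  pred_E <- numeric(length(mats))
  pred_Y <- numeric(length(mats))
  mass <- numeric(length(mats))
  chunk <- 100L
  for (s0 in seq(1L, length(mats), by = chunk)) {
    idx <- s0:min(s0 + chunk - 1L, length(mats))
    G <- .voxelize_many(mats[idx], config$geometry, state$grid_cache)
    pred_E[idx] <- predict(surrogates$E, G)
    pred_Y[idx] <- predict(surrogates$Y, G)
    mass[idx] <- colMeans(G)
  }
  pool <- list(matrices = mats, pred_E = pred_E, pred_Y = pred_Y, mass = mass)
  picks <- select_candidates(pool, config$constraints, state$best_inband_Y,
                             config$k, state$keys)
  oracle <- .get_oracle(config)
  prev_best <- state$best_inband_Y
  if (length(picks) > 0) {
    G_sel <- .voxelize_many(mats[picks], config$geometry, state$grid_cache)
    state <- .label_designs(state, mats[picks], G_sel, oracle,
                            config$constraints)
    new_E <- state$E[(length(state$E) - length(picks) + 1L):length(state$E)]
    mean_E_err <- mean(abs(pred_E[picks] - new_E))
  } else {
    mean_E_err <- NA_real_
  }
  # retrained from scratch every round (fresh seed): on a null round this
  # re-initialises the fit so persistent mispredictions do not lock the
  # selector permanently
  surrogates <- .train_surrogates(state, config$surrogate_spec,
                                  config$seed + 100L * round)
  state$round <- round
  row <- data.frame(round = round, n_pool = length(mats),
                    n_selected = length(picks),
                    n_labeled = length(state$Y),
                    oracle_calls = state$oracle_calls,
                    best_inband_Y = state$best_inband_Y,
                    improved = state$best_inband_Y > prev_best,
                    mean_abs_E_err = mean_E_err)
  state$history <- rbind(state$history, row)
  list(state = state, surrogates = surrogates, row = row)
}

# stratified-by-kind initial design set, deduplicated; the kind cursor
# advances on duplicates too, so a small family (e.g. central on a coarse
# ladder) cannot stall the draw
.initial_designs <- function(config) {
  set.seed(config$seed)
  mats <- list()
  keys <- character(0)
  ki <- 0L
  tries <- 0L
  while (length(mats) < config$n_initial && tries < 100L * config$n_initial) {
    tries <- tries + 1L
    kind <- .arrangement_kinds[ki %% 4L + 1L]
    ki <- ki + 1L
    m <- generate_matrix(kind, config$shape, config$ladder)
    key <- .matrix_key(m)
    if (key %in% keys) next
    mats[[length(mats) + 1L]] <- m
    keys <- c(keys, key)
  }
  if (length(mats) < config$n_initial)
    warning(sprintf("initial design set has %d of %d requested designs",
                    length(mats), config$n_initial))
  mats
}

#' Run the full multi-objective active-learning loop
#'
#' Prepares (or reuses) the generative models, labels a stratified initial
#' design set with the oracle, trains the twin surrogates, and iterates
#' [run_round()] until the stopping rule fires.
#'
#' @param config A [mall_config()].
#' @return An object of class `mall_result`: the final `state`, the history
#'   table, the golden criterion, and the stop reason
#'   (`"success"`, `"stalled"` or `"max_rounds"`).
#' @export
run_mall <- function(config) {
  config <- prepare_generative(config)
  golden <- golden_criterion(config$constraints$E_target, config$oracle_spec,
                             config$shape)
  if (is.na(config$constraints$mass_criterion))
    config$constraints$mass_criterion <- golden$mass_fraction
  oracle <- .get_oracle(config)
  state <- .new_state(config$seed)
  if (!is.null(config$grid_cache)) state$grid_cache <- config$grid_cache
  mats <- .initial_designs(config)
  grids <- .voxelize_many(mats, config$geometry, state$grid_cache)
  state <- .label_designs(state, mats, grids, oracle, config$constraints)
  surrogates <- .train_surrogates(state, config$surrogate_spec, config$seed)
  reason <- "max_rounds"
  stall <- 0L
  for (r in seq_len(config$stopping$max_rounds)) {
    res <- run_round(state, surrogates, config)
    state <- res$state
    surrogates <- res$surrogates
    if (is.finite(state$best_inband_Y) &&
        state$best_inband_Y >= (1 + config$stopping$margin) * golden$Y) {
      reason <- "success"
      break
    }
    stall <- if (isTRUE(res$row$improved)) 0L else stall + 1L
    if (stall >= config$stopping$patience) {
      reason <- "stalled"
      break
    }
  }
  structure(list(state = state, history = state$history, golden = golden,
                 stop_reason = reason,
                 success = reason == "success",
                 best_inband_Y = state$best_inband_Y,
                 oracle_calls = state$oracle_calls,
                 surrogates = surrogates, config = config),
            class = "mall_result")
}

#' @export
print.mall_result <- function(x, ...) {
  cat(sprintf("active-learning run: %d rounds, %d oracle calls, best in-band Y %.4g MPa (golden %.4g), stop: %s\n",
              x$state$round, x$oracle_calls, x$best_inband_Y, x$golden$Y,
              x$stop_reason))
  invisible(x)
}

#' Random-search baseline under the same oracle budget
#'
#' Labels the same initial set, then draws admissible designs uniformly
#' (i.i.d. ladder entries), applies the mass cap, and labels `k` per round.
#'
#' @param config A [mall_config()].
#' @return A list with the history table, best in-band Y and oracle calls.
#' @export
run_random_baseline <- function(config) {
  golden <- golden_criterion(config$constraints$E_target, config$oracle_spec,
                             config$shape)
  if (is.na(config$constraints$mass_criterion))
    config$constraints$mass_criterion <- golden$mass_fraction
  oracle <- .get_oracle(config)
  set.seed(config$seed)
  mats <- .initial_designs(config)
  E <- numeric(0)
  Y <- numeric(0)
  keys <- character(0)
  labelled <- function(m) {
    lab <- oracle(m)
    E <<- c(E, lab$E)
    Y <<- c(Y, lab$Y)
    keys <<- c(keys, .matrix_key(m))
  }
  for (m in mats) labelled(m)
  history <- NULL
  cap <- config$constraints$mass_criterion * (1 + config$constraints$mass_slack)
  for (r in seq_len(config$stopping$max_rounds)) {
    picked <- 0L
    tries <- 0L
    while (picked < config$k && tries < 500L) {
      tries <- tries + 1L
      m <- porosity_matrix(array(
        config$ladder[sample.int(length(config$ladder), config$shape^3,
                                 replace = TRUE)],
        rep(config$shape, 3)), discrete = TRUE)
      if (mean(1 - m) > cap) next
      if (.matrix_key(m) %in% keys) next
      labelled(m)
      picked <- picked + 1L
    }
    inb <- .inband(E, config$constraints)
    history <- rbind(history, data.frame(
      round = r, n_selected = picked, n_labeled = length(Y),
      oracle_calls = length(Y),
      best_inband_Y = if (any(inb)) max(Y[inb]) else -Inf))
  }
  inb <- .inband(E, config$constraints)
  list(history = history,
       best_inband_Y = if (any(inb)) max(Y[inb]) else -Inf,
       oracle_calls = length(Y), golden = golden)
}

# minimal RBF-kernel Gaussian process used by the BO baseline
.gp_fit <- function(X, y, noise = 1e-6) {
  X <- as.matrix(X)
  mu <- mean(y)
  sdv <- stats::sd(y)
  if (sdv == 0) sdv <- 1
  ys <- (y - mu) / sdv
  d <- as.matrix(stats::dist(X))
  ell <- stats::median(d[d > 0])
  if (!is.finite(ell) || ell == 0) ell <- 1
  K <- exp(-0.5 * (d / ell)^2) + diag(noise + 1e-8, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  list(X = X, L = L, alpha = alpha, ell = ell, mu = mu, sdv = sdv)
}

.gp_predict <- function(gp, Xnew) {
  Xnew <- as.matrix(Xnew)
  cross <- exp(-0.5 * (.cdist(Xnew, gp$X) / gp$ell)^2)
  mean_s <- as.vector(cross %*% gp$alpha)
  v <- forwardsolve(t(gp$L), t(cross))
  var_s <- pmax(1 - colSums(v^2), 1e-12)
  list(mean = mean_s * gp$sdv + gp$mu, sd = sqrt(var_s) * gp$sdv)
}

.cdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  sqrt(pmax(outer(an, bn, "+") - 2 * A %*% t(B), 0))
}

#' Bayesian-optimisation baseline in the latent space
#'
#' Fits RBF Gaussian processes for E and Y on the labeled latent codes and
#' selects candidates by expected improvement on Y multiplied by the
#' probability (under the E process) of landing in the modulus band; the
#' mass cap is applied beforehand. Uses the same generative models, initial
#' set and oracle budget as [run_mall()].
#'
#' @param config A [mall_config()] (with `cae`/`gmm` present or fittable).
#' @return A list with the history table, best in-band Y and oracle calls.
#' @export
run_bo_baseline <- function(config) {
  config <- prepare_generative(config)
  golden <- golden_criterion(config$constraints$E_target, config$oracle_spec,
                             config$shape)
  if (is.na(config$constraints$mass_criterion))
    config$constraints$mass_criterion <- golden$mass_fraction
  oracle <- .get_oracle(config)
  set.seed(config$seed)
  mats <- .initial_designs(config)
  Z <- do.call(rbind, lapply(mats, function(m)
    encode(config$cae, expand_matrix(m))))
  E <- numeric(0)
  Y <- numeric(0)
  keys <- character(0)
  for (m in mats) {
    lab <- oracle(m)
    E <- c(E, lab$E)
    Y <- c(Y, lab$Y)
    keys <- c(keys, .matrix_key(m))
  }
  cap <- config$constraints$mass_criterion * (1 + config$constraints$mass_slack)
  history <- NULL
  for (r in seq_len(config$stopping$max_rounds)) {
    round_seed <- config$seed + 7919L * r
    set.seed(round_seed)
    z <- sample_latent(config$gmm, config$n_samples, seed = round_seed)
    mats_r <- decode_to_matrix(z, config$cae, snap = TRUE,
                               shape = config$shape, ladder = config$ladder)
    keys_r <- vapply(mats_r, .matrix_key, character(1))
    keep <- !duplicated(keys_r) & !keys_r %in% keys
    mass_r <- vapply(mats_r, function(m) mean(1 - m), numeric(1))
    keep <- keep & mass_r <= cap
    if (!any(keep)) {
      history <- rbind(history, data.frame(round = r, n_selected = 0L,
                                           n_labeled = length(Y),
                                           oracle_calls = length(Y),
                                           best_inband_Y = .best_inband(E, Y, config)))
      next
    }
    mats_r <- mats_r[keep]
    zk <- z[keep, , drop = FALSE]
    gpY <- .gp_fit(Z, Y)
    gpE <- .gp_fit(Z, E)
    pY <- .gp_predict(gpY, zk)
    pE <- .gp_predict(gpE, zk)
    inb <- .inband(E, config$constraints)
    best <- if (any(inb)) max(Y[inb]) else max(Y)
    imp <- pY$mean - best
    zs <- imp / pY$sd
    ei <- imp * stats::pnorm(zs) + pY$sd * stats::dnorm(zs)
    half <- config$constraints$E_band * config$constraints$E_target
    p_band <- stats::pnorm((config$constraints$E_target + half - pE$mean) / pE$sd) -
      stats::pnorm((config$constraints$E_target - half - pE$mean) / pE$sd)
    score <- ei * p_band
    picks <- order(score, decreasing = TRUE)[seq_len(min(config$k, length(score)))]
    for (i in picks) {
      lab <- oracle(mats_r[[i]])
      E <- c(E, lab$E)
      Y <- c(Y, lab$Y)
      keys <- c(keys, .matrix_key(mats_r[[i]]))
      Z <- rbind(Z, zk[i, ])
    }
    history <- rbind(history, data.frame(round = r, n_selected = length(picks),
                                         n_labeled = length(Y),
                                         oracle_calls = length(Y),
                                         best_inband_Y = .best_inband(E, Y, config)))
  }
  list(history = history, best_inband_Y = .best_inband(E, Y, config),
       oracle_calls = length(Y), golden = golden)
}

.best_inband <- function(E, Y, config) {
  inb <- .inband(E, config$constraints)
  if (any(inb)) max(Y[inb]) else -Inf
}

#' Enumerate every design on a small ladder (toy landscape)
#'
#' @param shape Matrix edge (2 recommended: `length(ladder)^8` designs).
#' @param ladder Porosity ladder.
#' @return A `shape^3` x n matrix; each column one design.
#' @export
enumerate_designs <- function(shape = 2, ladder = c(0.3, 0.6, 0.9)) {
  cells <- shape^3
  grid <- do.call(expand.grid, rep(list(ladder), cells))
  t(as.matrix(grid))
}

#' Brute-force optimum of the constrained strength maximisation
#'
#' Labels every enumerable design with the oracle and returns the best
#' strength among designs whose oracle modulus lies in the band and whose
#' mass respects the cap.
#'
#' @param constraints A [mall_constraints()].
#' @param ospec An [oracle_spec()].
#' @param shape,ladder Toy landscape definition.
#' @return List with `best_Y`, `best_design`, `n_designs`, `n_feasible`.
#' @export
brute_force_optimum <- function(constraints, ospec = oracle_spec(),
                                shape = 2, ladder = c(0.3, 0.6, 0.9)) {
  designs <- enumerate_designs(shape, ladder)
  n <- ncol(designs)
  E <- numeric(n)
  Y <- numeric(n)
  mass <- numeric(n)
  for (i in seq_len(n)) {
    m <- porosity_matrix(array(designs[, i], rep(shape, 3)))
    lab <- synthetic_oracle(m, ospec)
    E[i] <- lab$E
    Y[i] <- lab$Y
    mass[i] <- lab$mass_fraction
  }
  ok <- .inband(E, constraints) &
    mass <= constraints$mass_criterion * (1 + constraints$mass_slack)
  if (!any(ok)) stop("no feasible design on the toy landscape")
  best <- which(ok)[which.max(Y[ok])]
  list(best_Y = Y[best],
       best_design = array(designs[, best], rep(shape, 3)),
       n_designs = n, n_feasible = sum(ok))
}
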