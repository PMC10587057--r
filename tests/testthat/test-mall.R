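test_that("golden criterion inverts the uniform-design modulus", {
  osp <- oracle_spec()
  g <- golden_criterion(5000 * 0.25, osp, shape = 3)
  expect_equal(g$p_uniform, 0.5, tolerance = 0.005)
  expect_lte(abs(g$E - 1250) / 1250, 0.005)
  expect_equal(g$mass_fraction, 1 - g$p_uniform, tolerance = 1e-9)
  expect_error(golden_criterion(4000, osp, shape = 3), "outside")
  expect_error(golden_criterion(10, osp, shape = 3), "outside")
})

.mk_pool <- function(pred_E, pred_Y, mass) {
  n <- length(pred_E)
  # base-8 digits of i give n distinct designs
  mats <- lapply(seq_len(n), function(i)
    porosity_matrix(array(0.2 + 0.1 * ((i %/% 8^(0:7)) %% 8), c(2, 2, 2))))
  list(matrices = mats, pred_E = pred_E, pred_Y = pred_Y, mass = mass)
}

test_that("selection enforces the mass cap before anything else", {
  cons <- mall_constraints(E_target = 1000, mass_criterion = 0.4)
  # candidate 16% over the mass criterion is rejected despite a huge Y
  pool <- .mk_pool(pred_E = c(1000, 1000), pred_Y = c(1e6, 10),
                   mass = c(0.4 * 1.16, 0.40))
  set.seed(1)
  picks <- select_candidates(pool, cons, best_Y = 1, k = 2)
  expect_identical(picks, 2L)
})

test_that("selection with no improving candidate and epsilon 0 is empty", {
  cons <- mall_constraints(E_target = 1000, mass_criterion = 0.5,
                           epsilon = 0)
  pool <- .mk_pool(pred_E = rep(1000, 3), pred_Y = c(1, 2, 3),
                   mass = rep(0.4, 3))
  expect_length(select_candidates(pool, cons, best_Y = 5, k = 2), 0)
})

test_that("selection ranks improving candidates by predicted strength", {
  cons <- mall_constraints(E_target = 1000, mass_criterion = 0.5,
                           epsilon = 0)
  pool <- .mk_pool(pred_E = rep(1000, 3), pred_Y = c(10, 20, 30),
                   mass = rep(0.4, 3))
  picks <- select_candidates(pool, cons, best_Y = 5, k = 2)
  expect_identical(picks, c(3L, 2L))
  # out-of-band candidates never selected
  pool$pred_E <- c(1000, 2000, 1000)
  picks <- select_candidates(pool, cons, best_Y = 5, k = 3)
  expect_identical(sort(picks), c(1L, 3L))
})

test_that("already labeled designs are not re-selected", {
  cons <- mall_constraints(E_target = 1000, mass_criterion = 0.5,
                           epsilon = 0)
  pool <- .mk_pool(pred_E = rep(1000, 3), pred_Y = c(10, 20, 30),
                   mass = rep(0.4, 3))
  key2 <- gyrodesign:::.matrix_key(pool$matrices[[3]])
  picks <- select_candidates(pool, cons, best_Y = 5, k = 3,
                             labeled_keys = key2)
  expect_false(3L %in% picks)
})

test_that("exploration picks occur at about the epsilon rate", {
  cons <- mall_constraints(E_target = 1000, mass_criterion = 0.5,
                           epsilon = 0.05)
  pool <- .mk_pool(pred_E = rep(1000, 40),
                   pred_Y = c(rep(50, 20), rep(1, 20)),
                   mass = rep(0.4, 40))
  set.seed(42)
  explores <- 0L
  n_sel <- 0L
  for (i in 1:1000) {
    picks <- select_candidates(pool, cons, best_Y = 10, k = 1)
    n_sel <- n_sel + length(picks)
    explores <- explores + sum(pool$pred_Y[picks] <= 10)
  }
  bt <- binom.test(explores, n_sel, p = 0.05)
  expect_gt(bt$p.value, 0.01)
})

test_that("a short loop run is reproducible and accounting is consistent", {
  cfg <- toy_config_with_models(seed = 3)
  cfg$stopping <- stopping_rule(margin = 5, patience = 3, max_rounds = 2)
  cfg$n_samples <- 400
  cfg$k <- 4
  cfg$n_initial <- 55
  r1 <- suppressWarnings(run_mall(cfg))
  r2 <- suppressWarnings(run_mall(cfg))
  expect_identical(r1$history, r2$history)
  expect_equal(r1$oracle_calls, 55 + sum(r1$history$n_selected))
  # labeled set grows by exactly the selected count each round
  expect_equal(diff(c(55, r1$history$n_labeled)), r1$history$n_selected)
  # best in-band strength never decreases across rounds
  expect_true(all(diff(r1$history$best_inband_Y) >= 0))
  # every loop-labeled candidate satisfies the mass cap (the initial
  # stratified set is unfiltered by design)
  cap <- cfg$constraints$mass_criterion * (1 + cfg$constraints$mass_slack)
  loop_labeled <- r1$state$mass[-seq_len(55)]
  expect_true(all(loop_labeled <= cap + 1e-9))
  # success flag implies the margin inequality
  expect_equal(r1$success,
               r1$best_inband_Y >= (1 + cfg$stopping$margin) * r1$golden$Y)
  # histories serialize losslessly
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_history_csv(r1$history, path)
  back <- read_history_csv(path)
  expect_equal(back$best_inband_Y, r1$history$best_inband_Y)
  expect_equal(back$n_selected, r1$history$n_selected)
})

test_that("baselines run under the same budget and schema", {
  cfg <- toy_config_with_models(seed = 5)
  cfg$stopping <- stopping_rule(margin = 5, patience = 3, max_rounds = 2)
  cfg$n_samples <- 300
  cfg$k <- 3
  cfg$n_initial <- 55
  rb <- run_random_baseline(cfg)
  expect_equal(rb$oracle_calls,
               55 + sum(rb$history$n_selected))
  expect_lte(rb$oracle_calls, 55 + 2 * 3)
  bo <- run_bo_baseline(cfg)
  expect_lte(bo$oracle_calls, 55 + 2 * 3)
  expect_true(all(c("round", "n_selected", "n_labeled", "oracle_calls",
                    "best_inband_Y") %in% names(bo$history)))
  expect_true(all(c("round", "n_selected", "n_labeled", "oracle_calls",
                    "best_inband_Y") %in% names(rb$history)))
})

test_that("toy landscape enumeration and optimum are well-defined", {
  designs <- enumerate_designs(2, c(0.3, 0.6, 0.9))
  expect_equal(dim(designs), c(8, 6561))
  expect_equal(nrow(unique(t(designs))), 6561)
  cons <- toy_constraints()
  bf <- toy_brute_force()
  expect_equal(bf$n_designs, 6561)
  expect_gt(bf$n_feasible, 0)
  lab <- synthetic_oracle(porosity_matrix(bf$best_design), toy_oracle_spec())
  expect_equal(lab$Y, bf$best_Y)
  expect_lte(abs(lab$E - cons$E_target), cons$E_band * cons$E_target)
})
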