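test_that("regression metrics match hand-computed and brute-force values", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$mae, 0)
  expect_equal(m$r2, 1)
  y <- c(4, 8, 6, 10)
  m <- regression_metrics(y, rep(mean(y), 4))
  expect_equal(m$r2, 0)
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$r2, 0.5)
  set.seed(6)
  for (i in 1:5) {
    y <- rnorm(100)
    yh <- rnorm(100)
    m <- regression_metrics(y, yh)
    expect_equal(m$mae, sum(abs(y - yh)) / 100, tolerance = 1e-10)
    expect_equal(m$r2, 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }
  expect_warning(m <- regression_metrics(c(2, 2, 2), c(1, 2, 3)),
                 "zero variance")
  expect_true(is.na(m$r2))
})

test_that("surrogate input validation catches bad data", {
  d <- small_labeled_set()
  expect_error(train_surrogate(d$grids[, 1:10], d$E[1:10]), "at least 50")
  expect_error(train_surrogate(d$grids * 0.5, d$E), "binary")
  expect_error(train_surrogate(d$grids, d$E[-1]), "label length")
})

test_that("constant labels give a degenerate but exact fit", {
  d <- small_labeled_set()
  mod <- train_surrogate(d$grids[, 1:60], rep(42, 60),
                         surrogate_spec(epochs = 2, seed = 1))
  pr <- predict(mod, d$grids[, 61:70])
  expect_equal(pr, rep(42, 10))
  expect_warning(met <- evaluate_surrogate(mod, d$grids[, 61:70], rep(42, 10)),
                 "zero variance")
  expect_equal(met$mae, 0)
  expect_error(compute_ram(mod, d$grids[, 61]), "constant")
})

test_that("the surrogate learns oracle labels on compact grids", {
  d <- small_labeled_set()
  tr <- 1:120
  te <- 121:150
  mod <- train_surrogate(d$grids[, tr], d$E[tr],
                         surrogate_spec(target = "E", epochs = 12, seed = 3))
  met <- evaluate_surrogate(mod, d$grids[, te], d$E[te])
  expect_gt(met$r2, 0.5)
  expect_lt(met$mae, diff(range(d$E)) / 4)
})

test_that("training is deterministic and survives serialization", {
  d <- small_labeled_set()
  sp <- surrogate_spec(epochs = 3, seed = 11)
  m1 <- train_surrogate(d$grids[, 1:60], d$E[1:60], sp)
  m2 <- train_surrogate(d$grids[, 1:60], d$E[1:60], sp)
  p1 <- predict(m1, d$grids[, 61:80])
  expect_identical(p1, predict(m2, d$grids[, 61:80]))
  path <- tempfile(fileext = ".rds")
  on.exit(unlink(path))
  saveRDS(m1, path)
  expect_identical(p1, predict(readRDS(path), d$grids[, 61:80]))
})

test_that("activation maps are well-formed and deterministic", {
  d <- small_labeled_set()
  mod <- train_surrogate(d$grids[, 1:60], d$E[1:60],
                         surrogate_spec(epochs = 5, seed = 2))
  ram <- compute_ram(mod, d$grids[, 61])
  expect_s3_class(ram, "ram_volume")
  expect_equal(dim(ram), dim(voxelize(d$mats[[1]], d$geo)))
  expect_gte(min(ram), 0)
  expect_equal(max(ram), 1)
  ram2 <- compute_ram(mod, d$grids[, 61])
  expect_identical(unclass(ram), unclass(ram2))
})

test_that("activation maps localise the octant that drives the label", {
  # labels depend only on the porosity of the (1,1,1) subunit of a 2^3
  # design; a well-trained surrogate's attention should concentrate there
  geo <- toy_geometry()
  set.seed(55)
  ladder <- porosity_ladder()
  mats <- lapply(1:100, function(i)
    porosity_matrix(array(sample(ladder, 8, replace = TRUE), c(2, 2, 2)),
                    discrete = TRUE))
  grids <- matrix(0, grid_edge(geo)^3, 100)
  for (i in 1:100) grids[, i] <- as.numeric(voxelize(mats[[i]], geo))
  y <- vapply(mats, function(m) 100 * (1 - m[1, 1, 1])^2, numeric(1))
  mod <- train_surrogate(grids[, 1:80], y[1:80],
                         surrogate_spec(epochs = 20, lr = 2e-3, seed = 4,
                                        val_frac = 0))
  n <- grid_edge(geo)
  half <- n / 2
  inside <- 0L
  for (i in 81:100) {
    ram <- compute_ram(mod, grids[, i])
    oct <- mean(ram[1:half, 1:half, 1:half])
    # mean inside the causal octant > overall mean <=> inside > outside
    if (oct > mean(ram)) inside <- inside + 1L
  }
  expect_gte(inside, 15L)
})
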