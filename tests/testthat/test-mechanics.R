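test_that("curve validation rejects malformed input", {
  expect_error(stress_strain_curve(c(0, 0.1), c(1, 2)), "10 points")
  expect_error(stress_strain_curve(seq(0.1, 0, length.out = 12), 1:12),
               "increasing")
  expect_error(stress_strain_curve(seq(-0.01, 0.1, length.out = 12), 1:12),
               "non-negative")
})

test_that("elastic modulus recovers the slope of the linear limb", {
  lin <- stress_strain_curve(seq(0, 0.02, length.out = 50),
                             5000 * seq(0, 0.02, length.out = 50))
  expect_equal(as.numeric(elastic_modulus(lin)), 5000)
  bil <- bilinear_curve(5000, 120)
  expect_equal(as.numeric(elastic_modulus(bil)), 5000, tolerance = 1 / 5000)
  # doubling stresses doubles the modulus
  bil2 <- stress_strain_curve(bil$strain, 2 * bil$stress)
  expect_equal(as.numeric(elastic_modulus(bil2)),
               2 * as.numeric(elastic_modulus(bil)))
  flat <- stress_strain_curve(seq(0, 0.1, length.out = 30),
                              c(0, (2:30)^0.2))
  expect_error(elastic_modulus(flat), "linear")
})

test_that("offset yield intersects the translated elastic line", {
  bil <- bilinear_curve(5000, 120)
  E <- as.numeric(elastic_modulus(bil))
  expect_equal(offset_yield(bil, E), 120, tolerance = 0.1 / 120)
  # knee-point recovery at zero offset (knee placed exactly on a sample)
  bil_grid <- bilinear_curve(5000, 120, strain_max = 0.072, n = 301)
  expect_equal(offset_yield(bil_grid, as.numeric(elastic_modulus(bil_grid)),
                            offset = 0), 120, tolerance = 1e-6)
  lin <- stress_strain_curve(seq(0, 0.02, length.out = 50),
                             5000 * seq(0, 0.02, length.out = 50))
  expect_error(offset_yield(lin, 5000), "no yield")
})

test_that("offset yield recovers generator plateaus across random curves", {
  set.seed(17)
  for (i in 1:50) {
    E <- runif(1, 500, 8000)
    plateau <- runif(1, 20, 200)
    crv <- bilinear_curve(E, plateau, n = 400)
    Eh <- as.numeric(elastic_modulus(crv))
    expect_equal(offset_yield(crv, Eh), plateau, tolerance = 1e-3)
  }
})

test_that("Gibson-Ashby OLS recovers generating constants exactly", {
  p <- seq(0.2, 0.9, by = 0.1)
  for (gen in list(c(C = 0.84, a = 2.11), c(C = 0.64, a = 1.86))) {
    Y <- gen["C"] * (1 - p)^gen["a"] * 120
    fit <- fit_gibson_ashby(p, Y, 120)
    expect_equal(fit$C, unname(gen["C"]), tolerance = 1e-6)
    expect_equal(fit$alpha, unname(gen["a"]), tolerance = 1e-6)
    expect_lt(fit$residual, 1e-20)
  }
  expect_error(fit_gibson_ashby(rep(0.5, 5), rep(30, 5)), "rank-deficient")
  expect_error(fit_gibson_ashby(c(0.2, 0.5), c(10, 20)), "3 points")
  expect_error(fit_gibson_ashby(c(0.2, 0.5, 1.2), c(10, 20, 5)), "\\(0, 1\\)")
})

test_that("Gibson-Ashby OLS agrees with a brute-force grid minimiser", {
  set.seed(31)
  for (i in 1:5) {
    p <- runif(6, 0.25, 0.85)
    Y <- exp(rnorm(6, log(0.7 * (1 - p)^2 * 120), 0.05))
    fit <- fit_gibson_ashby(p, Y, 120)
    # brute-force search over (log C, alpha) around the OLS answer
    lc <- seq(log(fit$C) - 0.2, log(fit$C) + 0.2, length.out = 81)
    al <- seq(fit$alpha - 0.4, fit$alpha + 0.4, length.out = 81)
    loss <- outer(lc, al, function(a, b)
      vapply(seq_along(a), function(j)
        sum((log(Y / 120) - a[j] - b[j] * log(1 - p))^2), numeric(1)))
    best <- which(loss == min(loss), arr.ind = TRUE)[1, ]
    expect_equal(log(fit$C), lc[best[1]], tolerance = 0.01)
    expect_equal(fit$alpha, al[best[2]], tolerance = 0.02)
    expect_lte(fit$residual, min(loss) + 1e-12)
  }
})

test_that("analytic oracle collapses to the closed form on uniform designs", {
  osp <- oracle_spec()
  for (p in c(0.3, 0.5, 0.8)) {
    m <- porosity_matrix(array(p, c(3, 3, 3)))
    lab <- synthetic_oracle(m, osp)
    expect_equal(lab$E, 5000 * (1 - p)^2)
    expect_equal(lab$Y, 120 * (1 - p)^2.1 * (1 + 0.1 * (1 - p)))
    expect_equal(lab$mass_fraction, 1 - p)
  }
  m <- porosity_matrix(array(0.5, c(3, 3, 3)))
  expect_equal(synthetic_oracle(m, osp)$E, 1250)
  expect_error(synthetic_oracle(array(0.5, c(5, 5, 5)), osp), "edge")
})

test_that("oracle is monotone: removing material never helps", {
  osp <- oracle_spec()
  set.seed(13)
  for (rep in 1:40) {
    m <- generate_matrix("random", 3)
    base <- synthetic_oracle(m, osp)
    idx <- sample.int(27, 1)
    v <- as.vector(unclass(m))
    if (v[idx] >= 0.9) next
    v2 <- v
    v2[idx] <- v[idx] + 0.1  # more porosity = less material
    worse <- synthetic_oracle(porosity_matrix(array(v2, c(3, 3, 3))), osp)
    expect_lte(worse$E, base$E)
    expect_lte(worse$Y, base$Y)
  }
})

test_that("oracle is equivariant under load-axis-preserving symmetries", {
  osp <- oracle_spec()
  set.seed(19)
  syms <- list(
    function(a) aperm(a, c(2, 1, 3)),            # swap x and y
    function(a) a[dim(a)[1]:1, , ],              # mirror x
    function(a) a[, dim(a)[2]:1, ],              # mirror y
    function(a) a[, , dim(a)[3]:1],              # mirror z
    function(a) aperm(a, c(2, 1, 3))[dim(a)[1]:1, , ])  # rotate about z
  for (rep in 1:10) {
    m <- generate_matrix("random", 3)
    base <- synthetic_oracle(m, osp)
    for (s in syms) {
      tr <- synthetic_oracle(porosity_matrix(s(unclass(m))), osp)
      expect_equal(tr$E, base$E, tolerance = 1e-12)
      expect_equal(tr$Y, base$Y, tolerance = 1e-12)
    }
  }
})

test_that("oracle curves reproduce their own E and Y after post-processing", {
  osp <- oracle_spec()
  set.seed(23)
  for (rep in 1:10) {
    m <- generate_matrix("random", 3)
    lab <- synthetic_oracle(m, osp, curve = TRUE)
    E <- as.numeric(elastic_modulus(lab$curve))
    expect_equal(E, lab$E, tolerance = 1e-3)
    expect_equal(offset_yield(lab$curve, E), lab$Y, tolerance = 1e-3)
  }
})

test_that("curves round-trip through CSV", {
  crv <- bilinear_curve(3000, 80)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_curve_csv(crv, path)
  back <- read_curve_csv(path)
  expect_equal(back$strain, crv$strain)
  expect_equal(back$stress, crv$stress)
})
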