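# Mechanics post-processing and the analytic property oracle.
#
# The oracle is a deterministic closed-form stand-in for a calibrated
# compression simulation: per-subunit moduli follow a power law in solid
# fraction (Gibson-Ashby scaling), load-axis columns combine in series,
# strength is set by the weakest transverse layer and boosted by material at
# the face centers.

#' Construct and validate a stress-strain curve
#'
#' @param strain Non-negative, strictly increasing unitless strains.
#' @param stress Stresses in MPa, same length as `strain`.
#' @return An object of class `stress_strain_curve` (data.frame).
#' @export
stress_strain_curve <- function(strain, stress) {
  if (length(strain) != length(stress)) stop("strain and stress lengths differ")
  if (length(strain) < 10) stop("curve needs at least 10 points")
  if (strain[1] < 0) stop("strain must be non-negative")
  if (any(diff(strain) <= 0)) stop("strain must be strictly increasing")
  if (any(!is.finite(strain)) || any(!is.finite(stress)))
    stop("curve values must be finite")
  structure(data.frame(strain = strain, stress = stress),
            class = c("stress_strain_curve", "data.frame"))
}

#' Generate an idealised bilinear compression curve
#'
#' Linear loading at modulus `E` up to the plateau stress, then perfectly
#' plastic. Used for oracle curve output and as a test fixture generator.
#'
#' @param E Elastic modulus in MPa.
#' @param plateau Plateau (yield) stress in MPa.
#' @param strain_max Final strain; defaults to three times the knee strain.
#' @param n Number of samples.
#' @return A [stress_strain_curve()].
#' @export
bilinear_curve <- function(E, plateau, strain_max = NULL, n = 300) {
  stopifnot(E > 0, plateau > 0, n >= 10)
  if (is.null(strain_max)) strain_max <- 3 * plateau / E + 0.005
  eps <- seq(0, strain_max, length.out = n)
  stress_strain_curve(eps, pmin(E * eps, plateau))
}

# slope and R^2 of an ordinary least-squares line through (x, y)
.ols_line <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  res <- y - my - slope * (x - mx)
  sst <- sum((y - my)^2)
  r2 <- if (sst <= 0) NA_real_ else 1 - sum(res^2) / sst
  list(slope = slope, r2 = r2)
}

#' Elastic modulus from the linear region of a stress-strain curve
#'
#' The linear region is located by growing a window greedily from the first
#' 10 points for as long as its ordinary least-squares fit retains
#' R^2 >= `r2_min`. Because R^2 alone tolerates a few post-yield points at
#' the end of such a window, the window end is then trimmed while the last
#' point's residual exceeds twice the window fit's root-mean-square
#' residual (a no-op on clean linear data). The modulus is the slope of the
#' final window fit.
#'
#' @param curve A [stress_strain_curve()].
#' @param r2_min Linearity threshold on the window fit (default 0.999).
#' @return Modulus in MPa with attribute `window` = c(first, last) indices.
#' @export
#' @examples
#' elastic_modulus(bilinear_curve(5000, 120))
elastic_modulus <- function(curve, r2_min = 0.999) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  n <- nrow(curve)
  w <- 10L
  fit <- .ols_line(curve$strain[1:w], curve$stress[1:w])
  if (is.na(fit$r2) || fit$r2 < r2_min)
    stop("no initial window of >= 10 points is linear enough to define E")
  while (w < n) {
    cand <- .ols_line(curve$strain[1:(w + 1L)], curve$stress[1:(w + 1L)])
    if (is.na(cand$r2) || cand$r2 < r2_min) break
    w <- w + 1L
  }
  repeat {
    x <- curve$strain[1:w]
    y <- curve$stress[1:w]
    fit <- .ols_line(x, y)
    res <- y - mean(y) - fit$slope * (x - mean(x))
    rmse <- sqrt(mean(res^2))
    if (w <= 10L || rmse <= 1e-9 * max(abs(y)) || abs(res[w]) <= 2 * rmse)
      break
    w <- w - 1L
  }
  structure(fit$slope, window = c(1L, w))
}

#' Offset yield strength of a stress-strain curve
#'
#' Translates the elastic line horizontally by `offset` strain (0.2% by
#' default) and reports the stress at its first intersection with the curve,
#' using linear interpolation between samples.
#'
#' @param curve A [stress_strain_curve()].
#' @param E Elastic modulus in MPa (from [elastic_modulus()]).
#' @param offset Strain offset (default 0.002).
#' @return Yield strength in MPa.
#' @export
#' @examples
#' crv <- bilinear_curve(5000, 120)
#' offset_yield(crv, elastic_modulus(crv))  # 120
offset_yield <- function(curve, E, offset = 0.002) {
  stopifnot(inherits(curve, "stress_strain_curve"), E > 0)
  g <- curve$stress - E * (curve$strain - offset)
  # strictly-below crossing with a small tolerance: at zero offset the
  # elastic limb coincides with the line (g == 0 up to rounding) and must
  # not count as yielded
  tol <- 1e-8 * max(abs(curve$stress), 1)
  idx <- which(g < -tol)
  if (length(idx) == 0) stop("no yield before curve end")
  i <- idx[1]
  if (i == 1) return(curve$stress[1])
  t <- g[i - 1] / (g[i - 1] - g[i])
  curve$stress[i - 1] + t * (curve$stress[i] - curve$stress[i - 1])
}

#' Fit the Gibson-Ashby strength scaling law
#'
#' Fits `Y = C (1 - p)^alpha * Y0` by ordinary least squares on the
#' log-linear form `log(Y / Y0) = log(C) + alpha * log(1 - p)`.
#'
#' @param p Porosities in (0, 1).
#' @param Y Yield strengths in MPa (> 0).
#' @param Y0 Constituent material strength in MPa.
#' @return List with `C`, `alpha`, `Y0` and `residual` (sum of squared
#'   log-residuals), class `gibson_ashby_fit`.
#' @export
fit_gibson_ashby <- function(p, Y, Y0 = 120) {
  if (length(p) != length(Y)) stop("p and Y lengths differ")
  if (length(p) < 3) stop("need at least 3 points")
  if (any(p <= 0) || any(p >= 1)) stop("porosities must lie in (0, 1)")
  if (any(Y <= 0)) stop("strengths must be positive")
  x <- log(1 - p)
  if (stats::var(x) == 0) stop("all porosities equal: scaling fit is rank-deficient")
  y <- log(Y / Y0)
  fit <- stats::lm(y ~ x)
  structure(list(C = exp(unname(stats::coef(fit)[1])),
                 alpha = unname(stats::coef(fit)[2]),
                 Y0 = Y0,
                 residual = sum(stats::residuals(fit)^2)),
            class = "gibson_ashby_fit")
}

#' @export
print.gibson_ashby_fit <- function(x, ...) {
  cat(sprintf("Gibson-Ashby fit: Y = %.4g (1 - p)^%.4g x %.4g MPa (SS log-residual %.3g)\n",
              x$C, x$alpha, x$Y0, x$residual))
  invisible(x)
}

#' Analytic oracle specification
#'
#' Constituent constants default to the calibrated compression-simulation
#' material values (modulus 5 GPa, strength 120 MPa). The modulus exponent
#' follows the classic quadratic Gibson-Ashby scaling and the strength
#' exponent the fitted value for heterogeneous designs; `lambda` is the
#' relative strength gain per unit of face-center solid fraction.
#'
#' @param E0 Constituent elastic modulus in MPa.
#' @param Y0 Constituent yield strength in MPa.
#' @param modulus_exponent Exponent of (1 - p) in the per-subunit modulus.
#' @param strength_exponent Exponent of (1 - p) in the per-subunit strength.
#' @param lambda Face-center reinforcement gain.
#' @param load_axis Compression axis: "x", "y" or "z".
#' @return An object of class `oracle_spec`.
#' @export
oracle_spec <- function(E0 = 5000, Y0 = 120, modulus_exponent = 2.0,
                        strength_exponent = 2.1, lambda = 0.1,
                        load_axis = c("z", "x", "y")) {
  load_axis <- match.arg(load_axis)
  stopifnot(E0 > 0, Y0 > 0, modulus_exponent > 0, strength_exponent > 0,
            lambda >= 0)
  structure(list(E0 = E0, Y0 = Y0, modulus_exponent = modulus_exponent,
                 strength_exponent = strength_exponent, lambda = lambda,
                 load_axis = load_axis),
            class = "oracle_spec")
}

# indices (as an s^3 logical array counted with multiplicity) of the
# subunits nearest the six face centers; odd s gives 1 subunit per face,
# even s the 4 tied nearest.
.face_center_index <- function(s) {
  ctr <- (s + 1) / 2
  near <- which(abs(seq_len(s) - ctr) == min(abs(seq_len(s) - ctr)))
  idx <- matrix(0L, nrow = 0, ncol = 3)
  for (axis in 1:3) for (side in c(1L, s)) {
    others <- expand.grid(near, near)
    block <- matrix(0L, nrow(others), 3)
    block[, axis] <- side
    block[, setdiff(1:3, axis)] <- as.matrix(others)
    idx <- rbind(idx, block)
  }
  idx
}

#' Analytic mechanics oracle for a porosity matrix
#'
#' Deterministic closed-form labels standing in for a calibrated compression
#' simulation. With per-subunit solid fraction `1 - p`:
#' * per-subunit modulus `e = E0 (1 - p)^q`;
#' * each load-axis column of `s` subunits contributes the series stiffness
#'   `s / sum(1/e)`; the scaffold modulus E is the mean over the `s^2`
#'   columns;
#' * each transverse layer has strength `mean(Y0 (1 - p)^r)` over its `s^2`
#'   subunits; the scaffold strength is the weakest layer times a
#'   face-center reinforcement `1 + lambda * fc`, where `fc` is the mean
#'   solid fraction over the subunits nearest the six face centers.
#'
#' @param m A [porosity_matrix()] (any cubic shape).
#' @param spec An [oracle_spec()].
#' @param curve If `TRUE`, also return an idealised bilinear stress-strain
#'   curve with modulus E and plateau Y.
#' @return List with `E` (MPa), `Y` (MPa), `mass_fraction` (mean solid
#'   fraction of the design), and optionally `curve`.
#' @export
#' @examples
#' synthetic_oracle(porosity_matrix(array(0.5, c(3, 3, 3))))$E  # 1250
synthetic_oracle <- function(m, spec = oracle_spec(), curve = FALSE) {
  m <- as_porosity_matrix(m)
  p <- unclass(m)
  s <- dim(p)[1]
  ax <- match(spec$load_axis, c("x", "y", "z"))
  if (ax != 3) p <- aperm(p, switch(ax, c(3, 2, 1), c(1, 3, 2), c(1, 2, 3)))
  e <- spec$E0 * (1 - p)^spec$modulus_exponent
  col_stiff <- s / apply(1 / e, c(1, 2), sum)
  E <- mean(col_stiff)
  str_unit <- spec$Y0 * (1 - p)^spec$strength_exponent
  layer_strength <- apply(str_unit, 3, mean)
  fc_idx <- .face_center_index(s)
  fc <- mean(1 - p[fc_idx])
  Y <- min(layer_strength) * (1 + spec$lambda * fc)
  out <- list(E = E, Y = Y, mass_fraction = mean(1 - p))
  if (curve) out$curve <- bilinear_curve(E, Y)
  out
}

#' Build an oracle function from a specification
#'
#' Returns a closure `function(m) -> list(E, Y, mass_fraction)` wrapping
#' [synthetic_oracle()]; the common interface consumed by the active
#' learning loop, so an external solver adapter ([command_oracle()]) can be
#' swapped in.
#'
#' @param spec An [oracle_spec()].
#' @return An oracle function.
#' @export
analytic_oracle <- function(spec = oracle_spec()) {
  force(spec)
  function(m) synthetic_oracle(m, spec)
}

#' External-command oracle adapter
#'
#' Adapts an external mechanics solver to the oracle interface: the design
#' is written as a porosity CSV, the command is run with the input and
#' output paths substituted for `{input}` and `{output}`, and the resulting
#' two-column stress-strain CSV (strain, stress_MPa) is post-processed with
#' [elastic_modulus()] and [offset_yield()].
#'
#' @param command Command template containing `{input}` and `{output}`.
#' @return An oracle function `function(m) -> list(E, Y, mass_fraction)`.
#' @export
command_oracle <- function(command) {
  force(command)
  function(m) {
    m <- as_porosity_matrix(m)
    fin <- tempfile(fileext = ".csv")
    fout <- tempfile(fileext = ".csv")
    on.exit(unlink(c(fin, fout)))
    write_porosity_csv(m, fin)
    cmd <- gsub("{output}", fout, gsub("{input}", fin, command, fixed = TRUE),
                fixed = TRUE)
    status <- system(cmd)
    if (status != 0) stop(sprintf("oracle command failed (exit %d): %s", status, cmd))
    crv <- read_curve_csv(fout)
    E <- as.numeric(elastic_modulus(crv))
    list(E = E, Y = offset_yield(crv, E),
         mass_fraction = 1 - mean(unclass(m)))
  }
}

#' Read / write stress-strain curves as two-column CSV
#'
#' @param path CSV path with columns `strain`, `stress_MPa`.
#' @return A [stress_strain_curve()].
#' @export
read_curve_csv <- function(path) {
  d <- utils::read.csv(path)
  stress_strain_curve(d[[1]], d[[2]])
}

#' @rdname read_curve_csv
#' @param curve A [stress_strain_curve()].
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(data.frame(strain = curve$strain, stress_MPa = curve$stress),
                   path, row.names = FALSE)
  invisible(path)
}
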