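# Unlabeled porosity-matrix corpus generation for autoencoder training.
# Four arrangement families are used: a core/shell 'central' grading, layer
# gradings along z ('vertical') or along x/y ('horizontal'), and fully
# 'random' matrices.

.arrangement_kinds <- c("central", "vertical", "horizontal", "random")

#' Corpus specification for unlabeled porosity matrices
#'
#' @param n_per_interval Matrices generated per mean-porosity interval.
#' @param shapes Subset of c(2, 3, 4): matrix edges to generate.
#' @param ladder Admissible porosity ladder (see [porosity_ladder()]).
#' @param intervals Matrix with columns lo, hi: mean-porosity bins.
#' @param seed Integer seed making generation bit-reproducible.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_per_interval = 3000, shapes = c(2, 3, 4),
                        ladder = porosity_ladder(),
                        intervals = NULL, seed = 1L) {
  stopifnot(n_per_interval > 0, all(shapes %in% c(2, 3, 4)))
  if (is.null(intervals)) {
    lo <- seq(0.2, 0.8, by = 0.1)
    intervals <- cbind(lo = lo, hi = lo + 0.1)
  }
  structure(list(n_per_interval = as.integer(n_per_interval),
                 shapes = as.integer(shapes), ladder = ladder,
                 intervals = intervals, seed = as.integer(seed)),
            class = "corpus_spec")
}

# draw one ladder value biased towards `mu`; the soft-window width scales
# with the ladder spacing so coarse and fine ladders mix values comparably
.draw_near <- function(ladder, mu, n = 1, tau = NULL) {
  if (is.null(tau))
    tau <- 0.8 * if (length(ladder) > 1) stats::median(diff(ladder)) else 0.1
  w <- exp(-abs(ladder - mu) / tau)
  ladder[sample.int(length(ladder), n, replace = TRUE, prob = w)]
}

#' Generate one porosity matrix of a given arrangement family
#'
#' * `central`: two ladder values, a core (subunits nearest the scaffold
#'   center by Chebyshev distance) and a shell (the rest).
#' * `vertical`: one ladder value per z-layer.
#' * `horizontal`: one ladder value per x- or y-layer (axis drawn at random).
#' * `random`: i.i.d. ladder values per subunit.
#'
#' Uses the R random number generator: seed with [set.seed()] for
#' reproducibility.
#'
#' @param kind One of `"central"`, `"vertical"`, `"horizontal"`, `"random"`.
#' @param shape Matrix edge (2, 3 or 4).
#' @param ladder Admissible porosity values.
#' @param mu Optional target mean porosity biasing the draws.
#' @return A [porosity_matrix()] with `discrete = TRUE`.
#' @export
generate_matrix <- function(kind = .arrangement_kinds, shape = 3,
                            ladder = porosity_ladder(), mu = NULL) {
  kind <- match.arg(kind)
  stopifnot(shape %in% c(2, 3, 4), length(ladder) >= 1)
  if (length(ladder) == 0) stop("empty porosity ladder")
  draw <- function(n) {
    if (is.null(mu)) ladder[sample.int(length(ladder), n, replace = TRUE)]
    else .draw_near(ladder, mu, n)
  }
  s <- as.integer(shape)
  vals <- switch(kind,
    central = {
      ctr <- (s + 1) / 2
      d <- abs(slice.index(array(0, c(s, s, s)), 1) - ctr)
      d <- pmax(d, abs(slice.index(array(0, c(s, s, s)), 2) - ctr))
      d <- pmax(d, abs(slice.index(array(0, c(s, s, s)), 3) - ctr))
      cs <- draw(2)
      ifelse(d <= min(d), cs[1], cs[2])
    },
    vertical = {
      lay <- draw(s)
      array(rep(lay, each = s * s), c(s, s, s))
    },
    horizontal = {
      lay <- draw(s)
      if (sample.int(2, 1) == 1) {
        array(rep(lay, times = s * s), c(s, s, s))        # x-layers
      } else {
        array(rep(rep(lay, each = s), times = s), c(s, s, s))  # y-layers
      }
    },
    random = array(draw(s^3), c(s, s, s))
  )
  porosity_matrix(array(vals, c(s, s, s)), discrete = TRUE)
}

#' Generate the unlabeled corpus of expanded porosity matrices
#'
#' For each mean-porosity interval, `n_per_interval` matrices are drawn with
#' arrangement kinds and shapes cycled evenly, accepted only if their mean
#' porosity falls inside the interval, expanded to 12^3 via
#' [expand_matrix()], and deduplicated by exact equality.
#'
#' @param spec A [corpus_spec()].
#' @return A list with `arrays` (a 1728 x n matrix, one flattened 12^3 array
#'   per column) and `manifest` (data.frame: kind, shape, mean_porosity,
#'   interval).
#' @export
#' @examples
#' cc <- generate_corpus(corpus_spec(n_per_interval = 5, seed = 7))
#' dim(cc$arrays)
generate_corpus <- function(spec = corpus_spec()) {
  set.seed(spec$seed)
  cols <- list()
  kind_v <- character(0)
  shape_v <- integer(0)
  meanp_v <- numeric(0)
  intv_v <- character(0)
  seen <- new.env(parent = emptyenv())
  ki <- 0L
  si <- 0L
  for (b in seq_len(nrow(spec$intervals))) {
    lo <- spec$intervals[b, 1]
    hi <- spec$intervals[b, 2]
    closed_hi <- b == nrow(spec$intervals)
    for (j in seq_len(spec$n_per_interval)) {
      kind <- .arrangement_kinds[ki %% 4L + 1L]
      ki <- ki + 1L
      shape <- spec$shapes[si %% length(spec$shapes) + 1L]
      si <- si + 1L
      m <- NULL
      key <- NULL
      for (try in seq_len(200)) {
        mu <- stats::runif(1, lo, hi)
        cand <- generate_matrix(kind, shape, spec$ladder, mu = mu)
        mp <- mean(cand)
        ok <- mp >= lo && (mp < hi || (closed_hi && mp <= hi + 1e-12))
        if (!ok) next
        k <- paste(round(as.vector(cand) * 10), collapse = "")
        if (!is.null(seen[[k]])) next  # duplicate: redraw
        m <- cand
        key <- k
        break
      }
      if (is.null(m)) next  # family exhausted for this interval
      seen[[key]] <- TRUE
      cols[[length(cols) + 1L]] <- as.vector(expand_matrix(m))
      kind_v <- c(kind_v, kind)
      shape_v <- c(shape_v, shape)
      meanp_v <- c(meanp_v, mean(m))
      intv_v <- c(intv_v, sprintf("[%.1f,%.1f%s", lo, hi, if (closed_hi) "]" else ")"))
    }
  }
  if (length(cols) == 0) stop("corpus generation produced no matrices")
  list(arrays = matrix(unlist(cols), nrow = 1728),
       manifest = data.frame(kind = kind_v, shape = shape_v,
                             mean_porosity = meanp_v, interval = intv_v,
                             stringsAsFactors = FALSE))
}

#' Write a corpus manifest as CSV
#'
#' @param corpus Result of [generate_corpus()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_corpus_manifest <- function(corpus, path) {
  utils::write.csv(corpus$manifest, path, row.names = FALSE)
  invisible(path)
}
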