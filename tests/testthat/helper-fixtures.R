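# Shared fixtures, built lazily and cached for the whole test run.
# Expensive objects (trained models, labeled design sets) are computed once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  got <- .fixtures[[name]]
  if (!is.null(got)) return(got)
  val <- builder()
  .fixtures[[name]] <- val
  val
}

# small geometry for fast voxel work in unit tests (24^3 grids)
small_geometry <- function() unit_cell_spec(voxels_per_unit = 8)

# toy landscape study conditions: 2^3 designs on a 3-level ladder,
# compressed to 16^3 voxel grids; target modulus = uniform p = 0.6
toy_ladder <- function() c(0.3, 0.6, 0.9)

toy_geometry <- function() unit_cell_spec(cells_per_axis = 2,
                                          voxels_per_unit = 8)

toy_oracle_spec <- function() oracle_spec()

toy_E_target <- function() {
  synthetic_oracle(porosity_matrix(array(0.6, c(2, 2, 2))),
                   toy_oracle_spec())$E
}

toy_constraints <- function() {
  golden <- golden_criterion(toy_E_target(), toy_oracle_spec(), shape = 2)
  mall_constraints(E_target = toy_E_target(),
                   mass_criterion = golden$mass_fraction)
}

toy_config <- function(seed = 1) {
  mall_config(
    shape = 2, ladder = toy_ladder(), geometry = toy_geometry(),
    oracle_spec_ = toy_oracle_spec(),
    constraints = toy_constraints(),
    stopping = stopping_rule(margin = 0.3, patience = 8, max_rounds = 8),
    cae_spec_ = cae_spec(epochs = 50, seed = 42),
    surrogate_spec_ = surrogate_spec(epochs = 10, lr = 2e-3, seed = 42,
                                     val_frac = 0),
    corpus_spec_ = corpus_spec(n_per_interval = 240, shapes = 2,
                               ladder = toy_ladder(), seed = 42),
    n_samples = 2000, k = 6, n_initial = 60, seed = seed,
    grid_cache = fixture("toy_grid_cache",
                         function() new.env(parent = emptyenv())))
}

# toy generative models (CAE + GMM), trained once and shared across seeds
toy_generative <- function() {
  fixture("toy_generative", function() {
    suppressWarnings(prepare_generative(toy_config(seed = 1)))
  })
}

toy_config_with_models <- function(seed = 1) {
  base <- toy_generative()
  cfg <- toy_config(seed = seed)
  cfg$cae <- base$cae
  cfg$gmm <- base$gmm
  cfg
}

toy_brute_force <- function() {
  fixture("toy_brute_force", function() {
    brute_force_optimum(toy_constraints(), toy_oracle_spec(), shape = 2,
                        ladder = toy_ladder())
  })
}

# a small labeled design set on 24^3 grids for surrogate unit tests
small_labeled_set <- function() {
  fixture("small_labeled_set", function() {
    set.seed(99)
    kinds <- c("central", "vertical", "horizontal", "random")
    mats <- lapply(seq_len(150), function(i)
      generate_matrix(kinds[(i - 1) %% 4 + 1], 3))
    geo <- small_geometry()
    grids <- matrix(0, grid_edge(geo)^3, length(mats))
    for (i in seq_along(mats)) grids[, i] <- as.numeric(voxelize(mats[[i]], geo))
    osp <- oracle_spec()
    list(mats = mats, grids = grids, geo = geo,
         E = vapply(mats, function(m) synthetic_oracle(m, osp)$E, numeric(1)),
         Y = vapply(mats, function(m) synthetic_oracle(m, osp)$Y, numeric(1)))
  })
}

# mid-sized mixed corpus used by the autoencoder tests
corpus_500 <- function() {
  fixture("corpus_500", function() {
    generate_corpus(corpus_spec(n_per_interval = 75, seed = 11))
  })
}

cae_500 <- function() {
  fixture("cae_500", function() {
    suppressWarnings(train_cae(corpus_500(), cae_spec()))
  })
}
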