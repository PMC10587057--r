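test_that("arrangement families have their defining structure", {
  set.seed(3)
  for (i in 1:20) {
    m <- generate_matrix("central", 3)
    shell <- unclass(m)
    core <- shell[2, 2, 2]
    expect_true(all(shell[-14] == shell[1]))  # 26 shell entries share a value
    expect_s3_class(m, "porosity_matrix")

    v <- generate_matrix("vertical", 3)
    for (k in 1:3) expect_equal(length(unique(as.vector(v[, , k]))), 1L)
    expect_lte(length(unique(as.vector(v))), 3L)

    h <- generate_matrix("horizontal", 3)
    layers_x <- apply(h, 1, function(s) length(unique(as.vector(s))))
    layers_y <- apply(h, 2, function(s) length(unique(as.vector(s))))
    expect_true(all(layers_x == 1) || all(layers_y == 1))

    r <- generate_matrix("random", 2)
    expect_true(all(as.vector(r) %in% porosity_ladder()))
  }
})

test_that("central arrangement puts the chosen core value at the center", {
  found_distinct <- FALSE
  set.seed(11)
  for (i in 1:50) {
    m <- generate_matrix("central", 3)
    if (m[2, 2, 2] != m[1, 1, 1]) found_distinct <- TRUE
  }
  expect_true(found_distinct)
})

test_that("matrix generation is deterministic under a fixed seed", {
  set.seed(123)
  a <- generate_matrix("random", 3)
  set.seed(123)
  b <- generate_matrix("random", 3)
  expect_identical(a, b)
})

test_that("corpus generation respects intervals, shapes and validation", {
  spec <- corpus_spec(n_per_interval = 10, shapes = c(2, 3), seed = 5,
                      intervals = cbind(lo = c(0.4, 0.5), hi = c(0.5, 0.6)))
  cc <- generate_corpus(spec)
  expect_lte(ncol(cc$arrays), 20)
  expect_equal(nrow(cc$arrays), 1728)
  expect_true(all(cc$arrays >= 0.2 & cc$arrays <= 0.9))
  first <- cc$manifest$interval == "[0.4,0.5)"
  expect_true(all(cc$manifest$mean_porosity[first] >= 0.4))
  expect_true(all(cc$manifest$mean_porosity[first] < 0.5))
  # every array passes porosity-matrix validation after contraction
  for (i in seq_len(ncol(cc$arrays))) {
    s <- cc$manifest$shape[i]
    a <- array(cc$arrays[, i], c(12, 12, 12))
    expect_s3_class(porosity_matrix(contract_matrix(a, s), discrete = TRUE),
                    "porosity_matrix")
  }
})

test_that("corpus kinds are cycled evenly and output is reproducible", {
  spec <- corpus_spec(n_per_interval = 8, shapes = 3, seed = 21,
                      intervals = cbind(lo = c(0.4, 0.6), hi = c(0.5, 0.7)))
  cc <- generate_corpus(spec)
  counts <- table(cc$manifest$kind)
  expect_lte(diff(range(counts)), 1)
  cc2 <- generate_corpus(spec)
  expect_identical(cc$arrays, cc2$arrays)
  expect_identical(cc$manifest, cc2$manifest)
  # duplicates removed by exact equality
  keys <- apply(cc$arrays, 2, paste, collapse = ",")
  expect_false(any(duplicated(keys)))
})
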