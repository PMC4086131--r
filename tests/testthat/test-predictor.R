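make_separable <- function(n = 100, seed = 1, gap = 2) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- cbind(stats::rnorm(n) + gap * (y == 1), stats::rnorm(n))
  list(X = X, y = y)
}

test_that("feature assembly is deterministic with fixed schema length", {
  aln <- make_msa(30, 12, conserved_positions = c(3, 4), seed = 2)
  track <- conservation_track(aln)
  qs <- strsplit(aln$query_seq, "")[[1]]
  v <- new_variant(qs[3], 3, if (qs[3] == "A") "C" else "A")
  x1 <- assemble_features(v, track)
  x2 <- assemble_features(v, track)
  expect_identical(x1, x2)
  expect_equal(length(x1), length(feature_schema()$names))
  expect_identical(names(x1), feature_schema()$names)
  # identity variant without structure: unit mass ratio, sentinels, flags
  vid <- new_variant(qs[5], 5, qs[5])
  xid <- assemble_features(vid, track)
  expect_equal(unname(xid["mass_ratio"]), 1)
  expect_equal(unname(xid["functional_group_change"]), 0)
  expect_equal(unname(xid["structure_missing"]), 1)
  expect_equal(unname(xid["ligand_distance"]), MISSING_SENTINEL)
  # conservation missing at position -> hard error
  expect_error(assemble_features(new_variant("A", 999, "C"), track),
               "no conservation score")
})

test_that("a separable problem trains to validation accuracy 1", {
  d <- make_separable(200, seed = 3, gap = 6)
  m <- train_member(d$X[1:100, ], d$y[1:100], d$X[101:200, ], d$y[101:200])
  expect_equal(m$validation_accuracy, 1.0)
  expect_lt(m$platt$A, 0)  # probability increases with the decision value
  expect_error(train_member(d$X[1:4, ], rep(1, 4), d$X[5:8, ], d$y[5:8]),
               "single label")
})

test_that("permuted labels give chance-level validation accuracy", {
  set.seed(9)
  n <- 200
  X <- matrix(stats::rnorm(n * 4), n)
  y <- sample(rep(c(0L, 1L), n / 2))   # labels independent of X
  m <- train_member(X[1:100, ], y[1:100], X[101:200, ], y[101:200])
  expect_lt(abs(m$validation_accuracy - 0.5), 0.15)
})

test_that("Platt calibration matches an independent gradient-descent fit", {
  # symmetric case: B ~ 0
  f <- c(-2, -1, 1, 2)
  y <- c(0, 0, 1, 1)
  p <- fit_platt(f, y)
  expect_lt(abs(p$B), 1e-4)
  o <- oracle_platt(f, y)
  expect_lt(abs(p$A - o$A), 1e-4)
  expect_lt(abs(p$B - o$B), 1e-4)
  # random validation sets
  set.seed(14)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    y <- stats::rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    f <- stats::rnorm(n) + 1.2 * (y == 1)
    p <- fit_platt(f, y)
    o <- oracle_platt(f, y)
    expect_lt(abs(p$A - o$A), 1e-4)
    expect_lt(abs(p$B - o$B), 1e-4)
    # monotonicity when A < 0
    if (p$A < 0) {
      probs <- platt_probability(p, sort(stats::rnorm(20)))
      expect_true(all(diff(probs) > 0))
    }
  }
})

test_that("probability combination is the stated convex combination", {
  expect_equal(combine_probabilities(matrix(0.7, 1, 5), rep(0.2, 5)), 0.7)
  expect_equal(combine_probabilities(matrix(c(1, 0, 0, 0, 0), 1), rep(1, 5)),
               0.2)
  accs <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  w <- accs / sum(accs)
  expect_equal(w, c(0.2571428571, 0.2285714286, 0.2, 0.1714285714,
                    0.1428571429), tolerance = 1e-9)
  expect_lt(abs(sum(w) - 1), 1e-12)
  # convexity on random member probabilities
  set.seed(2)
  for (i in 1:50) {
    p <- stats::runif(5)
    wts <- stats::runif(5)
    comb <- combine_probabilities(matrix(p, 1), wts)
    expect_gte(comb, min(p) - 1e-12)
    expect_lte(comb, max(p) + 1e-12)
  }
})

test_that("grid optimisation selects by accuracy with stated tie-breaks", {
  d <- make_separable(150, seed = 4, gap = 6)
  folds <- rep(1:5, length.out = 150)
  # single grid point: selected everywhere
  g1 <- grid_optimise(d$X, d$y, folds, C_grid = 0.5, j_grid = 2)
  expect_equal(g1$C, rep(0.5, 5))
  expect_equal(g1$j, rep(2, 5))
  # equal accuracy (fully separable at both C): smaller C wins, j nearest 1
  g2 <- grid_optimise(d$X, d$y, folds, C_grid = c(10, 0.1),
                      j_grid = c(4, 1))
  expect_true(all(g2$validation_accuracy == 1))
  expect_equal(g2$C, rep(0.1, 5))
  expect_equal(g2$j, rep(1, 5))
})

test_that("ensembles train, persist and predict deterministically", {
  spec <- fixture_spec(n_proteins = 12L, variants_per_protein = 8L,
                       protein_length = 40L, msa_depth = 15L,
                       fraction_with_structure = 0.5, seed = 5L)
  ds <- make_labelled_dataset(spec)
  X <- feature_matrix(ds$labelled, ds$msas, ds$structures, ds$sites)
  model <- train_ensemble(ds$labelled, X, seed = 5L, C_grid = c(0.1, 1),
                          j_grid = 1)
  expect_length(model$members, 5L)
  expect_lt(abs(sum(model$weights) - 1), 1e-12)
  p1 <- predict_ensemble(model, X)
  p2 <- predict_ensemble(model, X)
  expect_identical(p1, p2)
  expect_true(all(p1$probability >= 0 & p1$probability <= 1))
  # per-member convexity of the final probability
  members <- as.matrix(p1[, paste0("member_", 1:5)])
  expect_true(all(p1$probability >= apply(members, 1, min) - 1e-12))
  expect_true(all(p1$probability <= apply(members, 1, max) + 1e-12))
  # JSON round trip reproduces predictions bitwise-closely
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  p3 <- predict_ensemble(back, X)
  expect_equal(p3$probability, p1$probability, tolerance = 1e-12)
  # schema guard
  back$schema_version <- "0"
  expect_error(predict_ensemble(back, X), "schema")
})

test_that("end-to-end prediction ranks a pathogenic profile above a neutral one", {
  spec <- fixture_spec(n_proteins = 15L, variants_per_protein = 10L,
                       protein_length = 50L, msa_depth = 20L,
                       effect_size = 4, seed = 8L)
  ds <- make_labelled_dataset(spec)
  X <- feature_matrix(ds$labelled, ds$msas, ds$structures, ds$sites)
  model <- train_ensemble(ds$labelled, X, seed = 8L, C_grid = 1,
                          j_grid = 1)
  # strongly pathogenic profile: conserved, in-site, charge flip
  pid <- names(which(!vapply(ds$structures, is.null, TRUE)))[1]
  aln <- ds$msas[[pid]]
  qs <- strsplit(aln$query_seq, "")[[1]]
  lig <- Filter(function(s) s$site_type == "ligand", ds$sites[[pid]])[[1]]
  hot_pos <- lig$positions[1]
  hot_mut <- if (qs[hot_pos] %in% c("K", "R", "H")) "E" else "K"
  track <- conservation_track(aln)
  cold_pos <- track$position[order(track$score)][1]
  if (cold_pos == hot_pos) cold_pos <- track$position[order(track$score)][2]
  cold_mut <- setdiff(AA_ALPHABET, qs[cold_pos])[1]
  res <- varmod_predict(
    model, aln,
    list(new_variant(qs[hot_pos], hot_pos, hot_mut),
         new_variant(qs[cold_pos], cold_pos, cold_mut)),
    structure = ds$structures[[pid]], sites = ds$sites[[pid]])
  expect_true(all(res$valid))
  expect_gt(res$probability[1], res$probability[2])
  # empty variant list -> empty output
  empty <- varmod_predict(model, aln, list(),
                          structure = ds$structures[[pid]],
                          sites = ds$sites[[pid]])
  expect_equal(nrow(empty), 0L)
})
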