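toy_instance <- function(seed, n = 6, m = 5, k = 3) {
  set.seed(seed)
  assoc <- labeled_matrix(matrix(rbinom(n * m, 1, 0.3), n, m),
                          paste0("d", 1:n), paste0("e", 1:m))
  preds <- lapply(seq_len(k), function(i)
    labeled_matrix(matrix(runif(n * m), n, m), rownames(assoc),
                   colnames(assoc)))
  names(preds) <- paste0("src", seq_len(k))
  list(assoc = assoc, preds = preds)
}

# Variant whose penalty coefficients are positive by construction: sources
# score positives around 0.5 and negatives near 0, so the s=1 residual sum
# dominates the s=0 sum.
toy_instance_posc <- function(seed, n = 10, m = 8, k = 3) {
  set.seed(seed)
  assoc <- labeled_matrix(matrix(rbinom(n * m, 1, 0.3), n, m),
                          paste0("d", 1:n), paste0("e", 1:m))
  preds <- lapply(seq_len(k), function(i) {
    p <- 0.4 * assoc + matrix(runif(n * m, 0, 0.2), n, m)
    labeled_matrix(p, rownames(assoc), colnames(assoc))
  })
  names(preds) <- paste0("src", seq_len(k))
  list(assoc = assoc, preds = preds)
}

test_that("objective matches hand evaluation and the loop oracle", {
  assoc <- labeled_matrix(rbind(d = c(1, 0)), col_labels = c("e1", "e2"))
  pred <- labeled_matrix(rbind(d = c(0.5, 0)), col_labels = c("e1", "e2"))
  # one s=1 cell at P=0.5 and one s=0 cell at P=0, beta = 1
  expect_equal(fusion_objective(1, assoc, list(pred)), 0.25)
  # exact-fit source: both sums vanish
  expect_equal(fusion_objective(1, assoc, list(assoc)), 0)
  # quadratic form: doubling beta quadruples the term
  expect_equal(fusion_objective(2, assoc, list(pred)),
               4 * fusion_objective(1, assoc, list(pred)))
  # marked cells belong to neither stratum
  assoc2 <- assoc; assoc2[1, 2] <- -1
  pred2 <- pred; pred2[1, 2] <- 0.9
  expect_equal(fusion_objective(1, assoc2, list(pred2)), 0.25)
  for (seed in 1:3) {
    inst <- toy_instance(seed)
    beta <- c(0.2, 0.3, 0.5)
    expect_equal(fusion_objective(beta, inst$assoc, inst$preds),
                 oracle_objective(beta, inst$assoc, inst$preds))
  }
})

test_that("fuse_predictions is the weighted elementwise sum", {
  inst <- toy_instance(1)
  p <- inst$preds
  p[[1]][1, 1] <- 1; p[[2]][1, 1] <- 0; p[[3]][1, 1] <- 1
  fused <- fuse_predictions(p, c(0.5, 0.3, 0.2))
  expect_equal(fused[1, 1], 0.7)
  # identical sources are a fixed point
  same <- list(p[[1]], p[[1]], p[[1]])
  expect_equal(fuse_predictions(same, c(0.2, 0.3, 0.5)), p[[1]])
  # beta -> (1, 0, 0) limit recovers the first source
  eps <- 1e-9
  expect_equal(fuse_predictions(p, c(1 - 2 * eps, eps, eps)), p[[1]],
               tolerance = 1e-6)
  expect_error(fuse_predictions(p, c(0.5, 0.5)), "length")
})

test_that("simple average fusion equals fuse with uniform weights", {
  inst <- toy_instance(2)
  expect_equal(simple_average_fuse(inst$preds),
               fuse_predictions(inst$preds, rep(1 / 3, 3)))
  expect_equal(simple_average_fuse(inst$preds[1]), inst$preds[[1]])
  a <- inst$preds[[1]]; a[] <- 0
  b <- a; b[] <- 1
  expect_true(all(simple_average_fuse(list(a, b)) == 0.5))
  expect_error(simple_average_fuse(list()), "no sources")
})

test_that("optimized weights satisfy the constraints and beat uniform", {
  for (seed in 1:5) {
    inst <- toy_instance(seed, n = 10, m = 8)
    w <- suppressWarnings(optimize_weights(inst$assoc, inst$preds))
    expect_equal(sum(w$weights), 1, tolerance = 1e-6)
    expect_true(all(w$weights >= 1e-4 - 1e-12))
    expect_lte(w$value + 1e-9,
               fusion_objective(rep(1 / 3, 3), inst$assoc, inst$preds) + 1e-9)
  }
})

test_that("identical sources get uniform weights; smaller penalty gets more", {
  inst <- toy_instance_posc(3)
  same <- list(a = inst$preds[[1]], b = inst$preds[[1]], c = inst$preds[[1]])
  w <- optimize_weights(inst$assoc, same)
  expect_equal(unname(w$weights), rep(1 / 3, 3), tolerance = 1e-6)

  # all-positive coefficients: closed form beta_k ~ 1/c_k, c1 > c2 -> b2 > b1
  inst2 <- toy_instance_posc(7, n = 12, m = 10, k = 2)
  cc <- fusion_coefficients(inst2$assoc, inst2$preds)
  expect_true(all(cc > 0))
  w2 <- optimize_weights(inst2$assoc, inst2$preds)
  expect_equal(unname(w2$weights), unname((1 / cc) / sum(1 / cc)),
               tolerance = 1e-6)
  expect_equal(order(w2$weights), order(-cc))
})

test_that("optimizer agrees with the simplex grid-search oracle", {
  for (seed in 1:4) {
    inst <- toy_instance(seed + 20, n = 8, m = 6)
    cc <- fusion_coefficients(inst$assoc, inst$preds)
    w <- suppressWarnings(optimize_weights(inst$assoc, inst$preds))
    grid <- oracle_grid_weights(cc, step = 0.01)
    expect_lte(w$value, grid$value + 1e-9)
    if (all(cc > 0))
      expect_equal(unname(w$weights), grid$weights, tolerance = 0.011)
  }
})

test_that("an exact source plus a noise source: exact source dominates", {
  # the noise source scores like a typical predictor (bounded, mostly small)
  # but carries no signal; its coefficient is positive while the exact
  # source's is 0, so weight flows to the exact source
  inst <- toy_instance(9, n = 10, m = 8, k = 1)
  perfect <- inst$assoc
  set.seed(99)
  noise <- labeled_matrix(matrix(runif(80, 0, 0.3), 10, 8), rownames(perfect),
                          colnames(perfect))
  w <- suppressWarnings(
    optimize_weights(inst$assoc, list(perfect = perfect, noise = noise)))
  expect_gt(w$weights[["perfect"]], w$weights[["noise"]])
  # grid-oracle cross-check on the two-source slice
  cc <- fusion_coefficients(inst$assoc, list(perfect, noise))
  b1 <- seq(0.01, 0.99, by = 0.01)
  vals <- b1^2 * cc[1] + (1 - b1)^2 * cc[2]
  expect_gt(b1[which.min(vals)], 0.5)
})

test_that("a label-shuffled source receives the smallest of three weights", {
  s <- tiny_triple(seed = 16)
  marked <- mark_side_effects(s$assoc, s$side_effects)
  enc <- encode(fit_autoencoder(build_autoencoder(
    fast_encoder(ncol(s$features), seed = 16)), s$features), s$features)
  preds <- predict_sources(marked, enc, s$side_effects, 5)
  smallest <- vapply(1:6, function(seed) {
    set.seed(seed)
    shuffled <- preds$side
    shuffled[] <- sample(shuffled)
    three <- list(feature = preds$feature, side = preds$side,
                  shuffled = shuffled)
    cc <- fusion_coefficients(marked, three)
    w <- suppressWarnings(optimize_weights(marked, three))
    names(which.min(w$weights))
  }, "")
  expect_true(all(smallest == "shuffled"))
})

test_that("degenerate fusion inputs error", {
  inst <- toy_instance(4)
  expect_error(optimize_weights(inst$assoc, inst$preds[1]), "two sources")
  expect_error(optimize_weights(inst$assoc, inst$preds, epsilon = 0.5),
               "epsilon")
  bad <- inst$preds
  bad[[2]] <- bad[[2]][1:3, ]
  expect_error(fusion_objective(c(.3, .3, .4), inst$assoc, bad), "shape")
})
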