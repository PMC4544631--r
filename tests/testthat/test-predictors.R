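sim_xy <- function(n = 60, p = 120, n_qtl = 20, h2 = 0.8, seed = 1) {
  tp <- toy_population(n_markers = p, n_parents = 20,
                       n_crosses = ceiling(n / 5), lines_per_cross = 5:5,
                       seed = seed)
  pop <- tp$pop[seq_len(min(n, nrow(tp$pop))), ]
  poly <- colnames(pop)[apply(unclass(pop), 2, sd) > 0]
  arch <- draw_architecture(poly, n_qtl = min(n_qtl, length(poly)),
                            h2 = h2, seed = seed + 1)
  y <- simulate_trait(pop, arch, seed = seed + 2)
  list(X = pop, y = as.numeric(y), g = attr(y, "genetic_value"),
       arch = arch)
}

test_that("center_markers centers on training means, not target means", {
  X <- matrix(c(1, 1, 0, 1), 2, dimnames = list(c("a", "b"), c("m1", "m2")))
  ctr <- center_markers(X)
  expect_equal(unname(ctr$X[, "m1"]), c(0, 0))
  expect_equal(unname(ctr$X[, "m2"]), c(-0.5, 0.5))
  tgt <- matrix(c(1, 1), 1, dimnames = list("t", c("m1", "m2")))
  out <- center_markers(tgt, means = ctr$col_means)
  expect_equal(unname(out$X[1, ]), c(0, 0.5))  # training means, not its own
})

test_that("ridge_rrblup matches an explicit small-system inversion", {
  X <- matrix(c(0, 1, 1,
                1, 0, 1), 3, 2,
              dimnames = list(c("l1", "l2", "l3"), c("m1", "m2")))
  y <- c(1, 2, 4)
  fit <- ridge_rrblup(X, y, lambda = 1)
  # independent oracle: explicit 2x2 inverse via the adjugate formula
  Xc <- sweep(X, 2, colMeans(X))
  A <- crossprod(Xc) + diag(2)
  inv <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2) /
    (A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
  beta_hand <- drop(inv %*% crossprod(Xc, y - mean(y)))
  expect_equal(unname(fit$marker_effects), beta_hand, tolerance = 1e-12)
  expect_equal(fit$intercept, mean(y))
  # prediction equals the hand dot-product
  tgt <- X[2, , drop = FALSE]
  expect_equal(unname(predict(fit, tgt)),
               mean(y) + sum((tgt - colMeans(X)) * beta_hand),
               tolerance = 1e-12)
})

test_that("ridge degenerates sensibly: constant y, extreme shrinkage", {
  d <- sim_xy(seed = 11)
  fit0 <- ridge_rrblup(d$X, rep(2, length(d$y)), h2 = 0.5)
  expect_true(all(abs(fit0$marker_effects) < 1e-10))
  expect_true(all(abs(predict(fit0, d$X) - 2) < 1e-10))
  # h2 -> 0+ crushes effects toward zero
  tiny <- ridge_rrblup(d$X, d$y, h2 = 1e-6)
  mid <- ridge_rrblup(d$X, d$y, h2 = 0.5)
  expect_lt(max(abs(tiny$marker_effects)), 1e-4 * max(abs(mid$marker_effects)))
  expect_error(ridge_rrblup(d$X, d$y, h2 = 1.2), "h2")
  # primal (p <= n) solution agrees with the dual kernel form
  dd <- sim_xy(n = 30, p = 80, seed = 12)
  Xs <- unclass(impute_missing(dd$X))[, 1:20]
  f1 <- ridge_rrblup(Xs, dd$y, lambda = 3)
  Xc <- scale(Xs, center = TRUE, scale = FALSE)
  yc <- dd$y - mean(dd$y)
  beta_dual <- drop(crossprod(Xc, solve(tcrossprod(Xc) + diag(3, nrow(Xc)),
                                        yc)))
  expect_equal(unname(f1$marker_effects), unname(beta_dual),
               tolerance = 1e-10)
})

test_that("linear predictors are translation-equivariant in y", {
  d <- sim_xy(seed = 13)
  for (fitter in list(
    function(y) ridge_rrblup(d$X, y, h2 = 0.5),
    function(y) bayes_ridge_gibbs(d$X, y, gibbs_config(burn_in = 200,
                                                       n_iter = 800,
                                                       seed = 5)))) {
    f1 <- fitter(d$y)
    f2 <- fitter(d$y + 10)
    expect_equal(predict(f2, d$X), predict(f1, d$X) + 10, tolerance = 0.15)
    expect_equal(f2$marker_effects, f1$marker_effects, tolerance = 0.15)
  }
})

test_that("Gibbs samplers are deterministic given the seed and kill null signal", {
  d <- sim_xy(n = 40, p = 60, seed = 14)
  cfg <- gibbs_config(burn_in = 300, n_iter = 1200, seed = 9)
  b1 <- bayes_ridge_gibbs(d$X, d$y, cfg)
  b2 <- bayes_ridge_gibbs(d$X, d$y, cfg)
  expect_identical(b1$marker_effects, b2$marker_effects)
  l1 <- bayes_lasso_gibbs(d$X, d$y, cfg)
  l2 <- bayes_lasso_gibbs(d$X, d$y, cfg)
  expect_identical(l1$marker_effects, l2$marker_effects)
  # constant y: posterior mean effects collapse to zero
  y0 <- rep(1.5, length(d$y))
  expect_lt(max(abs(bayes_ridge_gibbs(d$X, y0, cfg)$marker_effects)), 0.02)
  expect_lt(max(abs(bayes_lasso_gibbs(d$X, y0, cfg)$marker_effects)), 0.02)
  expect_error(bayes_ridge_gibbs(d$X, c(d$y[-1], NA), cfg), "finite")
})

test_that("BRR posterior means track closed-form ridge at matched shrinkage", {
  d <- sim_xy(n = 60, p = 100, n_qtl = 30, h2 = 0.7, seed = 15)
  cfg <- gibbs_config(burn_in = 1000, n_iter = 5000, seed = 2)
  b <- bayes_ridge_gibbs(d$X, d$y, cfg)
  r <- ridge_rrblup(d$X, d$y, lambda = b$diagnostics$lambda)
  expect_gt(cor(b$marker_effects, r$marker_effects), 0.97)
})

test_that("BRR posterior means match exact grid-integrated posteriors", {
  # dual-route check on a system small enough for brute-force integration:
  # marginalize beta analytically, integrate over (mu, sigma2_e, sigma2_b)
  set.seed(1)
  n <- 15
  X <- matrix(rbinom(n * 2, 1, 0.5), n,
              dimnames = list(paste0("l", 1:n), c("m1", "m2")))
  y <- 0.8 * X[, 1] - 0.5 * X[, 2] + rnorm(n, 2, 0.7)
  cfg <- gibbs_config(burn_in = 5000, n_iter = 80000, seed = 3)
  fit <- bayes_ridge_gibbs(X, y, cfg)

  Xc <- scale(X, center = TRUE, scale = FALSE)
  log_post <- function(mu, s2e, s2b) {
    V <- s2b * tcrossprod(Xc) + diag(s2e, n)
    r <- y - mu
    as.numeric(-0.5 * determinant(V)$modulus) -
      0.5 * sum(r * solve(V, r)) +
      (-(3 / 2 + 1)) * log(s2e) - 4.5 / (2 * s2e) +
      (-(3 / 2 + 1)) * log(s2b) - 0.009 / (2 * s2b)
  }
  mus <- seq(1, 4, length.out = 40)
  s2es <- exp(seq(log(0.05), log(5), length.out = 50))
  s2bs <- exp(seq(log(1e-4), log(10), length.out = 60))
  tot <- 0; bsum <- c(0, 0); musum <- 0
  for (m in mus) for (a in s2es) for (b in s2bs) {
    w <- exp(log_post(m, a, b) + log(a) + log(b))
    if (!is.finite(w) || w == 0) next
    V <- b * tcrossprod(Xc) + diag(a, n)
    bm <- b * crossprod(Xc, solve(V, y - m))
    tot <- tot + w; bsum <- bsum + w * as.numeric(bm); musum <- musum + w * m
  }
  expect_equal(unname(fit$marker_effects), bsum / tot, tolerance = 0.01)
  expect_equal(fit$intercept, musum / tot, tolerance = 0.01)
})

test_that("the LASSO shrinks null markers harder than BRR", {
  # sparse truth: 5 strong QTLs among many nulls
  tp <- toy_population(n_markers = 220, n_parents = 24, n_crosses = 20,
                       lines_per_cross = 5:5, seed = 16)
  pop <- tp$pop
  poly <- colnames(pop)[apply(unclass(pop), 2, sd) > 0]
  qtl <- poly[seq(1, length(poly), length.out = 5)]
  arch <- structure(list(qtl_markers = qtl, effects = rep(3, 5), h2 = 0.9,
                         trait_name = "sparse"),
                    class = "trait_architecture")
  y <- as.numeric(simulate_trait(pop, arch, seed = 17))
  cfg <- gibbs_config(burn_in = 800, n_iter = 3000, seed = 3)
  bl <- bayes_lasso_gibbs(pop, y, cfg)
  br <- bayes_ridge_gibbs(pop, y, cfg)
  nulls <- setdiff(poly, qtl)
  expect_lt(mean(abs(bl$marker_effects[nulls])),
            mean(abs(br$marker_effects[nulls])))
})

test_that("GBLUP on an identity kinship shrinks phenotypes toward the mean", {
  y <- stats::setNames(c(1, 3, 5, 7), paste0("l", 1:4))
  ids <- c(names(y), "t1")
  K <- diag(5); dimnames(K) <- list(ids, ids)
  res <- gblup(K, y, delta = 1)
  # shrink factor 1/(1+delta) = 1/2 for training lines, mean for targets
  expect_equal(unname(res$gebv[names(y)]), mean(y) + (y - mean(y)) / 2,
               ignore_attr = TRUE)
  expect_equal(unname(res$gebv["t1"]), mean(y))
})

test_that("GBLUP equals ridge through the dual identity K = XX'/c", {
  d <- sim_xy(n = 20, p = 50, seed = 18)
  X <- unclass(impute_missing(d$X))[1:20, ]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  c0 <- ncol(X)
  K <- tcrossprod(Xc) / c0
  dimnames(K) <- list(rownames(X), rownames(X))
  lambda <- 7
  rid <- ridge_rrblup(X, d$y[1:20], lambda = lambda)
  g <- gblup(K, stats::setNames(d$y[1:20], rownames(X)),
             delta = lambda / c0)
  expect_lt(max(abs(g$gebv[rownames(X)] - predict(rid, X))), 1e-8)
})

test_that("GBLUP flags a singular kinship in strict mode and jitters otherwise", {
  X <- matrix(c(0, 1, 0, 1,
                0, 1, 0, 1,
                1, 0, 1, 0), 3, 4, byrow = TRUE,
              dimnames = list(paste0("l", 1:3), paste0("m", 1:4)))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  K <- tcrossprod(Xc) / ncol(X)
  dimnames(K) <- list(rownames(X), rownames(X))
  y <- stats::setNames(c(1, 2, 3), rownames(X))
  expect_error(gblup(K, y, delta = 0, strict = TRUE), "singular")
  expect_warning(res <- gblup(K, y, delta = 0), "jitter")
  expect_true(all(is.finite(res$gebv)))
})

test_that("RKHS behaves at kernel extremes and ignores marker order", {
  d <- sim_xy(n = 30, p = 60, seed = 19)
  X <- unclass(impute_missing(d$X))
  # flat kernel: predictions collapse to the mean
  flat <- rkhs_fit(X, d$y, bandwidth = 1e12, regularization = 1)
  expect_equal(unname(predict(flat, X)), rep(mean(d$y), nrow(X)),
               tolerance = 1e-4)
  # vanishing regularization interpolates the training data
  sub <- X[1:10, ]; ysub <- d$y[1:10]
  interp <- rkhs_fit(sub, ysub, bandwidth = median(dist(sub)^2),
                     regularization = 0)
  expect_equal(unname(predict(interp, sub)), ysub, tolerance = 1e-4)
  # column permutation leaves predictions unchanged
  perm <- sample(ncol(X))
  f1 <- rkhs_fit(X, d$y, bandwidth = 50, regularization = 0.5)
  f2 <- rkhs_fit(X[, perm], d$y, bandwidth = 50, regularization = 0.5)
  expect_equal(predict(f1, X), predict(f2, X[, perm]), tolerance = 1e-10)
})

test_that("Random Forest is seeded, handles constants and finds a strong QTL", {
  d <- sim_xy(n = 50, p = 40, seed = 20)
  X <- unclass(impute_missing(d$X))
  f1 <- random_forest_fit(X, d$y, n_trees = 60, seed = 4)
  f2 <- random_forest_fit(X, d$y, n_trees = 60, seed = 4)
  expect_identical(predict(f1, X), predict(f2, X))
  fc <- suppressWarnings(random_forest_fit(X, rep(3, nrow(X)), n_trees = 30,
                                           seed = 4))
  expect_true(all(abs(predict(fc, X) - 3) < 1e-10))
  # single dominant marker driving most of the variance
  set.seed(5)
  x1 <- rbinom(120, 1, 0.5)
  Xs <- cbind(q = x1, matrix(rbinom(120 * 20, 1, 0.5), 120))
  colnames(Xs) <- paste0("m", seq_len(ncol(Xs)))
  rownames(Xs) <- paste0("l", seq_len(nrow(Xs)))
  ys <- 2 * x1 + rnorm(120, 0, 0.5)
  frf <- random_forest_fit(Xs, ys, n_trees = 150, seed = 6)
  expect_gt(cor(predict(frf, Xs), ys)^2, 0.5)
})

test_that("prediction rejects mismatched marker panels", {
  d <- sim_xy(n = 30, p = 40, seed = 21)
  fit <- ridge_rrblup(d$X, d$y, h2 = 0.5)
  Xbad <- unclass(impute_missing(d$X))
  colnames(Xbad)[2] <- "other_marker"
  expect_error(predict(fit, Xbad), "do not match")
})

test_that("fit_gebv dispatches every method end to end", {
  d <- sim_xy(n = 50, p = 80, n_qtl = 15, h2 = 0.9, seed = 22)
  X <- impute_missing(d$X)
  cfg <- gibbs_config(burn_in = 200, n_iter = 1000, seed = 1)
  accs <- vapply(c("ridge", "brr", "blasso", "rkhs", "rf"), function(mm) {
    fit <- fit_gebv(mm, X, d$y, cfg = cfg, n_trees = 60, seed = 2)
    accuracy(predict(fit, X), d$y)
  }, numeric(1))
  gb <- fit_gebv("gblup", X, stats::setNames(d$y, rownames(X)), target = X)
  accs <- c(accs, gblup = accuracy(gb, d$y))
  expect_true(all(accs > 0.5))
})
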