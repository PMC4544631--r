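#' Center marker columns on training means
#'
#' Subtracts each marker's training-set mean from its column.  Target-set
#' genotypes must be centered with the *training* means so that marker
#' effects transfer: `center_markers(target, means = ctr$col_means)`.
#'
#' @param X a [marker_matrix()] or numeric matrix (lines x markers).
#' @param means optional numeric vector of column means to use (training
#'   means when centering a target set); defaults to the column means of `X`.
#' @return List with `X` (centered matrix) and `col_means`.
#' @export
center_markers <- function(X, means = NULL) {
  X <- .as_design(X)
  if (is.null(means)) means <- colMeans(X)
  list(X = sweep(X, 2, means, "-"), col_means = means)
}

# Coerce predictor input to a plain numeric design matrix; marker matrices
# are mean-imputed first so no NA reaches the solvers.
.as_design <- function(X) {
  if (is_marker_matrix(X)) {
    if (anyNA(unclass(X))) X <- impute_missing(X)
    unclass(X)
  } else {
    as.matrix(X)
  }
}

.new_gs_fit <- function(method, intercept, marker_effects, col_means,
                        training_line_ids, model_state = NULL,
                        diagnostics = list()) {
  structure(list(method = method, intercept = intercept,
                 marker_effects = marker_effects, col_means = col_means,
                 training_line_ids = training_line_ids,
                 model_state = model_state, diagnostics = diagnostics),
            class = c(paste0("gs_", tolower(method)), "gs_fit"))
}

#' @export
print.gs_fit <- function(x, ...) {
  cat(sprintf("gs_fit [%s]: %d training lines, %s\n", x$method,
              length(x$training_line_ids),
              if (is.null(x$marker_effects)) "kernel/ensemble state"
              else paste0(length(x$marker_effects), " marker effects")))
  invisible(x)
}

#' Ridge-regression BLUP (RR-BLUP)
#'
#' Closed-form ridge solution for the marker model `y = 1*mu + X beta + e`:
#' `beta = (X'X + lambda I)^-1 X'(y - ybar)` on the centered design, with
#' the shrinkage tied to heritability through the RR-BLUP variance
#' partition `lambda = sigma2_e / sigma2_beta = (1 - h2)/h2 * sum_j Var(x_j)`.
#' When markers outnumber lines the numerically identical dual (kernel)
#' form is used.
#'
#' @param X training genotypes ([marker_matrix()] or matrix).
#' @param y numeric phenotypes, one per training line.
#' @param h2 heritability driving the shrinkage, in (0, 1); default 0.37.
#' @param lambda optional explicit ridge parameter overriding `h2`.
#' @return A `gs_fit` with per-marker effects.
#' @export
ridge_rrblup <- function(X, y, h2 = 0.37, lambda = NULL) {
  X <- .as_design(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2, ncol(X) >= 1)
  if (is.null(lambda)) {
    if (!(h2 > 0 && h2 < 1)) stop("h2 must be in (0, 1)")
    lambda <- (1 - h2) / h2 * sum(apply(X, 2, stats::var))
  }
  ctr <- center_markers(X)
  Xc <- ctr$X
  yc <- y - mean(y)
  n <- nrow(Xc); p <- ncol(Xc)
  beta <- if (p <= n) {
    drop(solve(crossprod(Xc) + diag(lambda, p), crossprod(Xc, yc)))
  } else {
    drop(crossprod(Xc, solve(tcrossprod(Xc) + diag(lambda, n), yc)))
  }
  names(beta) <- colnames(X)
  .new_gs_fit("ridge", mean(y), beta, ctr$col_means, rownames(X),
              diagnostics = list(lambda = lambda, h2 = h2))
}

#' Gibbs sampler configuration for the Bayesian regressions
#'
#' Hyperparameters for [bayes_ridge_gibbs()] and [bayes_lasso_gibbs()].
#' Defaults: residual prior scale 4.5 with 3 df, marker-effect prior scale
#' 0.009 with 3 df, shrinkage anchored at heritability 0.37, burn-in 20,000
#' of 60,000 iterations.  The chain lengths are what full-scale analyses
#' use; exploratory runs and the test suite use much shorter chains since
#' the estimands are posterior means of a well-mixing conjugate sampler.
#'
#' @param S_eps,df_eps residual-variance prior scale and degrees of freedom.
#' @param S_beta,df_beta marker-effect-variance prior scale and df.
#' @param h2_lambda heritability anchoring the LASSO shrinkage prior.
#' @param burn_in,n_iter,thin chain control; `burn_in < n_iter`.
#' @param seed integer seed for the chain.
#' @return A list of class `gibbs_config`.
#' @export
gibbs_config <- function(S_eps = 4.5, df_eps = 3, S_beta = 0.009,
                         df_beta = 3, h2_lambda = 0.37, burn_in = 20000,
                         n_iter = 60000, thin = 1, seed = NULL) {
  stopifnot(S_eps > 0, S_beta > 0, df_eps > 0, df_beta > 0,
            h2_lambda > 0, h2_lambda < 1, burn_in >= 0, burn_in < n_iter,
            thin >= 1)
  structure(list(S_eps = S_eps, df_eps = df_eps, S_beta = S_beta,
                 df_beta = df_beta, h2_lambda = h2_lambda,
                 burn_in = as.integer(burn_in), n_iter = as.integer(n_iter),
                 thin = as.integer(thin), seed = seed),
            class = "gibbs_config")
}

#' Bayesian ridge regression by Gibbs sampling
#'
#' Model `y = 1*mu + X beta + e` with a Gaussian prior of common variance on
#' all marker effects; both variances carry scaled-inverse-chi-squared
#' priors.  Posterior means are taken over post-burn-in samples.  With
#' matched shrinkage `lambda = E[sigma2_e]/E[sigma2_beta]` the posterior
#' mean effects agree with the closed-form ridge solution.
#'
#' @param X training genotypes; centered internally.
#' @param y numeric phenotypes.
#' @param cfg a [gibbs_config()].
#' @return A `gs_fit` with posterior-mean effects; `diagnostics` holds the
#'   posterior-mean variances and implied shrinkage.
#' @export
bayes_ridge_gibbs <- function(X, y, cfg = gibbs_config()) {
  X <- .as_design(X)
  stopifnot(inherits(cfg, "gibbs_config"), nrow(X) == length(y))
  if (any(!is.finite(y))) stop("phenotypes must be finite")
  ctr <- center_markers(X)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- brr_gibbs_cpp(ctr$X, y, cfg$n_iter, cfg$burn_in, cfg$thin,
                       cfg$S_eps, cfg$df_eps, cfg$S_beta, cfg$df_beta)
  beta <- drop(res$beta)
  names(beta) <- colnames(X)
  .new_gs_fit("brr", res$mu, beta, ctr$col_means, rownames(X),
              diagnostics = list(sigma2_e = res$sigma2_e,
                                 sigma2_beta = res$sigma2_beta,
                                 lambda = res$sigma2_e / res$sigma2_beta,
                                 n_samples = res$n_samples))
}

#' Bayesian LASSO by Gibbs sampling
#'
#' Park-Casella hierarchy: `beta_j ~ N(0, sigma2_e * tau2_j)` with
#' `tau2_j ~ Exp(lambda2/2)`, giving each marker its own shrinkage (the
#' marginal effect prior is double-exponential).  `lambda2` has a
#' Gamma(shape 1, rate delta) hyperprior whose mean equals the shrinkage a
#' ridge model would use at heritability `cfg$h2_lambda`: the prior variance
#' of an effect is `2 sigma2_e / lambda2`, so solving
#' `lambda2 = 2 * (1-h2)/h2 * sum_j Var(x_j)` anchors the prior at the same
#' variance partition and `delta = 1/lambda2` sets the hyperprior mean there.
#'
#' @inheritParams bayes_ridge_gibbs
#' @return A `gs_fit` with posterior-mean effects.
#' @export
bayes_lasso_gibbs <- function(X, y, cfg = gibbs_config()) {
  X <- .as_design(X)
  stopifnot(inherits(cfg, "gibbs_config"), nrow(X) == length(y))
  if (any(!is.finite(y))) stop("phenotypes must be finite")
  ctr <- center_markers(X)
  h2 <- cfg$h2_lambda
  lambda2_0 <- 2 * (1 - h2) / h2 * sum(apply(X, 2, stats::var))
  if (!is.finite(lambda2_0) || lambda2_0 <= 0) lambda2_0 <- 1
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- bl_gibbs_cpp(ctr$X, y, cfg$n_iter, cfg$burn_in, cfg$thin,
                      cfg$S_eps, cfg$df_eps, lambda2_0,
                      1, 1 / lambda2_0)
  beta <- drop(res$beta)
  names(beta) <- colnames(X)
  .new_gs_fit("blasso", res$mu, beta, ctr$col_means, rownames(X),
              diagnostics = list(sigma2_e = res$sigma2_e,
                                 lambda2 = res$lambda2,
                                 n_samples = res$n_samples))
}

# Spectral REML for y = mu + g + e, g ~ N(0, sigma2_g K): profile the REML
# log-likelihood over delta = sigma2_e/sigma2_g on the eigenbasis of K.
.spectral_reml <- function(K, y, interval = c(-10, 10)) {
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  ot <- drop(crossprod(eg$vectors, rep(1, length(y))))
  n <- length(y)
  nll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    mu <- sum(ot * w * yt) / sum(ot * ot * w)
    r <- yt - ot * mu
    s2g <- sum(r * r * w) / (n - 1)
    0.5 * ((n - 1) * log(s2g) + sum(log(d + delta)) + log(sum(ot * ot * w)))
  }
  opt <- stats::optimize(nll, interval)
  delta <- exp(opt$minimum)
  w <- 1 / (d + delta)
  mu <- sum(ot * w * yt) / sum(ot * ot * w)
  r <- yt - ot * mu
  s2g <- sum(r * r * w) / (n - 1)
  list(delta = delta, mu = mu, sigma2_g = s2g, sigma2_e = s2g * delta)
}

#' GBLUP: mixed-model breeding values on a marker kinship
#'
#' Solves the animal-model mixed equations on a kinship matrix `K` spanning
#' training and target lines: `g_hat = K[.,t] (K[t,t] + delta I)^-1 (y - mu)`
#' with `delta = sigma2_e / sigma2_g` estimated by spectral REML on the
#' training block (or supplied).  Returns a GEBV for every line in `K`.
#' Highly related panels can make `K[t,t] + delta I` numerically singular;
#' by default a 1e-6 diagonal jitter is added with a warning, while
#' `strict = TRUE` raises an error instead.
#'
#' @param K symmetric kinship matrix with line ids as dimnames (e.g. from
#'   [ibs_kinship()] or `tcrossprod` of centered markers).
#' @param y named numeric vector of training phenotypes; names must be rows
#'   of `K`.  Lines of `K` absent from `y` are targets.
#' @param delta optional fixed variance ratio `sigma2_e / sigma2_g`.
#' @param strict error (rather than jitter) on a singular system.
#' @return A `gblup_result`: list with `gebv` (named, all lines of `K`),
#'   `mu`, `delta`, `sigma2_g`, `sigma2_e`.
#' @export
gblup <- function(K, y, delta = NULL, strict = FALSE) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8) stop("kinship matrix must be symmetric")
  ids <- rownames(K)
  if (is.null(ids) || is.null(names(y))) {
    stop("K and y must carry line ids (dimnames/names)")
  }
  train <- match(names(y), ids)
  if (anyNA(train)) stop("training line(s) missing from K: ",
                         paste(names(y)[is.na(train)][1:3], collapse = ", "))
  Ktt <- K[train, train]
  if (is.null(delta)) {
    vc <- .spectral_reml(Ktt, y)
    delta <- max(vc$delta, 1e-8)
    mu <- vc$mu
    s2g <- vc$sigma2_g; s2e <- vc$sigma2_e
  } else {
    mu <- mean(y)
    s2g <- NA_real_; s2e <- NA_real_
  }
  A <- Ktt + diag(delta, nrow(Ktt))
  sol <- tryCatch(solve(A, y - mu), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol))) {
    if (strict) stop("kinship singular: (K_tt + delta I) could not be inverted")
    warning("kinship system singular; adding 1e-6 diagonal jitter")
    sol <- solve(A + diag(1e-6, nrow(A)), y - mu)
  }
  gebv <- mu + drop(K[, train] %*% sol)
  names(gebv) <- ids
  structure(list(gebv = gebv, mu = mu, delta = delta,
                 sigma2_g = s2g, sigma2_e = s2e,
                 training_line_ids = names(y)),
            class = "gblup_result")
}

#' Gaussian-kernel RKHS regression
#'
#' Kernel ridge regression with the Gaussian kernel
#' `K_ij = exp(-d2_ij / theta)` on squared Euclidean marker distances:
#' `alpha = (K + lambda I)^-1 (y - ybar)`, predictions via the cross-kernel
#' to the training lines.  The bandwidth defaults to the median of pairwise
#' squared distances (median heuristic); the regularization defaults to the
#' spectral-REML variance ratio on the training kernel, so no tuning is
#' required for routine use.
#'
#' @param X training genotypes.
#' @param y numeric phenotypes.
#' @param bandwidth kernel bandwidth `theta` (> 0); `NULL` for the median
#'   heuristic.
#' @param regularization ridge parameter (>= 0); `NULL` for spectral REML.
#' @return A `gs_fit` storing the training design and dual coefficients.
#' @export
rkhs_fit <- function(X, y, bandwidth = NULL, regularization = NULL) {
  X <- .as_design(X)
  stopifnot(nrow(X) == length(y))
  d2 <- as.matrix(stats::dist(X))^2
  if (is.null(bandwidth)) {
    bandwidth <- stats::median(d2[upper.tri(d2)])
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  stopifnot(bandwidth > 0)
  K <- exp(-d2 / bandwidth)
  if (is.null(regularization)) {
    regularization <- .spectral_reml(K, y)$delta
  }
  stopifnot(regularization >= 0)
  alpha <- solve(K + diag(regularization + 1e-10, nrow(K)), y - mean(y))
  .new_gs_fit("rkhs", mean(y), NULL, NULL, rownames(X),
              model_state = list(X_train = X, alpha = drop(alpha),
                                 bandwidth = bandwidth,
                                 regularization = regularization))
}

#' Random Forest regression on markers
#'
#' Bagged regression trees with random marker subsampling at each split
#' (wraps [randomForest::randomForest()]).  Defaults follow the standard
#' regression settings: 500 trees and `mtry = floor(markers / 3)`.
#'
#' @param X training genotypes.
#' @param y numeric phenotypes.
#' @param n_trees number of trees.
#' @param mtry candidate markers per split.
#' @param seed integer seed (the forest is deterministic given the seed).
#' @return A `gs_fit` wrapping the forest.
#' @export
random_forest_fit <- function(X, y, n_trees = 500, mtry = NULL, seed = NULL) {
  X <- .as_design(X)
  stopifnot(nrow(X) == length(y), n_trees >= 1)
  if (is.null(mtry)) mtry <- max(1, floor(ncol(X) / 3))
  stopifnot(mtry >= 1, mtry <= ncol(X))
  if (!is.null(seed)) set.seed(seed)
  colnames(X) <- make.names(colnames(X))  # forest requires syntactic names
  rf <- randomForest::randomForest(x = X, y = y, ntree = n_trees, mtry = mtry)
  .new_gs_fit("rf", mean(y), NULL, NULL, rownames(X),
              model_state = list(forest = rf, marker_ids = colnames(X)))
}

#' Predict GEBVs for a target set
#'
#' @param object a `gs_fit`.
#' @param target a [marker_matrix()] or numeric matrix whose markers match
#'   the training markers in id and order.
#' @param ... unused.
#' @return Named numeric vector of GEBVs.
#' @export
predict.gs_fit <- function(object, target, ...) {
  Xt <- .as_design(target)
  train_ids <- if (!is.null(object$marker_effects)) {
    names(object$marker_effects)
  } else if (!is.null(object$model_state$X_train)) {
    colnames(object$model_state$X_train)
  } else {
    object$model_state$marker_ids
  }
  if (!is.null(train_ids) && !is.null(colnames(Xt)) &&
      object$method != "rf") {
    if (!identical(colnames(Xt), train_ids)) {
      bad <- utils::head(which(colnames(Xt) != train_ids |
                                 is.na(match(colnames(Xt), train_ids))), 5)
      stop("target markers do not match training markers (first mismatches at columns ",
           paste(bad, collapse = ", "), ")")
    }
  }
  out <- switch(object$method,
    ridge = , brr = , blasso = {
      Xc <- sweep(Xt, 2, object$col_means, "-")
      object$intercept + drop(Xc %*% object$marker_effects)
    },
    rkhs = {
      st <- object$model_state
      d2 <- outer(rowSums(Xt^2), rowSums(st$X_train^2), "+") -
        2 * tcrossprod(Xt, st$X_train)
      object$intercept + drop(exp(-pmax(d2, 0) / st$bandwidth) %*% st$alpha)
    },
    rf = {
      colnames(Xt) <- make.names(colnames(Xt))
      if (!identical(colnames(Xt), object$model_state$marker_ids)) {
        stop("target markers do not match training markers")
      }
      drop(stats::predict(object$model_state$forest, Xt))
    },
    stop("no predict method for '", object$method, "'"))
  names(out) <- rownames(Xt)
  out
}

#' Fit any of the five GEBV methods through one interface
#'
#' Dispatcher used by the cross-validation machinery.  `"gblup"` needs the
#' target genotypes up front (the mixed model solves for training and target
#' lines jointly on one kinship), so `target` is required for it; the other
#' methods ignore `target` at fit time.
#'
#' @param method one of `"ridge"`, `"brr"`, `"blasso"`, `"gblup"`,
#'   `"rkhs"`, `"rf"`.
#' @param X training genotypes.
#' @param y training phenotypes (named for gblup).
#' @param target target genotypes (gblup only).
#' @param h2 heritability for the ridge shrinkage.
#' @param cfg a [gibbs_config()] for the Bayesian methods.
#' @param n_trees,seed Random Forest controls.
#' @return For `"gblup"` a named GEBV vector for the target lines; otherwise
#'   a `gs_fit` (use [predict.gs_fit()]).
#' @export
fit_gebv <- function(method, X, y, target = NULL, h2 = 0.37,
                     cfg = gibbs_config(burn_in = 2000, n_iter = 10000),
                     n_trees = 500, seed = NULL) {
  method <- match.arg(method, c("ridge", "brr", "blasso", "gblup", "rkhs",
                                "rf"))
  if (method == "gblup") {
    if (is.null(target)) stop("gblup requires target genotypes")
    Xtr <- .as_design(X); Xta <- .as_design(target)
    if (!identical(colnames(Xtr), colnames(Xta))) {
      stop("target markers do not match training markers")
    }
    all_X <- rbind(Xtr, Xta)
    Xc <- scale(all_X, center = TRUE, scale = FALSE)
    K <- tcrossprod(Xc) / ncol(Xc)
    dimnames(K) <- list(rownames(all_X), rownames(all_X))
    yy <- y
    names(yy) <- rownames(Xtr)
    res <- gblup(K, yy)
    return(res$gebv[rownames(Xta)])
  }
  switch(method,
    ridge = ridge_rrblup(X, y, h2 = h2),
    brr = bayes_ridge_gibbs(X, y, cfg = cfg),
    blasso = bayes_lasso_gibbs(X, y, cfg = cfg),
    rkhs = rkhs_fit(X, y),
    rf = random_forest_fit(X, y, n_trees = n_trees, seed = seed))
}
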