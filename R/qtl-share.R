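#' Cross-population prediction accuracy versus shared QTL fraction
#'
#' Simulation experiment explaining why cross-population prediction fails:
#' two genotyped populations receive traits governed by partially shared
#' QTL architectures, a model is trained on the first population's trait
#' and used to predict the second population's lines, and the accuracy
#' against the second population's own trait is recorded.  The shared
#' fraction runs over a grid (default 10-100% in steps of 10) at each
#' heritability level (default 0.3 and 0.6), with `n_reps` independent
#' architecture draws per cell.
#'
#' For the closed-form ridge method the training design is fixed across
#' replicates, so the linear predictor map is precomputed once per
#' heritability level; this is numerically identical to refitting.
#'
#' @param pop_train,pop_valid [marker_matrix()] objects; QTLs are drawn
#'   from the markers polymorphic in, and common to, both.
#' @param fractions shared-QTL fractions in (0, 1].
#' @param h2_levels trait heritabilities.
#' @param method prediction method (see [fit_gebv()]); default `"ridge"`.
#' @param n_qtl QTLs in the parent architecture (default 100).
#' @param sigma_a sd of additive QTL effects.
#' @param n_reps replicates per grid cell (default 50).
#' @param scheme subset scheme for [shared_subsets()].
#' @param seed master seed; replicate substreams are derived from it.
#' @param ... passed to [fit_gebv()] for non-ridge methods.
#' @return Data frame with one row per (fraction, h2): `fraction`, `h2`,
#'   `mean_r`, `sd_r`, `se_r`, `n_reps`.
#' @export
qtl_sharing_experiment <- function(pop_train, pop_valid,
                                   fractions = seq(0.1, 1, by = 0.1),
                                   h2_levels = c(0.3, 0.6),
                                   method = "ridge", n_qtl = 100,
                                   sigma_a = 1, n_reps = 50,
                                   scheme = c("independent", "overlap"),
                                   seed = 1, ...) {
  stopifnot(is_marker_matrix(pop_train), is_marker_matrix(pop_valid))
  scheme <- match.arg(scheme)
  common <- intersect_markers(list(pop_train, pop_valid))
  tr <- impute_missing(common[[1]])
  va <- impute_missing(common[[2]])
  poly <- apply(unclass(tr), 2, stats::sd) > 0 &
    apply(unclass(va), 2, stats::sd) > 0
  candidates <- colnames(tr)[poly]
  if (length(candidates) < n_qtl) {
    stop("only ", length(candidates),
         " shared polymorphic markers; need >= n_qtl = ", n_qtl)
  }
  Xtr <- unclass(tr)
  Xva <- unclass(va)
  # Precomputed ridge predictor map per h2: valid GEBV = M %*% (y - ybar) + ybar
  ridge_maps <- NULL
  if (method == "ridge") {
    ridge_maps <- lapply(stats::setNames(h2_levels, h2_levels), function(h2) {
      lambda <- (1 - h2) / h2 * sum(apply(Xtr, 2, stats::var))
      mu <- colMeans(Xtr)
      Xc <- sweep(Xtr, 2, mu, "-")
      Vc <- sweep(Xva, 2, mu, "-")
      Vc %*% t(Xc) %*% solve(tcrossprod(Xc) + diag(lambda, nrow(Xc)))
    })
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  grid <- expand.grid(fraction = fractions, h2 = h2_levels)
  acc <- matrix(NA_real_, n_reps, nrow(grid))
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    arch <- draw_architecture(candidates, n_qtl = n_qtl, sigma_a = sigma_a)
    for (g in seq_len(nrow(grid))) {
      sub <- shared_subsets(arch, grid$fraction[g], scheme = scheme)
      sub$train$h2 <- grid$h2[g]
      sub$valid$h2 <- grid$h2[g]
      y_tr <- simulate_trait(tr, sub$train)
      y_va <- simulate_trait(va, sub$valid)
      pred <- if (method == "ridge") {
        M <- ridge_maps[[as.character(grid$h2[g])]]
        drop(M %*% (y_tr - mean(y_tr))) + mean(y_tr)
      } else if (method == "gblup") {
        fit_gebv("gblup", tr, stats::setNames(as.numeric(y_tr), names(y_tr)),
                 target = va, ...)
      } else {
        fit <- fit_gebv(method, tr, as.numeric(y_tr), ...)
        predict(fit, va)
      }
      acc[r, g] <- suppressWarnings(accuracy(pred, as.numeric(y_va)))
    }
  }
  data.frame(fraction = grid$fraction, h2 = grid$h2,
             mean_r = colMeans(acc, na.rm = TRUE),
             sd_r = apply(acc, 2, stats::sd, na.rm = TRUE),
             se_r = apply(acc, 2, stats::sd, na.rm = TRUE) /
               sqrt(colSums(!is.na(acc))),
             n_reps = colSums(!is.na(acc)))
}
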