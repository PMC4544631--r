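#' Prediction accuracy as Pearson correlation
#'
#' The accuracy of a genomic prediction is the Pearson correlation between
#' GEBVs and observed phenotypes in the validation set.  A constant vector
#' makes the correlation undefined; that case returns `NA` with a warning
#' rather than an error so resampling loops can record and skip it.
#'
#' @param gebv,observed equal-length numeric vectors (length >= 3).
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
accuracy <- function(gebv, observed) {
  if (length(gebv) != length(observed)) stop("length mismatch")
  if (length(gebv) < 3) stop("need at least 3 pairs")
  if (stats::sd(gebv) == 0 || stats::sd(observed) == 0) {
    warning("constant vector; accuracy undefined")
    return(NA_real_)
  }
  stats::cor(gebv, observed)
}

#' Random training/validation partition of one population
#'
#' @param ids character vector of line ids (n >= 5).
#' @param train_fraction fraction assigned to training; train size is
#'   `round(train_fraction * n)`, validation the remainder.
#' @return List with `train` and `validation` id vectors (disjoint,
#'   exhaustive).
#' @export
split_single <- function(ids, train_fraction = 0.8) {
  n <- length(ids)
  stopifnot(n >= 5)
  k <- round(train_fraction * n)
  if (k < 1 || k >= n) stop("train_fraction leaves an empty partition")
  tr <- sample(ids, k)
  list(train = tr, validation = setdiff(ids, tr))
}

#' Cross-validation scheme descriptor
#'
#' Three schemes: `"single"` resamples within one population; `"composite"`
#' pools several populations and resamples the pool; `"cross"` fits on a
#' random 80% of the training population(s) and evaluates on a random 20%
#' of a held-out validation population, refitting every iteration.
#'
#' @param kind `"single"`, `"composite"` or `"cross"`.
#' @param training_populations character vector of population names.
#' @param validation_population held-out population name (cross only).
#' @param train_fraction training fraction per iteration (default 0.8).
#' @param n_iterations number of resamplings (default 200).
#' @param seed master seed; per-iteration substreams are derived from it.
#' @return A list of class `cv_scheme`.
#' @export
cv_scheme <- function(kind = c("single", "composite", "cross"),
                      training_populations, validation_population = NULL,
                      train_fraction = 0.8, n_iterations = 200, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "cross") {
    if (is.null(validation_population)) {
      stop("cross scheme needs a validation population")
    }
    if (validation_population %in% training_populations) {
      stop("validation population must be disjoint from training populations")
    }
  }
  stopifnot(train_fraction > 0, train_fraction < 1, n_iterations >= 1)
  structure(list(kind = kind,
                 training_populations = training_populations,
                 validation_population = validation_population,
                 train_fraction = train_fraction,
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

.pool_populations <- function(populations, names) {
  mats <- lapply(populations[names], `[[`, "geno")
  if (length(mats) > 1) mats <- intersect_markers(mats)
  geno <- do.call(rbind, lapply(mats, unclass))
  pheno <- do.call(c, unname(lapply(populations[names], function(p) p$pheno)))
  pheno <- pheno[rownames(geno)]
  list(geno = geno, pheno = pheno)
}

#' Run a cross-validation experiment
#'
#' Executes the resampling scheme, refitting the prediction model in every
#' iteration and scoring the held-out lines with [accuracy()].  Populations
#' with different marker panels are first harmonized to their common
#' markers.  Iterations whose accuracy is undefined (constant predictions)
#' are recorded as `NA` and excluded from the mean/sd with a warning count.
#'
#' @param scheme a [cv_scheme()].
#' @param populations named list; each element a list with `geno` (a
#'   [marker_matrix()]) and `pheno` (named numeric vector over its lines).
#' @param method prediction method, see [fit_gebv()].
#' @param trait trait label carried into the result.
#' @param ... passed to [fit_gebv()] (e.g. `h2`, `cfg`, `n_trees`).
#' @return A `cv_result`: list with `per_iteration_r`, `mean_r`, `sd_r`,
#'   `n_undefined`, `scheme`, `method`, `trait`.
#' @export
run_cv <- function(scheme, populations, method = "ridge", trait = "trait",
                   ...) {
  stopifnot(inherits(scheme, "cv_scheme"))
  need <- c(scheme$training_populations, scheme$validation_population)
  miss <- setdiff(need, names(populations))
  if (length(miss) > 0) stop("unknown population(s): ",
                             paste(miss, collapse = ", "))
  if (scheme$kind == "cross") {
    pooled <- .pool_populations(populations, need)
    train_ids_all <- unlist(lapply(scheme$training_populations, function(nm)
      rownames(populations[[nm]]$geno)))
    valid_ids_all <- rownames(populations[[scheme$validation_population]]$geno)
  } else {
    pooled <- .pool_populations(populations, scheme$training_populations)
    train_ids_all <- rownames(pooled$geno)
    valid_ids_all <- NULL
  }
  geno <- pooled$geno
  pheno <- pooled$pheno
  if (anyNA(pheno)) stop("phenotype missing for some genotyped lines")
  set.seed(scheme$seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1, scheme$n_iterations)
  rs <- vapply(seq_len(scheme$n_iterations), function(i) {
    set.seed(iter_seeds[i])
    if (scheme$kind == "cross") {
      tr <- sample(train_ids_all,
                   round(scheme$train_fraction * length(train_ids_all)))
      va <- sample(valid_ids_all,
                   max(3, round((1 - scheme$train_fraction) *
                                  length(valid_ids_all))))
    } else {
      sp <- split_single(train_ids_all, scheme$train_fraction)
      tr <- sp$train; va <- sp$validation
    }
    Xtr <- geno[tr, , drop = FALSE]
    Xva <- geno[va, , drop = FALSE]
    if (method == "gblup") {
      pred <- fit_gebv("gblup", Xtr, pheno[tr], target = Xva, ...)
    } else {
      fit <- fit_gebv(method, Xtr, pheno[tr], seed = iter_seeds[i], ...)
      pred <- predict(fit, Xva)
    }
    suppressWarnings(accuracy(pred, pheno[va]))
  }, numeric(1))
  n_und <- sum(is.na(rs))
  if (n_und > 0) warning(n_und, " iteration(s) had undefined accuracy")
  structure(list(per_iteration_r = rs,
                 mean_r = mean(rs, na.rm = TRUE),
                 sd_r = stats::sd(rs, na.rm = TRUE),
                 n_undefined = n_und, scheme = scheme, method = method,
                 trait = trait),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s/%s, %s]: mean r = %.3f (sd %.3f, %d iterations%s)\n",
              x$scheme$kind, x$method, x$trait, x$mean_r, x$sd_r,
              x$scheme$n_iterations,
              if (x$n_undefined > 0) paste0(", ", x$n_undefined, " undefined")
              else ""))
  invisible(x)
}
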