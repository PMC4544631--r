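#' Draw a simulated trait architecture
#'
#' Samples `n_qtl` distinct QTL markers uniformly without replacement from a
#' set of candidate markers (typically the markers common to the training
#' and validation populations) and assigns each an additive effect drawn
#' i.i.d. from Normal(0, `sigma_a`^2).  Effects are attached to the allele
#' coded 1.
#'
#' @param common_markers character vector of candidate marker ids.
#' @param n_qtl number of QTLs (default 100).
#' @param sigma_a standard deviation of additive effects (default 1).
#' @param h2 narrow-sense line-mean heritability used when the trait is
#'   simulated (in (0, 1]).
#' @param trait_name label.
#' @param seed integer seed.
#' @return A `trait_architecture`: list with `qtl_markers`, `effects`, `h2`,
#'   `trait_name`.
#' @export
draw_architecture <- function(common_markers, n_qtl = 100, sigma_a = 1,
                              h2 = 0.6, trait_name = "sim", seed = NULL) {
  common_markers <- as.character(common_markers)
  if (n_qtl > length(common_markers)) {
    stop("n_qtl (", n_qtl, ") exceeds the ", length(common_markers),
         " available markers")
  }
  stopifnot(h2 > 0, h2 <= 1, sigma_a >= 0)
  if (!is.null(seed)) set.seed(seed)
  qtl <- sample(common_markers, n_qtl)
  structure(list(qtl_markers = qtl,
                 effects = stats::rnorm(n_qtl, 0, sigma_a),
                 h2 = h2, trait_name = trait_name),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("trait_architecture '%s': %d QTLs, h2 = %.2f, sd(effects) = %.3f\n",
              x$trait_name, length(x$qtl_markers), x$h2, stats::sd(x$effects)))
  invisible(x)
}

#' Partially shared architectures for two populations
#'
#' From a parent architecture of `n` QTLs, builds one architecture for the
#' training population's trait and one for the validation population's
#' trait, sharing a controlled number of QTLs.  Two schemes:
#'
#' * `"independent"` (default): each architecture is an independent draw of
#'   `round(fraction * n)` QTLs (without replacement, keeping the original
#'   effects), so the expected shared proportion of each subset is
#'   `fraction` and the realized overlap is hypergeometric.
#' * `"overlap"`: the training trait keeps all `n` QTLs and the validation
#'   trait uses a random subset of `round(fraction * n)` of them, making the
#'   shared proportion of the training architecture exactly `fraction`.
#'
#' @param arch a `trait_architecture` from [draw_architecture()].
#' @param fraction value in (0, 1]; `round(fraction * n)` must be >= 1.
#' @param scheme `"independent"` or `"overlap"`.
#' @param seed integer seed.
#' @return List with elements `train` and `valid`, both `trait_architecture`.
#' @export
shared_subsets <- function(arch, fraction, scheme = c("independent", "overlap"),
                           seed = NULL) {
  stopifnot(inherits(arch, "trait_architecture"),
            fraction > 0, fraction <= 1)
  scheme <- match.arg(scheme)
  n <- length(arch$qtl_markers)
  k <- round(fraction * n)
  if (k < 1) stop("fraction * n_qtl must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  take <- function(idx, tag) {
    structure(list(qtl_markers = arch$qtl_markers[idx],
                   effects = arch$effects[idx], h2 = arch$h2,
                   trait_name = paste0(arch$trait_name, "_", tag)),
              class = "trait_architecture")
  }
  if (scheme == "independent") {
    list(train = take(sample.int(n, k), "train"),
         valid = take(sample.int(n, k), "valid"))
  } else {
    list(train = take(seq_len(n), "train"),
         valid = take(sample.int(n, k), "valid"))
  }
}

#' Simulate a trait on a genotyped population
#'
#' The genetic value of line i is the sum of its QTL genotypes weighted by
#' the architecture's additive effects.  Gaussian noise is then added with
#' variance `Var(g) * (1 - h2) / h2`, computed from the variance of the
#' genetic values realized in this population, so that the expected realized
#' heritability equals the architecture's `h2`.
#'
#' @param m a [marker_matrix()] containing all QTL markers (missing calls
#'   are mean-imputed on the fly).
#' @param arch a `trait_architecture`.
#' @param seed integer seed for the noise draw.
#' @return Named numeric vector of phenotypes (one per line) with attribute
#'   `genetic_value` holding the noise-free values.
#' @export
simulate_trait <- function(m, arch, seed = NULL) {
  stopifnot(is_marker_matrix(m), inherits(arch, "trait_architecture"))
  miss <- setdiff(arch$qtl_markers, colnames(m))
  if (length(miss) > 0) {
    stop("QTL marker(s) absent from genotype matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  X <- unclass(m)[, arch$qtl_markers, drop = FALSE]
  if (anyNA(X)) X <- unclass(impute_missing(m[, arch$qtl_markers]))
  g <- drop(X %*% arch$effects)
  names(g) <- rownames(m)
  if (arch$h2 < 1) {
    vg <- stats::var(g)
    if (vg == 0) stop("genetic variance is zero; heritability < 1 undefined")
    if (!is.null(seed)) set.seed(seed)
    e <- stats::rnorm(length(g), 0, sqrt(vg * (1 - arch$h2) / arch$h2))
  } else {
    e <- rep(0, length(g))
  }
  y <- g + e
  attr(y, "genetic_value") <- g
  y
}
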