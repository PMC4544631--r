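#' Identity-by-state kinship from dominant marker genotypes
#'
#' `K_ij` is the proportion of markers at which lines i and j carry the same
#' genotype code (simple matching on 0/1 calls):
#' `K = (X X' + (1-X)(1-X)') / m`, which is symmetric, positive
#' semi-definite and has unit diagonal on complete binary data.  Missing
#' calls must be imputed first ([impute_missing()]); with fractional imputed
#' values the same bilinear form is used.
#'
#' @param m a [marker_matrix()] or a list of them.  A list is first
#'   restricted to the shared markers ([intersect_markers()]) and stacked;
#'   population ids become the group labels.
#' @param groups optional named character vector (line id -> group label).
#' @return A `kinship_matrix`: numeric matrix with line-id dimnames and
#'   attributes `groups` and `normalized` (FALSE).
#' @export
ibs_kinship <- function(m, groups = NULL) {
  if (is.list(m) && !is_marker_matrix(m)) {
    mats <- intersect_markers(m)
    if (is.null(groups)) {
      groups <- unlist(lapply(mats, function(x)
        stats::setNames(rep(attr(x, "population_id"), nrow(x)), rownames(x))))
    }
    vals <- do.call(rbind, lapply(mats, unclass))
  } else {
    stopifnot(is_marker_matrix(m))
    vals <- unclass(m)
    if (is.null(groups)) {
      groups <- stats::setNames(rep(attr(m, "population_id"), nrow(vals)),
                                rownames(vals))
    }
  }
  if (ncol(vals) == 0) stop("no markers")
  if (anyNA(vals)) stop("missing genotypes; run impute_missing() first")
  K <- (tcrossprod(vals) + tcrossprod(1 - vals)) / ncol(vals)
  dimnames(K) <- list(rownames(vals), rownames(vals))
  structure(K, groups = groups, normalized = FALSE,
            class = c("kinship_matrix", "matrix", "array"))
}

#' Normalize a kinship matrix by its mean diagonal
#'
#' Divides every coefficient by the average diagonal value so that the mean
#' self-kinship is exactly 1; estimators whose diagonal exceeds 1 (e.g.
#' TASSEL-style scaled kinships) are brought onto a 0-1-ish coancestry
#' scale.  Values are reported as computed and never clipped.
#'
#' @param k a `kinship_matrix`.
#' @return The normalized `kinship_matrix` (idempotent).
#' @export
normalize_kinship <- function(k) {
  stopifnot(inherits(k, "kinship_matrix"))
  md <- mean(diag(k))
  if (md <= 0) stop("mean diagonal is not positive")
  out <- unclass(k) / md
  structure(out, groups = attr(k, "groups"), normalized = TRUE,
            class = class(k))
}

#' Within- and between-population kinship summary
#'
#' Mean, minimum and maximum of the off-diagonal coancestry coefficients for
#' every pair of population groups (self-kinships are excluded from
#' within-group statistics).
#'
#' @param k a `kinship_matrix` with a `groups` attribute.
#' @return Data frame with columns `group_a`, `group_b`, `mean`, `min`,
#'   `max`, `n_pairs`.
#' @export
kinship_group_summary <- function(k) {
  stopifnot(inherits(k, "kinship_matrix"))
  groups <- attr(k, "groups")
  if (is.null(groups)) stop("kinship matrix has no group labels")
  g <- groups[rownames(k)]
  lv <- unique(g)
  rows <- list()
  for (a in seq_along(lv)) {
    for (b in a:length(lv)) {
      ia <- which(g == lv[a]); ib <- which(g == lv[b])
      block <- unclass(k)[ia, ib, drop = FALSE]
      vals <- if (a == b) block[upper.tri(block)] else as.vector(block)
      if (length(vals) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        group_a = lv[a], group_b = lv[b], mean = mean(vals),
        min = min(vals), max = max(vals), n_pairs = length(vals),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Linkage disequilibrium between two markers in inbred lines
#'
#' Squared Pearson correlation of the 0/1 genotype columns.  For fully
#' inbred lines the genotype column is the haplotype, so this equals the
#' haplotype-level r-squared.
#'
#' @param a,b numeric 0/1 vectors over the same lines.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("marker columns differ in length")
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("LD undefined for a monomorphic marker")
  }
  stats::cor(a, b)^2
}

#' LD r-squared for marker pairs within chromosomes
#'
#' Computes [ld_r2()] for all pairs of polymorphic markers lying on the same
#' chromosome (or all pairs when no map is given), with the map distance
#' when available.
#'
#' @param m a [marker_matrix()].
#' @param map optional [genetic_map()]; restricts pairs to mapped markers on
#'   a shared chromosome.
#' @param max_pairs optional cap on the number of pairs (random subsample).
#' @param seed seed for the subsample.
#' @return Data frame: `marker_a`, `marker_b`, `r2` and (with a map)
#'   `chromosome`, `dist_cM`.
#' @export
ld_pairs <- function(m, map = NULL, max_pairs = NULL, seed = NULL) {
  stopifnot(is_marker_matrix(m))
  vals <- unclass(m)
  poly <- apply(vals, 2, function(x) stats::sd(x, na.rm = TRUE) > 0)
  vals <- vals[, poly, drop = FALSE]
  if (!is.null(map)) {
    keep <- colnames(vals)[colnames(vals) %in% map$marker]
    vals <- vals[, keep, drop = FALSE]
    pos <- map$position_cM[match(colnames(vals), map$marker)]
    chr <- map$chromosome[match(colnames(vals), map$marker)]
    pairs <- do.call(rbind, lapply(unique(chr), function(cc) {
      j <- which(chr == cc)
      if (length(j) < 2) return(NULL)
      t(utils::combn(j, 2))
    }))
  } else {
    pairs <- t(utils::combn(ncol(vals), 2))
  }
  if (is.null(pairs) || nrow(pairs) == 0) stop("no eligible marker pairs")
  if (!is.null(max_pairs) && nrow(pairs) > max_pairs) {
    if (!is.null(seed)) set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  }
  r2 <- vapply(seq_len(nrow(pairs)), function(i)
    ld_r2(vals[, pairs[i, 1]], vals[, pairs[i, 2]]), numeric(1))
  out <- data.frame(marker_a = colnames(vals)[pairs[, 1]],
                    marker_b = colnames(vals)[pairs[, 2]], r2 = r2,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    out$chromosome <- chr[pairs[, 1]]
    out$dist_cM <- abs(pos[pairs[, 1]] - pos[pairs[, 2]])
  }
  out
}
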