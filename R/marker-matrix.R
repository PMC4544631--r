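#' Marker matrix for fully inbred lines
#'
#' A `marker_matrix` stores dominant presence/absence genotype calls for a set
#' of inbred lines (doubled haploids or advanced-generation inbreds), coded 0/1
#' with `NA` for missing calls.  There is no heterozygote code: lines are
#' treated as fully homozygous, which is the appropriate model for DH and
#' F7-or-later material scored with dominant markers.
#'
#' @param genotypes numeric matrix, lines in rows and markers in columns;
#'   values must be 0, 1 or `NA`.
#' @param line_ids character vector of unique line identifiers; defaults to
#'   the rownames of `genotypes`.
#' @param marker_ids character vector of unique marker identifiers; defaults
#'   to the colnames of `genotypes`.
#' @param population_id single string naming the population.
#'
#' @return An object of class `marker_matrix`: the genotype matrix with
#'   `line_ids` as rownames, `marker_ids` as colnames and a `population_id`
#'   attribute.
#' @export
marker_matrix <- function(genotypes, line_ids = rownames(genotypes),
                          marker_ids = colnames(genotypes),
                          population_id = "pop") {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (is.null(line_ids) || is.null(marker_ids)) {
    stop("line_ids and marker_ids are required (or set dimnames on genotypes)")
  }
  line_ids <- as.character(line_ids)
  marker_ids <- as.character(marker_ids)
  if (nrow(genotypes) != length(line_ids) ||
      ncol(genotypes) != length(marker_ids)) {
    stop("genotype matrix shape does not match id lengths")
  }
  if (anyDuplicated(line_ids)) {
    stop("duplicate line ids: ", paste(unique(line_ids[duplicated(line_ids)]),
                                       collapse = ", "))
  }
  if (anyDuplicated(marker_ids)) {
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  }
  bad <- !is.na(genotypes) & !(genotypes %in% c(0, 1))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("genotype values must be 0, 1 or missing; found %g at line '%s', marker '%s'",
                 genotypes[idx[1], idx[2]], line_ids[idx[1]], marker_ids[idx[2]]))
  }
  dimnames(genotypes) <- list(line_ids, marker_ids)
  structure(genotypes, class = c("marker_matrix", "matrix", "array"),
            population_id = as.character(population_id)[1])
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix '%s': %d lines x %d markers (%.1f%% missing)\n",
              attr(x, "population_id"), nrow(x), ncol(x),
              100 * mean(is.na(unclass(x)))))
  invisible(x)
}

#' @rdname marker_matrix
#' @param x object to test or subset.
#' @export
is_marker_matrix <- function(x) inherits(x, "marker_matrix")

#' @export
`[.marker_matrix` <- function(x, i, j, ..., drop = FALSE) {
  pop <- attr(x, "population_id")
  out <- NextMethod(drop = FALSE)
  structure(out, class = c("marker_matrix", "matrix", "array"),
            population_id = pop)
}

line_ids <- function(m) rownames(m)
marker_ids <- function(m) colnames(m)

#' Read a genotype matrix from delimited text
#'
#' Expects a header row of marker ids and a first column of line ids.  The
#' delimiter is detected from the file extension (`.csv` is comma, anything
#' else tab) unless given explicitly.
#'
#' @param path file path.
#' @param missing_token string standing for a missing call (default `"NA"`).
#' @param population_id population label attached to the result; defaults to
#'   the file name without extension.
#' @param sep field delimiter, `"\t"` or `","`; `NULL` to detect.
#' @return A [marker_matrix()].
#' @export
read_genotype_matrix <- function(path, missing_token = "NA",
                                 population_id = NULL, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", na.strings = character())
  if (ncol(df) < 2) stop("genotype file needs a line-id column and >=1 marker")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  vals[vals == missing_token] <- NA
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- (is.na(num) & !is.na(vals)) | (!is.na(num) & !(num %in% c(0, 1)))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid genotype value '%s' at line '%s', marker '%s'",
                 vals[idx[1], idx[2]], ids[idx[1]],
                 colnames(df)[-1][idx[2]]))
  }
  if (is.null(population_id)) {
    population_id <- sub("\\.[^.]*$", "", basename(path))
  }
  marker_matrix(num, line_ids = ids, marker_ids = colnames(df)[-1],
                population_id = population_id)
}

#' Write a genotype matrix to delimited text
#'
#' @param m a [marker_matrix()].
#' @param path output file path.
#' @param missing_token string written for missing calls.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_genotype_matrix <- function(m, path, missing_token = "NA", sep = "\t") {
  stopifnot(is_marker_matrix(m))
  vals <- unclass(m)
  out <- cbind(line = rownames(vals),
               as.data.frame(ifelse(is.na(vals), missing_token,
                                    format(vals, trim = TRUE, digits = 15))))
  colnames(out) <- c("line", colnames(vals))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Impute missing genotype calls by the marker mean
#'
#' Each missing call is replaced by the mean of the non-missing calls at that
#' marker (the marker's allele frequency under 0/1 coding).  Markers with no
#' observed calls at all carry no information and are dropped with a warning.
#'
#' @param m a [marker_matrix()].
#' @return A [marker_matrix()] without missing values.  Imputed values are
#'   fractional, so downstream code must not assume strict 0/1 coding after
#'   imputation.
#' @export
impute_missing <- function(m) {
  stopifnot(is_marker_matrix(m))
  vals <- unclass(m)
  all_na <- colSums(!is.na(vals)) == 0
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " marker(s) with no observed calls: ",
            paste(utils::head(colnames(vals)[all_na], 5), collapse = ", "))
    vals <- vals[, !all_na, drop = FALSE]
  }
  nas <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- colMeans(vals, na.rm = TRUE)
    vals[nas] <- mu[nas[, 2]]
  }
  structure(vals, class = class(m), population_id = attr(m, "population_id"))
}

#' Restrict several populations to their shared markers
#'
#' Returns the input matrices restricted to the markers present in all of
#' them, in one common column order, so that marker effects estimated in one
#' population can be applied to another.
#'
#' @param matrices list of [marker_matrix()] objects (at least two).
#' @return A list of [marker_matrix()] objects with identical `marker_ids`.
#' @export
intersect_markers <- function(matrices) {
  stopifnot(length(matrices) >= 2, all(vapply(matrices, is_marker_matrix,
                                              logical(1))))
  common <- Reduce(intersect, lapply(matrices, colnames))
  if (length(common) == 0) stop("no markers are shared by all populations")
  lapply(matrices, function(m) m[, common])
}
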