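#' Genetic map
#'
#' Marker positions in centimorgans, chromosome-local and measured from the
#' chromosome start.  Stored as a data frame with columns `marker`,
#' `chromosome` and `position_cM`, sorted by chromosome then position.
#'
#' @param marker character vector of unique marker ids.
#' @param chromosome character (or coercible) chromosome labels.
#' @param position_cM non-negative numeric positions in cM.
#' @return A data frame of class `genetic_map`.
#' @export
genetic_map <- function(marker, chromosome, position_cM) {
  marker <- as.character(marker)
  chromosome <- as.character(chromosome)
  position_cM <- as.numeric(position_cM)
  if (anyDuplicated(marker)) stop("duplicate marker ids in map")
  if (any(is.na(position_cM)) || any(position_cM < 0)) {
    stop("map positions must be non-negative")
  }
  df <- data.frame(marker = marker, chromosome = chromosome,
                   position_cM = position_cM, stringsAsFactors = FALSE)
  df <- df[order(df$chromosome, df$position_cM, df$marker), ]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' @rdname genetic_map
#' @param x object to test.
#' @export
is_genetic_map <- function(x) inherits(x, "genetic_map")

#' Evenly spaced map over a model genome
#'
#' Builds a map of `n_markers` markers spread uniformly over a genome of
#' `n_chromosomes` chromosomes of equal length.  The default genome (21
#' chromosomes of 150 cM) mimics the hexaploid bread-wheat karyotype at the
#' coarse scale relevant to recombination counting and marker spacing.
#'
#' @param n_markers total number of markers.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_cM chromosome length in cM (equal for all).
#' @param prefix marker id prefix.
#' @return A [genetic_map()].
#' @export
uniform_map <- function(n_markers, n_chromosomes = 21, chrom_length_cM = 150,
                        prefix = "m") {
  stopifnot(n_markers >= n_chromosomes)
  per <- diff(round(seq(0, n_markers, length.out = n_chromosomes + 1)))
  chrom <- rep(paste0("chr", seq_len(n_chromosomes)), per)
  pos <- unlist(lapply(per, function(k) seq(0, chrom_length_cM,
                                            length.out = k)))
  genetic_map(sprintf("%s%04d", prefix, seq_len(n_markers)), chrom, pos)
}

#' Read/write a genetic map as tab-separated text
#'
#' The file has columns `marker`, `chromosome`, `position_cM`.
#'
#' @param path file path.
#' @return [read_genetic_map()] returns a [genetic_map()];
#'   [write_genetic_map()] returns `path` invisibly.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(df))) {
    stop("map file must have columns: ", paste(need, collapse = ", "))
  }
  genetic_map(df$marker, df$chromosome, df$position_cM)
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  stopifnot(is_genetic_map(map))
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
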