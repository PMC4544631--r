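#' Phenotype table for field trials with sub-block controls
#'
#' Plot-level trait records from an augmented field design: test lines sown
#' once, control cultivars repeated in every sub-block so that soil
#' heterogeneity can be estimated and removed.  Columns: `line`, `location`,
#' `sub_block`, `is_control` (logical), `trait`, `value`.
#'
#' @param line,location,sub_block,trait character vectors (recycled to a
#'   common length).
#' @param is_control logical vector flagging control-cultivar plots.
#' @param value numeric trait values in trait units (e.g. grain yield in
#'   t/ha, test weight in kg/hL, heading date in days).
#' @return A data frame of class `phenotype_table`.
#' @export
phenotype_table <- function(line, location, sub_block, is_control, trait,
                            value) {
  df <- data.frame(line = as.character(line),
                   location = as.character(location),
                   sub_block = as.character(sub_block),
                   is_control = as.logical(is_control),
                   trait = as.character(trait),
                   value = as.numeric(value), stringsAsFactors = FALSE)
  key <- with(df, paste(line, location, trait, sub_block, sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate record for the same line/location/trait/sub_block")
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' @rdname phenotype_table
#' @param x object to test.
#' @export
is_phenotype_table <- function(x) inherits(x, "phenotype_table")

#' Read/write a phenotype table as tab-separated text
#'
#' @param path file path.
#' @return [read_phenotype_table()] returns a [phenotype_table()];
#'   [write_phenotype_table()] returns `path` invisibly.
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("line", "location", "sub_block", "is_control", "trait", "value")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns: ", paste(need, collapse = ", "))
  }
  phenotype_table(df$line, df$location, df$sub_block, df$is_control,
                  df$trait, df$value)
}

#' @rdname read_phenotype_table
#' @param tab a [phenotype_table()].
#' @export
write_phenotype_table <- function(tab, path) {
  stopifnot(is_phenotype_table(tab))
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
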