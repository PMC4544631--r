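#' Adjust plot values for sub-block effects using repeated controls
#'
#' Fits the two-way fixed-effects model `Y_ij = mu + G_i + B_j + e_ij` by
#' least squares for one location and trait.  Because test lines are sown
#' once, sub-block effects are identified by the control cultivars repeated
#' in every sub-block.  Block effects are centered (sum-to-zero constraint)
#' and subtracted from the raw plot values; a line sown in several blocks
#' (a control) gets the mean of its adjusted plots.
#'
#' @param table a [phenotype_table()].
#' @param location location to adjust.
#' @param trait trait to adjust.
#' @return Data frame with columns `line`, `is_control`, `adjusted`.
#' @export
adjust_subblocks <- function(table, location, trait) {
  stopifnot(is_phenotype_table(table))
  d <- table[table$location == location & table$trait == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for location '", location,
                         "', trait '", trait, "'")
  blocks <- unique(d$sub_block)
  no_ctl <- blocks[!blocks %in% unique(d$sub_block[d$is_control])]
  if (length(no_ctl) > 0) {
    stop("sub-block(s) without control records: ",
         paste(no_ctl, collapse = ", "))
  }
  if (length(blocks) == 1) {
    adj <- d$value
  } else {
    line_f <- factor(d$line)
    block_f <- factor(d$sub_block)
    fit <- stats::lm(d$value ~ line_f + block_f)
    cf <- stats::coef(fit)
    b <- cf[paste0("block_f", levels(block_f))]
    b[is.na(b)] <- 0  # reference level and any aliased block
    names(b) <- levels(block_f)
    b <- b - mean(b)
    adj <- d$value - b[d$sub_block]
  }
  agg <- stats::aggregate(adj, list(line = d$line), mean)
  ctl <- stats::aggregate(d$is_control, list(line = d$line), any)
  data.frame(line = agg$line,
             is_control = ctl$x[match(agg$line, ctl$line)],
             adjusted = agg$x, stringsAsFactors = FALSE)
}

#' Across-location analysis of variance for adjusted line values
#'
#' Fits `Y_il = mu + G_i + Location_l + e_il` with random genotype effects
#' and fixed location effects.  On balanced data (every line observed once
#' at every location) variance components come from expected mean squares:
#' `sigma2_g = (MS_G - MS_E) / l`, with the genotype F test `MS_G / MS_E`.
#' Unbalanced data fall back to REML via [lme4::lmer()] (the F test is then
#' reported from the balanced approximation on the available cells and
#' should be read as indicative).  Negative moment estimates of `sigma2_g`
#' are truncated to zero and flagged.
#'
#' @param values data frame with columns `line`, `location`, `value`
#'   (typically the output of [adjust_subblocks()] stacked over locations).
#' @return An `anova_result`: list with `sigma2_g`, `sigma2_e`,
#'   `location_effects` (centered), `F_genotype`, `p_value`, `n_locations`,
#'   `truncated`, `method`.
#' @export
anova_locations <- function(values) {
  stopifnot(all(c("line", "location", "value") %in% names(values)))
  values <- values[stats::complete.cases(values[c("line", "location", "value")]), ]
  locs <- unique(values$location)
  if (length(locs) < 2) stop("at least two locations are required")
  tab <- table(values$line, values$location)
  balanced <- all(tab == 1)
  ell <- length(locs)
  loc_means <- tapply(values$value, values$location, mean)
  loc_eff <- stats::setNames(as.numeric(loc_means) - mean(loc_means),
                             names(loc_means))
  if (balanced) {
    fit <- stats::aov(value ~ factor(location) + factor(line), data = values)
    ss <- summary(fit)[[1]]
    ms_g <- ss["factor(line)", "Mean Sq"]
    ms_e <- ss["Residuals", "Mean Sq"]
    sigma2_g <- (ms_g - ms_e) / ell
    truncated <- sigma2_g < 0
    if (truncated) sigma2_g <- 0
    res <- list(sigma2_g = sigma2_g, sigma2_e = ms_e,
                location_effects = loc_eff,
                F_genotype = ms_g / ms_e,
                p_value = stats::pf(ms_g / ms_e,
                                    ss["factor(line)", "Df"],
                                    ss["Residuals", "Df"],
                                    lower.tail = FALSE),
                n_locations = ell, truncated = truncated, method = "moments")
  } else {
    fit <- lme4::lmer(value ~ factor(location) + (1 | line), data = values,
                      REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma2_g <- vc$vcov[vc$grp == "line"]
    sigma2_e <- vc$vcov[vc$grp == "Residual"]
    res <- list(sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                location_effects = loc_eff,
                F_genotype = NA_real_, p_value = NA_real_,
                n_locations = ell, truncated = FALSE, method = "REML")
  }
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("anova_result (%s): sigma2_g = %.4g, sigma2_e = %.4g, %d locations\n",
              x$method, x$sigma2_g, x$sigma2_e, x$n_locations))
  if (is.finite(x$F_genotype)) {
    cat(sprintf("  genotype F = %.3f (p = %.3g)\n", x$F_genotype, x$p_value))
  }
  invisible(x)
}

#' Line-mean heritability
#'
#' Entry-mean (line-mean) heritability over `l` locations:
#' `h2 = sigma2_g / (sigma2_g + sigma2_e / l)` — the repeatability of a line
#' mean computed over the trial locations, the standard plant-breeding scale
#' on which trial heritabilities are reported.
#'
#' @param a an `anova_result` from [anova_locations()].
#' @return Heritability in \[0, 1\].
#' @export
heritability_line_mean <- function(a) {
  stopifnot(inherits(a, "anova_result"))
  denom <- a$sigma2_g + a$sigma2_e / a$n_locations
  if (denom <= 0) stop("both variance components are zero; heritability undefined")
  a$sigma2_g / denom
}
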