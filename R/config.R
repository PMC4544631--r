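.default_config <- function() {
  list(
    output_dir = "crossgs_run",
    stages = c("simulate"),
    seed = 1,
    simulation = list(
      n_markers = 2500, n_chromosomes = 21, chrom_length_cM = 150,
      n_parents = 117, freq_dist = "beta", freq_shape = 0.2,
      freq_min = 0.1, freq_max = 0.9,
      n_crosses = 70, lines_per_cross_min = 4, lines_per_cross_max = 6,
      selfing_generations = 8,
      populations = list(list(id = "DH1", line_type = "DH"),
                         list(id = "RIL", line_type = "RIL")),
      n_qtl = 100, sigma_a = 1, h2 = 0.6
    ),
    gibbs = list(S_eps = 4.5, df_eps = 3, S_beta = 0.009, df_beta = 3,
                 h2_lambda = 0.37, burn_in = 20000, n_iter = 60000, thin = 1),
    cv = list(kind = "single", method = "ridge", train_fraction = 0.8,
              n_iterations = 200, training_populations = "DH1",
              validation_population = NULL),
    qtl_share = list(fractions = seq(0.1, 1, by = 0.1),
                     h2_levels = c(0.3, 0.6), n_reps = 50,
                     method = "ridge", scheme = "independent"),
    adjust = list(phenotype_file = NULL),
    log_level = "info"
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (path == "") key else paste0(path, "$", key)
    if (!key %in% names(defaults)) stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "populations") {
      if (!is.list(user[[key]])) stop("config key ", full, " must be a mapping")
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a run configuration
#'
#' Reads a YAML configuration, checks every key against the documented
#' schema (misspelled keys are an error, not silently ignored) and fills in
#' defaults: full-length Gibbs chains (20,000 burn-in of 60,000), 80%/200
#' iteration cross-validation, 100 QTLs with shared fractions 10-100% at
#' heritabilities 0.3 and 0.6, and a two-population DH+RIL simulation.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- .merge_config(cfg, user)
  }
  structure(cfg, class = c("run_config", "list"))
}

#' Run the configured analysis pipeline
#'
#' Executes the stages named in `cfg$stages` in order: `"simulate"` (write
#' genotype/map/phenotype/truth files for the configured populations),
#' `"kinship"` (normalized IBS kinship and group summary), `"cv"`
#' (cross-validation per the `cv` block) and `"qtl_share"` (the shared-QTL
#' accuracy grid).  All outputs are plain TSV/JSON under `cfg$output_dir`,
#' plus a `manifest.json` recording seeds, the resolved configuration, file
#' checksums, stage timings and the package version, which is sufficient to
#' reproduce every deterministic output.
#'
#' @param cfg a `run_config` from [load_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("crossgs")),
                   seed = cfg$seed, config = unclass(cfg), stages = list(),
                   files = list())
  sims <- NULL
  for (stage in cfg$stages) {
    t0 <- Sys.time()
    if (stage == "simulate") {
      sims <- .stage_simulate(cfg)
      for (nm in names(sims$files)) manifest$files[[nm]] <- sims$files[[nm]]
    } else if (stage == "kinship") {
      if (is.null(sims)) sims <- .stage_simulate(cfg)
      K <- normalize_kinship(ibs_kinship(lapply(sims$pops, impute_missing)))
      ksum <- kinship_group_summary(K)
      kf <- file.path(cfg$output_dir, "kinship_group_summary.tsv")
      utils::write.table(ksum, kf, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$files$kinship_summary <- kf
    } else if (stage == "cv") {
      if (is.null(sims)) sims <- .stage_simulate(cfg)
      populations <- lapply(sims$pops, function(p)
        list(geno = p, pheno = sims$pheno[[attr(p, "population_id")]]))
      sc <- cv_scheme(cfg$cv$kind, cfg$cv$training_populations,
                      cfg$cv$validation_population,
                      cfg$cv$train_fraction, cfg$cv$n_iterations,
                      seed = cfg$seed)
      res <- run_cv(sc, populations, method = cfg$cv$method,
                    cfg = do.call(gibbs_config, c(cfg$gibbs,
                                                  list(seed = cfg$seed))))
      cf <- file.path(cfg$output_dir, "cv_result.tsv")
      utils::write.table(data.frame(iteration = seq_along(res$per_iteration_r),
                                    r = res$per_iteration_r),
                         cf, sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(mean_r = res$mean_r, sd_r = res$sd_r,
                                method = res$method, kind = sc$kind),
                           file.path(cfg$output_dir, "cv_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      manifest$files$cv_result <- cf
    } else if (stage == "qtl_share") {
      if (is.null(sims)) sims <- .stage_simulate(cfg)
      if (length(sims$pops) < 2) stop("qtl_share needs two populations")
      tab <- qtl_sharing_experiment(
        sims$pops[[1]], sims$pops[[2]],
        fractions = cfg$qtl_share$fractions,
        h2_levels = cfg$qtl_share$h2_levels,
        method = cfg$qtl_share$method, n_qtl = cfg$simulation$n_qtl,
        n_reps = cfg$qtl_share$n_reps, scheme = cfg$qtl_share$scheme,
        seed = cfg$seed)
      qf <- file.path(cfg$output_dir, "qtl_sharing.tsv")
      utils::write.table(tab, qf, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$files$qtl_sharing <- qf
    } else {
      stop("unknown stage: ", stage)
    }
    manifest$stages[[stage]] <- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  manifest$files <- lapply(manifest$files, function(f)
    list(path = f, md5 = unname(tools::md5sum(f))))
  mf <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

.stage_simulate <- function(cfg) {
  sm <- cfg$simulation
  map <- uniform_map(sm$n_markers, sm$n_chromosomes, sm$chrom_length_cM)
  spec <- if (sm$freq_dist == "beta") {
    list(dist = "beta", shape1 = sm$freq_shape, shape2 = sm$freq_shape)
  } else {
    list(dist = "uniform", min = sm$freq_min, max = sm$freq_max)
  }
  founders <- simulate_founders(sm$n_parents, map, spec, seed = cfg$seed)
  files <- list()
  mapf <- file.path(cfg$output_dir, "map.tsv")
  write_genetic_map(map, mapf)
  files$map <- mapf
  pops <- list(); pheno <- list()
  for (i in seq_along(sm$populations)) {
    ps <- sm$populations[[i]]
    plan <- random_cross_plan(
      founders, sm$n_crosses,
      lines_per_cross = sm$lines_per_cross_min:sm$lines_per_cross_max,
      line_type = ps$line_type,
      selfing_generations = sm$selfing_generations,
      seed = cfg$seed + i)
    pop <- simulate_population(founders, plan, seed = cfg$seed + 100 + i,
                               population_id = ps$id)
    pops[[ps$id]] <- pop
    gf <- file.path(cfg$output_dir, paste0("genotypes_", ps$id, ".tsv"))
    write_genotype_matrix(pop, gf)
    files[[paste0("genotypes_", ps$id)]] <- gf
  }
  # one architecture on markers polymorphic in every population
  poly <- Reduce(`&`, lapply(pops, function(p)
    apply(unclass(p), 2, stats::sd) > 0))
  arch <- draw_architecture(colnames(pops[[1]])[poly],
                            n_qtl = min(sm$n_qtl, sum(poly)),
                            sigma_a = sm$sigma_a, h2 = sm$h2,
                            seed = cfg$seed + 500)
  truth <- list(qtl_markers = arch$qtl_markers, effects = arch$effects,
                h2 = arch$h2)
  for (id in names(pops)) {
    y <- simulate_trait(pops[[id]], arch, seed = cfg$seed + 900 +
                          match(id, names(pops)))
    pheno[[id]] <- stats::setNames(as.numeric(y), names(y))
    tf <- file.path(cfg$output_dir, paste0("trait_", id, ".tsv"))
    utils::write.table(data.frame(line = names(y),
                                  value = as.numeric(y),
                                  genetic_value = attr(y, "genetic_value")),
                       tf, sep = "\t", quote = FALSE, row.names = FALSE)
    files[[paste0("trait_", id)]] <- tf
  }
  trf <- file.path(cfg$output_dir, "truth.json")
  jsonlite::write_json(truth, trf, digits = NA)
  files$truth <- trf
  list(pops = pops, pheno = pheno, arch = arch, files = files)
}
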