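#' Simulate inbred founder haplotypes
#'
#' Founders are fully inbred, so each parent carries a single haplotype.  A
#' per-marker allele frequency is first drawn from `freq_spec`, then each
#' parent's allele is Bernoulli with that frequency.  Drawing frequencies
#' marker-by-marker creates the mixture of common and rare presence alleles
#' typical of dominant marker panels scored across elite germplasm.
#'
#' @param n_parents number of founder parents (>= 2).
#' @param map a [genetic_map()]; founders carry one allele per mapped marker.
#' @param freq_spec list describing the founder allele-frequency
#'   distribution: `list(dist = "beta", shape1, shape2)` (default
#'   Beta(0.2, 0.2), a U-shaped spectrum typical of dominant marker panels:
#'   many markers near fixation, so a realistic share of the panel is
#'   monomorphic within any one population while roughly half the markers
#'   segregate in two populations drawn from overlapping parent sets),
#'   `list(dist = "uniform", min, max)` or `list(dist = "fixed", p)`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return A `founder_set`: list with `haplotypes` (parents x markers 0/1
#'   matrix, marker columns in map order), `map` and `allele_freq`.
#' @export
simulate_founders <- function(n_parents, map,
                              freq_spec = list(dist = "beta",
                                               shape1 = 0.2, shape2 = 0.2),
                              seed = NULL) {
  stopifnot(n_parents >= 2, is_genetic_map(map))
  if (!is.null(seed)) set.seed(seed)
  p <- switch(freq_spec$dist,
    beta    = stats::rbeta(nrow(map), freq_spec$shape1, freq_spec$shape2),
    uniform = stats::runif(nrow(map), freq_spec$min, freq_spec$max),
    fixed   = rep(freq_spec$p, nrow(map)),
    stop("unknown freq_spec dist: ", freq_spec$dist))
  hap <- matrix(stats::rbinom(n_parents * nrow(map), 1, rep(p, each = n_parents)),
                nrow = n_parents,
                dimnames = list(sprintf("P%03d", seq_len(n_parents)),
                                map$marker))
  structure(list(haplotypes = hap, map = map, allele_freq = p),
            class = "founder_set")
}

#' Restrict a founder set to a subset of parents
#'
#' Used to build related breeding populations: two populations whose
#' crossing plans draw from overlapping subsets of one founder panel share
#' part of their pedigree, which yields a common polymorphic marker set and
#' realistic between-population kinship.
#'
#' @param founders a `founder_set`.
#' @param parents character vector of parent ids or integer indices.
#' @return A `founder_set` containing only those parents.
#' @export
founder_subset <- function(founders, parents) {
  stopifnot(inherits(founders, "founder_set"))
  out <- founders
  out$haplotypes <- founders$haplotypes[parents, , drop = FALSE]
  if (nrow(out$haplotypes) < 2) stop("need at least two parents")
  out
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf("founder_set: %d parents x %d markers on %d chromosome(s)\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              length(unique(x$map$chromosome))))
  invisible(x)
}

# Per-chromosome layout used by the meiosis engine: column indices (in map
# order) and Haldane recombination fractions between adjacent markers,
# r = 0.5 * (1 - exp(-2d)) for d in Morgans.
.map_layout <- function(map, marker_ids) {
  if (!all(marker_ids %in% map$marker)) {
    miss <- setdiff(marker_ids, map$marker)
    stop("marker(s) not on map: ", paste(utils::head(miss, 5), collapse = ", "))
  }
  ord <- match(map$marker, marker_ids)
  keep <- !is.na(ord)
  chrom <- map$chromosome[keep]
  pos <- map$position_cM[keep]
  idx <- ord[keep]
  lapply(split(seq_along(idx), chrom), function(k) {
    o <- order(pos[k])
    list(cols = idx[k][o],
         r = 0.5 * (1 - exp(-2 * diff(pos[k][o]) / 100)))
  })
}

.gamete_from_layout <- function(hap_a, hap_b, layout) {
  g <- hap_a
  for (ch in layout) {
    xo <- stats::rbinom(length(ch$r), 1, ch$r)
    phase <- (cumsum(c(stats::rbinom(1, 1, 0.5), xo))) %% 2
    cols <- ch$cols
    g[cols] <- ifelse(phase == 0, hap_a[cols], hap_b[cols])
  }
  g
}

#' Produce one recombinant gamete from a pair of haplotypes
#'
#' Crossovers between adjacent markers occur with the Haldane map-function
#' probability `r = 0.5 * (1 - exp(-2d))` for map distance `d` in Morgans;
#' chromosomes segregate independently and the starting parental phase of
#' each chromosome is a fair coin.  No crossover interference is modelled.
#'
#' @param hap_a,hap_b binary haplotypes named by marker id.
#' @param map a [genetic_map()] covering those markers.
#' @return A binary haplotype of the same length.
#' @export
meiotic_gamete <- function(hap_a, hap_b, map) {
  stopifnot(length(hap_a) == length(hap_b), is_genetic_map(map))
  layout <- .map_layout(map, names(hap_a))
  .gamete_from_layout(hap_a, hap_b, layout)
}

#' Crossing plan for a multi-family population
#'
#' @param crosses data frame with columns `parent_a`, `parent_b`, `n_lines`.
#' @param line_type `"DH"` (doubled haploids: one meiosis, genome doubled) or
#'   `"RIL"` (recombinant inbred lines by single-seed descent).
#' @param selfing_generations number of selfing meioses for RILs (>= 1);
#'   ignored for DH.
#' @return A list of class `cross_plan`.
#' @export
cross_plan <- function(crosses, line_type = c("DH", "RIL"),
                       selfing_generations = 8) {
  line_type <- match.arg(line_type)
  crosses <- as.data.frame(crosses)
  stopifnot(all(c("parent_a", "parent_b", "n_lines") %in% names(crosses)),
            all(crosses$n_lines >= 1),
            all(crosses$parent_a != crosses$parent_b),
            selfing_generations >= 1)
  structure(list(crosses = crosses, line_type = line_type,
                 selfing_generations = as.integer(selfing_generations)),
            class = "cross_plan")
}

#' Draw a random crossing plan from a founder set
#'
#' Each cross takes two distinct parents at random and contributes a family
#' of `sample(lines_per_cross, 1)` lines, emulating a breeding program that
#' derives a handful of lines from each F1.
#'
#' @param founders a `founder_set` (or a character vector of parent ids).
#' @param n_crosses number of crosses.
#' @param lines_per_cross integer vector of allowed family sizes (default
#'   8:10 lines per F1).
#' @param line_type,selfing_generations passed to [cross_plan()].
#' @param seed integer seed.
#' @return A [cross_plan()].
#' @export
random_cross_plan <- function(founders, n_crosses, lines_per_cross = 8:10,
                              line_type = c("DH", "RIL"),
                              selfing_generations = 8, seed = NULL) {
  parents <- if (inherits(founders, "founder_set")) {
    rownames(founders$haplotypes)
  } else as.character(founders)
  if (!is.null(seed)) set.seed(seed)
  pairs <- t(replicate(n_crosses, sample(parents, 2)))
  cross_plan(data.frame(parent_a = pairs[, 1], parent_b = pairs[, 2],
                        n_lines = sample(rep(lines_per_cross, 2), n_crosses,
                                         replace = TRUE)),
             line_type = match.arg(line_type),
             selfing_generations = selfing_generations)
}

#' Simulate a DH or RIL population from founders and a crossing plan
#'
#' DH lines are made by drawing one meiotic gamete from the F1 of each cross
#' and doubling it, so the line genotype equals the gamete.  RIL lines follow
#' single-seed descent: the F1 is selfed for `selfing_generations`
#' generations, drawing two independent gametes per generation; any marker
#' still heterozygous after the last selfing is fixed by a fair coin.
#' Monomorphic markers are retained (they are dropped only when populations
#' are intersected or models are fitted on polymorphic subsets).
#'
#' @param founders a `founder_set` from [simulate_founders()].
#' @param plan a [cross_plan()].
#' @param seed integer seed.
#' @param population_id label for the resulting population.
#' @return A [marker_matrix()] with one row per line and a `pedigree`
#'   attribute (data frame: line, parent_a, parent_b, cross index).
#' @export
simulate_population <- function(founders, plan, seed = NULL,
                                population_id = "simpop") {
  stopifnot(inherits(founders, "founder_set"), inherits(plan, "cross_plan"))
  if (!is.null(seed)) set.seed(seed)
  hap <- founders$haplotypes
  miss <- setdiff(unique(c(plan$crosses$parent_a, plan$crosses$parent_b)),
                  rownames(hap))
  if (length(miss) > 0) {
    stop("plan parents not in founder set: ", paste(miss, collapse = ", "))
  }
  layout <- .map_layout(founders$map, colnames(hap))
  n_total <- sum(plan$crosses$n_lines)
  geno <- matrix(NA_real_, n_total, ncol(hap),
                 dimnames = list(NULL, colnames(hap)))
  ped <- data.frame(line = character(n_total), parent_a = character(n_total),
                    parent_b = character(n_total), cross = integer(n_total),
                    stringsAsFactors = FALSE)
  row <- 0L
  for (k in seq_len(nrow(plan$crosses))) {
    pa <- hap[plan$crosses$parent_a[k], ]
    pb <- hap[plan$crosses$parent_b[k], ]
    for (j in seq_len(plan$crosses$n_lines[k])) {
      row <- row + 1L
      if (plan$line_type == "DH") {
        geno[row, ] <- .gamete_from_layout(pa, pb, layout)
      } else {
        h1 <- pa
        h2 <- pb
        for (gen in seq_len(plan$selfing_generations)) {
          new1 <- .gamete_from_layout(h1, h2, layout)
          new2 <- .gamete_from_layout(h1, h2, layout)
          h1 <- new1
          h2 <- new2
        }
        het <- h1 != h2
        res <- h1
        if (any(het)) {
          pick <- stats::rbinom(sum(het), 1, 0.5) == 1
          res[het] <- ifelse(pick, h1[het], h2[het])
        }
        geno[row, ] <- res
      }
      ped$line[row] <- sprintf("%s_c%02d_l%02d", population_id, k, j)
      ped$parent_a[row] <- plan$crosses$parent_a[k]
      ped$parent_b[row] <- plan$crosses$parent_b[k]
      ped$cross[row] <- k
    }
  }
  m <- marker_matrix(geno, line_ids = ped$line, marker_ids = colnames(hap),
                     population_id = population_id)
  attr(m, "pedigree") <- ped
  m
}

#' Count recombination breakpoints per line
#'
#' For each line, the parental origin of every marker where the two parents
#' differ is inferred and the number of origin switches along each
#' chromosome is counted.  On a fixed map, RILs accumulate roughly twice as
#' many observable breakpoints as DH lines from the same cross because every
#' selfing generation adds recombination until the genome fixes.
#'
#' @param m a [marker_matrix()] of inbred lines from a single cross.
#' @param hap_a,hap_b the parental haplotypes (named by marker id).
#' @param map a [genetic_map()].
#' @return Integer vector of breakpoint counts, one per line.
#' @export
count_breakpoints <- function(m, hap_a, hap_b, map) {
  stopifnot(is_marker_matrix(m))
  layout <- .map_layout(map, colnames(m))
  geno <- unclass(m)
  vapply(seq_len(nrow(geno)), function(i) {
    g <- geno[i, ]
    total <- 0L
    for (ch in layout) {
      cols <- ch$cols
      inf <- hap_a[cols] != hap_b[cols]
      if (sum(inf) < 2) next
      origin <- (g[cols][inf] == hap_b[cols][inf])
      total <- total + sum(diff(origin) != 0)
    }
    total
  }, integer(1))
}
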