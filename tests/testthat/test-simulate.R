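test_that("founder simulation is deterministic and matches its frequency spec", {
  map <- toy_map(100, n_chrom = 2)
  f1 <- simulate_founders(2, map, list(dist = "fixed", p = 0.5), seed = 3)
  f2 <- simulate_founders(2, map, list(dist = "fixed", p = 0.5), seed = 3)
  expect_identical(f1$haplotypes, f2$haplotypes)
  # expected Hamming distance between two parents at p = 0.5 is m/2
  dists <- replicate(200, {
    f <- simulate_founders(2, map, list(dist = "fixed", p = 0.5),
                           seed = sample.int(1e6, 1))
    sum(f$haplotypes[1, ] != f$haplotypes[2, ])
  })
  expect_gt(mean(dists), 45)  # binomial(100, 0.5) mean 50, MC band
  expect_lt(mean(dists), 55)
  # degenerate frequency 1 fixes the presence allele everywhere
  ff <- simulate_founders(3, map, list(dist = "fixed", p = 1), seed = 1)
  expect_true(all(ff$haplotypes == 1))
})

test_that("meiosis respects the Haldane map function", {
  # two markers at distance 0: always co-inherited
  map0 <- genetic_map(c("a", "b"), "1", c(5, 5))
  ha <- stats::setNames(c(0, 0), c("a", "b"))
  hb <- stats::setNames(c(1, 1), c("a", "b"))
  set.seed(1)
  g <- replicate(200, meiotic_gamete(ha, hb, map0))
  expect_true(all(g[1, ] == g[2, ]))

  # d = 10 cM: recombination fraction 0.5 * (1 - exp(-0.2)) = 0.0906
  map10 <- genetic_map(c("a", "b"), "1", c(0, 10))
  set.seed(2)
  g10 <- replicate(10000, meiotic_gamete(ha, hb, map10))
  rec <- mean(g10[1, ] != g10[2, ])
  expect_equal(rec, 0.5 * (1 - exp(-0.2)), tolerance = 0.12)

  # very large d: recombination fraction approaches 1/2
  mapL <- genetic_map(c("a", "b"), "1", c(0, 5000))
  set.seed(3)
  gL <- replicate(4000, meiotic_gamete(ha, hb, mapL))
  expect_equal(mean(gL[1, ] != gL[2, ]), 0.5, tolerance = 0.05)

  expect_error(meiotic_gamete(stats::setNames(0, "zz"),
                              stats::setNames(1, "zz"), map0),
               "not on map")
})

test_that("DH populations segregate correctly", {
  map <- toy_map(80, n_chrom = 2)
  f <- simulate_founders(4, map, seed = 5)
  # identical parents: no segregation, all lines equal the parent
  f$haplotypes[2, ] <- f$haplotypes[1, ]
  plan <- cross_plan(data.frame(parent_a = "P001", parent_b = "P002",
                                n_lines = 6), "DH")
  pop <- simulate_population(f, plan, seed = 6)
  expect_true(all(apply(unclass(pop), 1,
                        function(x) all(x == f$haplotypes[1, ]))))
  # line count matches the plan sum
  plan2 <- random_cross_plan(f, 3, 4:5, "DH", seed = 7)
  pop2 <- simulate_population(f, plan2, seed = 8)
  expect_identical(nrow(pop2), as.integer(sum(plan2$crosses$n_lines)))
  # segregation: at markers where parents differ, allele frequency ~ 0.5
  plan3 <- cross_plan(data.frame(parent_a = "P001", parent_b = "P003",
                                 n_lines = 400), "DH")
  pop3 <- simulate_population(f, plan3, seed = 9)
  seg <- f$haplotypes["P001", ] != f$haplotypes["P003", ]
  freqs <- colMeans(unclass(pop3)[, seg])
  expect_true(all(abs(freqs - 0.5) < 0.15))  # binomial(400, .5) band
})

test_that("RILs carry roughly twice the recombination of DH lines", {
  map <- uniform_map(1050, n_chromosomes = 21, chrom_length_cM = 150)
  f <- simulate_founders(2, map, list(dist = "fixed", p = 0.5), seed = 21)
  # fully informative cross: parents differ at every marker
  f$haplotypes[1, ] <- 0
  f$haplotypes[2, ] <- 1
  mk <- function(type) {
    plan <- cross_plan(data.frame(parent_a = "P001", parent_b = "P002",
                                  n_lines = 250), type,
                       selfing_generations = 8)
    simulate_population(f, plan, seed = if (type == "DH") 22 else 23)
  }
  dh <- mk("DH"); ril <- mk("RIL")
  ha <- f$haplotypes[1, ]; hb <- f$haplotypes[2, ]
  ratio <- mean(count_breakpoints(ril, ha, hb, map)) /
    mean(count_breakpoints(dh, ha, hb, map))
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.2)
})

test_that("simulating the same population twice with one seed is identical", {
  tp1 <- toy_population(seed = 99)
  tp2 <- toy_population(seed = 99)
  expect_identical(unclass(tp1$pop), unclass(tp2$pop))
})

test_that("overlapping founder panels yield a shared polymorphic marker set", {
  pair <- toy_population_pair()
  poly <- function(p) colnames(p)[apply(unclass(p), 2, sd) > 0]
  shared <- intersect(poly(pair$pop1), poly(pair$pop2))
  expect_gt(length(shared), 0.5 * ncol(pair$pop1))
})

test_that("architecture draws honor size, uniqueness and effect distribution", {
  mk <- sprintf("m%03d", 1:200)
  a <- draw_architecture(mk, n_qtl = 100, sigma_a = 1, seed = 1)
  expect_length(a$qtl_markers, 100)
  expect_false(anyDuplicated(a$qtl_markers) > 0)
  expect_error(draw_architecture(mk, n_qtl = 300), "exceeds")
  # exhaustive draw uses every marker
  a2 <- draw_architecture(mk, n_qtl = 200, seed = 2)
  expect_setequal(a2$qtl_markers, mk)
  # effects are centered with variance sigma_a^2 (law of large numbers)
  set.seed(3)
  eff <- unlist(replicate(60, draw_architecture(mk, 100, sigma_a = 2)$effects,
                          simplify = FALSE))
  expect_equal(mean(eff), 0, tolerance = 0.1)
  expect_equal(var(eff), 4, tolerance = 0.4)
})

test_that("shared_subsets controls subset size and expected overlap", {
  a <- draw_architecture(sprintf("m%03d", 1:150), 100, seed = 4)
  full <- shared_subsets(a, 1, seed = 5)
  expect_setequal(full$train$qtl_markers, a$qtl_markers)
  expect_setequal(full$valid$qtl_markers, a$qtl_markers)
  # fraction 0.5: each subset 50 QTLs, E|overlap| = 100 * 0.5 * 0.5 = 25
  set.seed(6)
  ov <- replicate(300, {
    s <- shared_subsets(a, 0.5)
    length(intersect(s$train$qtl_markers, s$valid$qtl_markers))
  })
  expect_equal(mean(ov), 25, tolerance = 1)
  # fraction 0.1: subsets of 10, hypergeometric E|overlap| = 1
  set.seed(7)
  ov10 <- replicate(400, {
    s <- shared_subsets(a, 0.1)
    length(intersect(s$train$qtl_markers, s$valid$qtl_markers))
  })
  expect_equal(mean(ov10), 1, tolerance = 0.35)
  # overlap scheme: valid is a subset of train with exact fraction
  s <- shared_subsets(a, 0.3, scheme = "overlap", seed = 8)
  expect_length(s$valid$qtl_markers, 30)
  expect_true(all(s$valid$qtl_markers %in% s$train$qtl_markers))
})

test_that("simulate_trait reaches the requested heritability", {
  tp <- toy_population(n_markers = 200, n_crosses = 12, seed = 31)
  poly <- colnames(tp$pop)[apply(unclass(tp$pop), 2, sd) > 0]
  arch <- draw_architecture(poly, n_qtl = 50, h2 = 1, seed = 32)
  y <- simulate_trait(tp$pop, arch)
  expect_identical(as.numeric(y), as.numeric(attr(y, "genetic_value")))
  # null architecture with h2 = 1 gives a constant phenotype
  arch0 <- arch; arch0$effects[] <- 0
  expect_true(sd(simulate_trait(tp$pop, arch0)) == 0)
  # zero genetic variance with h2 < 1 is an error
  arch0$h2 <- 0.5
  expect_error(simulate_trait(tp$pop, arch0), "zero")
  # realized h2 close to target on average
  arch6 <- arch; arch6$h2 <- 0.6
  set.seed(33)
  ratios <- replicate(80, {
    y <- simulate_trait(tp$pop, arch6)
    var(attr(y, "genetic_value")) / var(as.numeric(y))
  })
  expect_equal(mean(ratios), 0.6, tolerance = 0.04)
})
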