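test_that("generators are fully determined by (scenario, seed)", {
  sc <- preset_scenario("duplication", n = 50, dup_freq = 0.4)
  expect_identical(simulate_population(sc, seed = 5)$phenotypes,
                   simulate_population(sc, seed = 5)$phenotypes)
  expect_false(identical(simulate_population(sc, seed = 5)$phenotypes,
                         simulate_population(sc, seed = 6)$phenotypes))
  expect_identical(
    simulate_cross(G_WILD, G_HETDUP, 30, seed = 2)$phenotypes,
    simulate_cross(G_WILD, G_HETDUP, 30, seed = 2)$phenotypes)
  expect_identical(simulate_clone_reads(G_HETDUP, 10, 0.1, seed = 3),
                   simulate_clone_reads(G_HETDUP, 10, 0.1, seed = 3))
  qs <- qpcr_scenario(noise_sd = 0.05)
  expect_identical(simulate_qpcr(qs, seed = 4), simulate_qpcr(qs, seed = 4))
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_population(sc, seed = 5))
  expect_identical(runif(1), before)
})

test_that("presets encode the reference lineages", {
  rock <- simulate_population(preset_scenario("rockefeller", n = 20), seed = 1)
  expect_true(all(rock$phenotypes$call1011 == "Ile/Ile"))
  expect_true(all(rock$phenotypes$intron_call == "BB"))
  expect_true(all(rock$phenotypes$call1016 == "Val/Val"))
  ee <- simulate_population(preset_scenario("ee", n = 20), seed = 1)
  expect_true(all(ee$phenotypes$call1011 == "Ile/Met"))
  expect_true(all(ee$phenotypes$intron_call == "AB"))
})

test_that("random union of units matches its expectations", {
  # dup at 0.5: genotype classes 1/4 wild, 1/2 het-dup, 1/4 hom-dup; the
  # latter two are both typed Ile/Met, so E[Ile/Met] = 0.75, Met/Met = 0
  sim <- simulate_population(preset_scenario("duplication", n = 10000,
                                             dup_freq = 0.5), seed = 11)
  frac <- mean(sim$phenotypes$call1011 == "Ile/Met")
  expect_lt(abs(frac - 0.75), 0.02)
  expect_equal(sum(sim$phenotypes$call1011 == "Met/Met"), 0)
})

test_that("haplotype frequencies are recovered from simulated populations", {
  units <- lapply(canonical_haps, single_unit)
  truth <- c(0.5, 0.3, 0.2)
  sim <- simulate_population(population_scenario(units, truth, 10000),
                             seed = 21)
  counts <- population_counts(sim)
  est <- estimate_haplotype_frequencies(counts)
  expect_lt(max(abs(est - truth)), 0.02)
})

test_that("simulated crosses follow the gamete model", {
  off <- simulate_cross(G_HOMDUP, G_WILD, 20, seed = 31)
  expect_true(all(off$phenotypes$call1011 == "Ile/Met"))
  mono <- simulate_cross(G_WILD, G_WILD, 10, seed = 32)
  expect_equal(unique(mono$phenotypes$category), "IleIle_ValVal")
  f2 <- simulate_cross(G_HETDUP, G_HETDUP, 10000, seed = 33)
  expect_lt(abs(mean(f2$phenotypes$call1011 == "Ile/Ile") - 0.25), 0.02)
})

test_that("clone sampling covers a duplication carrier's three slots", {
  # single wild / dup genotype: slots IBV, IBV, MAV; with 9 error-free
  # clones both haplotypes are seen with probability ~0.974
  hits <- vapply(1:300, function(i) {
    recs <- simulate_clone_reads(G_HETDUP, 9, 0, seed = 4000 + i)
    keys <- unique(paste(recs$site1011, recs$intron, recs$site1016, sep = "+"))
    all(keys %in% c("Ile+B+Val", "Met+A+Val")) &&
      length(keys) == 2
  }, logical(1))
  expect_gte(mean(hits), 0.94)
  # error-free homozygote: all clones identical
  recs <- simulate_clone_reads(G_WILD, 12, 0, seed = 41)
  expect_equal(nrow(unique(recs[c("site1011", "intron", "site1016")])), 1)
})

test_that("noisy qPCR recovery matches Gaussian error propagation", {
  # With 3 assays x 3 replicates and per-well CT noise sd = 0.1, the mean
  # ddCT has sd sqrt(4 sd^2 / 9); integer recovery of c copies succeeds when
  # the log2 error lands inside (-log2(1 + 1/(2c)), -log2(1 - 1/(2c))].
  # That closed form is the oracle the Monte-Carlo estimate must match
  # (at 10 copies it is only ~0.72: exact recovery of high copy numbers at
  # this noise level is NOT near-certain).
  sd_well <- 0.1
  s <- sqrt(4 * sd_well^2 / 9)
  p_copy <- function(c) {
    stats::pnorm(-log2(1 - 1 / (2 * c)) / s) -
      stats::pnorm(-log2(1 + 1 / (2 * c)) / s)
  }
  predicted <- p_copy(2) * p_copy(6) * p_copy(10)
  sc <- qpcr_scenario(copies = c(Rock = 2, EE = 10, Hyb = 6),
                      noise_sd = sd_well)
  recov <- t(vapply(1:400, function(i) {
    pl <- analyze_plate(simulate_qpcr(sc, seed = 5000 + i))$per_lineage
    pl$cn[match(c("Rock", "EE", "Hyb"), pl$lineage)] == c(2L, 10L, 6L)
  }, logical(3)))
  mc_bound <- function(p) 3.5 * sqrt(p * (1 - p) / nrow(recov))
  expect_lt(abs(mean(rowSums(recov) == 3) - predicted), mc_bound(predicted))
  expect_gte(mean(recov[, 1]), 0.95)          # 2 copies: essentially always
  expect_lt(abs(mean(recov[, 2]) - p_copy(10)), mc_bound(p_copy(10)))
  expect_lt(abs(mean(recov[, 3]) - p_copy(6)), mc_bound(p_copy(6)))
  # all-calibrator plate: every ddct ~ 0
  sc0 <- qpcr_scenario(copies = c(Rock = 2, A = 2, B = 2), noise_sd = 0)
  res0 <- analyze_plate(simulate_qpcr(sc0, seed = 51))
  expect_equal(res0$per_assay$ddct, rep(0, 9), tolerance = 1e-12)
})

test_that("duplication scenarios regenerate the population signature", {
  # Met/Met phenotypes never occur when the only Met-bearing unit is the
  # duplication, and the Ile/Met excess is detectable by the HWE test
  haps2 <- c("Ile+B+Val", "Met+A+Val")
  n_rep <- 500
  reject <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    sim <- simulate_population(preset_scenario("duplication", n = 200,
                                               dup_freq = 0.3),
                               seed = 6000 + i)
    expect_equal(sum(sim$phenotypes$call1011 == "Met/Met"), 0)
    counts <- population_counts(sim, haps2)
    res <- analyze_population(counts, haps = haps2)
    reject[i] <- res$p < 0.05
  }
  expect_gte(mean(reject), 0.8)
})

test_that("classify_cross recovers the generating hypothesis", {
  # H2a broods point to H2a and reject H1/H2b; H1 broods leave H1 and H2b
  # indistinguishable (asserted as such)
  h2a <- cross_hypothesis("H2a")
  sim <- simulate_cross(h2a$parent1, h2a$parent2, 25, seed = 71)
  obs <- c(`Ile/Ile` = sum(sim$phenotypes$call1011 == "Ile/Ile"),
           `Ile/Met` = sum(sim$phenotypes$call1011 == "Ile/Met"))
  v <- classify_cross(obs)
  expect_equal(v$not_rejected, "H2a")
  h1 <- cross_hypothesis("H1")
  sim1 <- simulate_cross(h1$parent1, h1$parent2, 400, seed = 72)
  obs1 <- c(`Ile/Ile` = sum(sim1$phenotypes$call1011 == "Ile/Ile"),
            `Ile/Met` = sum(sim1$phenotypes$call1011 == "Ile/Met"))
  v1 <- classify_cross(obs1)
  expect_setequal(v1$not_rejected, c("H1", "H2b"))
  expect_equal(v1$hypotheses$H1$p, v1$hypotheses$H2b$p)
})

test_that("scenario validation rejects malformed inputs", {
  expect_error(population_scenario(list(dup_unit()), 0.9, 10), "sum to 1")
  expect_error(qpcr_scenario(copies = c(EE = 10)), "reference lineage")
  expect_error(simulate_clone_reads(G_WILD, 0, 0, seed = 1))
  expect_error(simulate_clone_reads(G_WILD, 5, 1, seed = 1))
})
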