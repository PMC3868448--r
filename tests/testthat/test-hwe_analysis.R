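test_that("largest-remainder count recovery reproduces published integers", {
  expect_equal(unname(counts_from_frequencies(
    c(0.056, 0, 0.222, 0.500, 0.222, 0), 18)), c(1L, 0L, 4L, 9L, 4L, 0L))
  expect_equal(unname(counts_from_frequencies(c(0.900, 0.100, 0), 20)),
               c(18L, 2L, 0L))
  expect_equal(unname(counts_from_frequencies(c(1, 0), 5)), c(5L, 0L))
  expect_error(counts_from_frequencies(c(0.5, 0.4), 10), "sum to")
  expect_error(counts_from_frequencies(c(0.5, 1.2), 10))
  # rounding slack up to 0.02 is tolerated (printed tables)
  expect_equal(sum(counts_from_frequencies(c(0.313, 0.688, 0), 16)), 16)
})

test_that("gene counting recovers haplotype frequencies", {
  f <- estimate_haplotype_frequencies(c(1, 0, 4, 9, 4, 0))
  expect_equal(unname(f), c(11, 12, 13) / 36, tolerance = 1e-12)
  expect_equal(names(f), c("Ile+B+Val", "Ile+A+Ile", "Met+A+Val"))
  f2 <- estimate_haplotype_frequencies(
    c(4, 12, 0), haps = c("Ile+B+Val", "Met+A+Val"))
  expect_equal(unname(f2), c(0.625, 0.375))
  f3 <- estimate_haplotype_frequencies(20, haps = "Ile+B+Val")
  expect_equal(unname(f3), 1)
  expect_error(estimate_haplotype_frequencies(c(0, 0, 0, 0, 0, 0)),
               "all category counts")
})

test_that("EM equals gene counting whenever phenotypes decode uniquely", {
  set.seed(421)
  for (rep in 1:25) {
    counts <- as.numeric(stats::rmultinom(1, sample(10:200, 1),
                                          prob = stats::runif(6, 0.01, 1)))
    if (sum(counts) == 0) next
    gc <- estimate_haplotype_frequencies(counts, method = "gene-counting")
    em <- estimate_haplotype_frequencies(counts, method = "em")
    expect_equal(gc, em, tolerance = 1e-9)
  }
  # two-haplotype model too
  gc <- estimate_haplotype_frequencies(c(13, 7, 0),
                                       haps = c("Ile+B+Val", "Met+A+Val"),
                                       method = "gene-counting")
  em <- estimate_haplotype_frequencies(c(13, 7, 0),
                                       haps = c("Ile+B+Val", "Met+A+Val"),
                                       method = "em")
  expect_equal(gc, em, tolerance = 1e-9)
})

test_that("EM matches a direct likelihood maximiser on ambiguous models", {
  # with both Ile+A+Val and Ile+B+Val declared, several haplotype pairs
  # collapse into the same two-site category, so gene counting is undefined
  haps <- c("Ile+A+Val", "Ile+B+Val", "Ile+A+Ile")
  counts <- c(IleIle_ValVal = 30, IleIle_ValIle = 14, IleIle_IleIle = 6)
  expect_error(
    estimate_haplotype_frequencies(counts, haps, method = "gene-counting"),
    "unique pair")
  em <- estimate_haplotype_frequencies(counts, haps, method = "em")
  expect_equal(sum(em), 1, tolerance = 1e-9)
  # independent oracle: multinomial likelihood maximised numerically
  loglik <- function(theta) {
    p <- exp(c(theta, 0)); p <- p / sum(p)
    e1 <- (p[1] + p[2])^2          # any pair without 1016Ile
    e2 <- 2 * (p[1] + p[2]) * p[3] # het for 1016
    e3 <- p[3]^2
    -(30 * log(e1) + 14 * log(e2) + 6 * log(e3))
  }
  opt <- stats::optim(c(0, 0), loglik)
  p_hat <- exp(c(opt$par, 0)); p_hat <- p_hat / sum(p_hat)
  # the category likelihood only identifies p1 + p2 and p3
  expect_equal(unname(em[3]), p_hat[3], tolerance = 1e-4)
  expect_equal(unname(em[1] + em[2]), p_hat[1] + p_hat[2], tolerance = 1e-4)
})

test_that("HWE expected proportions match the published cells", {
  e <- expected_phenotype_frequencies(c(11, 12, 13) / 36)
  expect_equal(sum(e), 1, tolerance = 1e-12)
  # printed cells were computed from rounded inputs; agree to +/- 0.001
  expect_lt(max(abs(e - c(0.094, 0.204, 0.111, 0.221, 0.240, 0.130))), 1e-3)
  e2 <- expected_phenotype_frequencies(
    estimate_haplotype_frequencies(c(6, 14, 0),
                                   haps = c("Ile+B+Val", "Met+A+Val")))
  expect_equal(unname(e2), c(0.4225, 0.455, 0.1225), tolerance = 1e-12)
  e3 <- expected_phenotype_frequencies(c(1, 0, 0))
  expect_equal(unname(e3), c(1, 0, 0, 0, 0, 0))
})

test_that("chi-square goodness of fit reproduces published statistics", {
  counts <- c(1, 0, 4, 9, 4, 0)
  e <- expected_phenotype_frequencies(estimate_haplotype_frequencies(counts))
  gt <- hwe_chi_square(counts, e)
  expect_equal(round(gt$chi2, 1), 14.7)
  expect_equal(gt$df, 5)
  expect_equal(gt$p, 0.0119, tolerance = 0.02) # printed 0.0119; exact 0.0118
  sb <- analyze_population(c(15, 1, 0), haps = c("Ile+B+Val", "Met+A+Val"))
  expect_equal(round(sb$chi2, 2), 0.02)
  expect_equal(round(sb$p, 4), 0.9917)
  # observed exactly n * expected
  gt0 <- hwe_chi_square(c(25, 50, 25), c(0.25, 0.5, 0.25))
  expect_equal(gt0$chi2, 0)
  expect_equal(gt0$p, 1)
})

test_that("zero expectation with observations warns with infinite statistic", {
  expect_warning(gt <- hwe_chi_square(c(3, 7), c(0, 1)), "zero expectation")
  expect_identical(gt$chi2, Inf)
  expect_equal(gt$p, 0)
  # zero expected AND zero observed contributes 0 but keeps df
  gt2 <- hwe_chi_square(c(10, 10, 0), c(0.5, 0.5, 0))
  expect_equal(gt2$df, 2)
  expect_equal(gt2$chi2, 0)
})

test_that("analyze_population chains the pieces", {
  fr <- analyze_population(c(4, 12, 0), haps = c("Ile+B+Val", "Met+A+Val"))
  expect_equal(round(fr$chi2, 1), 5.8)
  expect_equal(fr$df, 2)
  expect_equal(round(fr$p, 4), 0.0561)
  sr <- analyze_population(c(13, 7, 0), haps = c("Ile+B+Val", "Met+A+Val"))
  expect_equal(round(sr$chi2, 1), 0.9)
  expect_equal(round(sr$p, 4), 0.6377)
  mono <- analyze_population(20, haps = "Ile+B+Val")
  expect_error(hwe_chi_square(20, 1), "k >= 2") # guard, single category
  expect_equal(mono$chi2, 0)
  # from printed frequencies
  ap <- analyze_population(freqs = c(0.056, 0, 0.222, 0.5, 0.222, 0), n = 18)
  expect_equal(round(ap$chi2, 1), 14.7)
})

test_that("the packaged population table reproduces the verifiable rows", {
  df <- read_population_csv(extdata("population_phenotype_frequencies.csv"))
  expect_equal(nrow(df), 22)
  tab <- hwe_table(df)
  row_of <- function(loc, st) which(tab$locality == loc & tab$status == st)
  got <- function(loc, st) tab$chi2[row_of(loc, st)]
  expect_equal(got("Aparecida de Goiania", "R"), 14.7)
  expect_equal(got("Fortaleza", "R"), 5.8)
  expect_equal(got("Fortaleza", "S"), 4.4)
  expect_equal(got("Maceio", "R"), 2.0)
  expect_equal(got("Maceio", "S"), 3.8)
  expect_equal(got("Macapa", "unclassified"), 5.8)
  expect_equal(got("Santa Rosa", "unclassified"), 0.9)
  expect_equal(round(attr(tab, "analyses")[[
    row_of("Santa Barbara", "unclassified")]]$chi2, 2), 0.02)
  ij <- attr(tab, "analyses")[[row_of("Ijui", "unclassified")]]
  expect_equal(round(ij$chi2, 2), 0.06)
  expect_equal(ij$df, 2) # printed df "5" contradicts its own p; follow p
  expect_equal(round(ij$p, 4), 0.9727)
  # two-site six-category rows carry df = 5
  expect_equal(tab$df[row_of("Uberaba", "R")], 5)
})
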