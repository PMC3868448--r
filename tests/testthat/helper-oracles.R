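# Independent oracles and shared fixtures for the test suite.

# Brute-force two-sided Fisher p for a 2x2 table: enumerate the full
# hypergeometric support, compute each table's point probability from
# binomial coefficients, and sum those not exceeding the observed table's.
# Deliberately written from first principles, independent of the package's
# dhyper-based implementation.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + c; n <- b + d; k <- a + b
  total <- choose(m + n, k)
  prob_of <- function(x) choose(m, x) * choose(n, k - x) / total
  p_obs <- prob_of(a)
  support <- max(0, k - n):min(k, m)
  sum(vapply(support, prob_of, numeric(1))[
    vapply(support, prob_of, numeric(1)) <= p_obs * (1 + 1e-9)])
}

# The three canonical single-copy haplotypes behind the six-category table.
canonical_haps <- c("Ile+B+Val", "Ile+A+Ile", "Met+A+Val")

# Synthetic clone amplicon matching inst/extdata/synthetic_clone_rules.json:
# 1011 codon motif + intron filler (length encodes A/B) + 1016 codon motif.
synth_clone_rules <- function() {
  read_rules_json(system.file("extdata", "synthetic_clone_rules.json",
                              package = "navdup"))
}

synth_clone_seq <- function(hap) {
  if (is.character(hap)) hap <- parse_haplotype(hap)
  m1011 <- if (hap$site1011 == "Ile") "CATATTACG" else "CATATGACG"
  m1016 <- if (hap$site1016 == "Val") "TTGGTATCC" else "TTGATTTCC"
  filler <- strrep("T", if (hap$intron == "B") 50 else 20)
  paste0(m1011, filler, m1016)
}

extdata <- function(name) system.file("extdata", name, package = "navdup")

# Quick builders.
HAP_IBV <- parse_haplotype("Ile+B+Val")
HAP_IAV <- parse_haplotype("Ile+A+Val")
HAP_IAI <- parse_haplotype("Ile+A+Ile")
HAP_MAV <- parse_haplotype("Met+A+Val")
G_WILD <- genotype(single_unit("Ile+B+Val"), single_unit("Ile+B+Val"))
G_HETDUP <- genotype(single_unit("Ile+B+Val"), dup_unit())
G_HOMDUP <- genotype(dup_unit(), dup_unit())
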