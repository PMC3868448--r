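# Seeded generators for every input the pipeline consumes: random-union
# diploid populations over declared chromosome units, Mendelian crosses,
# clone sampling with error, and qPCR CT tables.  All outputs are fully
# determined by (scenario, seed).

#' Define a population scenario
#'
#' A population is specified by the frequencies of its transmissible
#' chromosome units; individuals are formed by random union (the
#' Hardy-Weinberg null over units, which is what the phenotype-table
#' analysis assumes for single units and what the duplication breaks at the
#' phenotype level).
#'
#' @param units A list of `nav_unit` objects.
#' @param freqs Numeric proportions, same length, summing to 1 (tolerance
#'   1e-9).
#' @param n Number of individuals.
#' @return A list of class `nav_pop_scenario`.
#' @export
population_scenario <- function(units, freqs, n) {
  if (inherits(units, "nav_unit")) units <- list(units)
  stopifnot(length(units) == length(freqs), n > 0)
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9) {
    stop("unit frequencies must be non-negative and sum to 1")
  }
  structure(list(units = units, freqs = freqs, n = as.integer(n)),
            class = "nav_pop_scenario")
}

#' Preset population scenarios
#'
#' `"rockefeller"`: monomorphic wild-type 1011Ile+B+1016Val (the insecticide
#' susceptibility reference strain).  `"ee"`: fixed for the duplicated unit
#' (the deltamethrin-selected lineage, homozygous for the duplication).
#' `"duplication"`: the duplicated unit at frequency `dup_freq` against the
#' single wild haplotype -- the minimal scenario showing the heterozygote
#' excess / missing Met-homozygote signature.
#'
#' @param name Preset name.
#' @param n Individuals.
#' @param dup_freq Duplicated-unit frequency for the `"duplication"` preset.
#' @return A `nav_pop_scenario`.
#' @export
preset_scenario <- function(name = c("rockefeller", "ee", "duplication"),
                            n = 100L, dup_freq = 0.5) {
  name <- match.arg(name)
  wild <- single_unit("Ile+B+Val")
  switch(name,
    rockefeller = population_scenario(list(wild), 1, n),
    ee = population_scenario(list(dup_unit()), 1, n),
    duplication = population_scenario(list(wild, dup_unit()),
                                      c(1 - dup_freq, dup_freq), n)
  )
}

#' Simulate a diploid population by random union of units
#'
#' @param scenario A `nav_pop_scenario`.
#' @param seed Integer seed; the output is fully determined by
#'   (scenario, seed).
#' @return A list with `genotypes` (list of `nav_genotype`) and `phenotypes`
#'   (data frame with `call1011`, `intron_call`, `call1016`, `category`).
#' @examples
#' sim <- simulate_population(preset_scenario("duplication", n = 50), seed = 1)
#' table(sim$phenotypes$call1011)
#' @export
simulate_population <- function(scenario, seed) {
  stopifnot(inherits(scenario, "nav_pop_scenario"))
  withr::with_seed(as.integer(seed), {
    k <- length(scenario$units)
    i1 <- sample.int(k, scenario$n, replace = TRUE, prob = scenario$freqs)
    i2 <- sample.int(k, scenario$n, replace = TRUE, prob = scenario$freqs)
    genotypes <- lapply(seq_len(scenario$n), function(i) {
      genotype(scenario$units[[i1[i]]], scenario$units[[i2[i]]])
    })
    phen <- lapply(genotypes, phenotype_of)
    list(
      genotypes = genotypes,
      phenotypes = data.frame(
        call1011 = vapply(phen, `[[`, character(1), "call1011"),
        intron_call = vapply(phen, `[[`, character(1), "intron_call"),
        call1016 = vapply(phen, `[[`, character(1), "call1016"),
        category = vapply(phen, category_of, character(1)),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Category counts of a simulated population
#'
#' @param sim Output of [simulate_population()].
#' @param haps Declared haplotype set defining the category columns.
#' @return Named integer counts in category order, ready for
#'   [analyze_population()].  Phenotype categories outside the declared set
#'   raise an error (they falsify the declared model).
#' @export
population_counts <- function(sim, haps = .CANONICAL_HAPS) {
  cats <- enumerate_phenotype_categories(haps)
  seen <- table(sim$phenotypes$category)
  extra <- setdiff(names(seen), cats)
  if (length(extra)) {
    stop("phenotypes outside the declared category set: ",
         paste(extra, collapse = ", "))
  }
  out <- stats::setNames(integer(length(cats)), cats)
  out[names(seen)] <- as.integer(seen)
  out
}

#' Simulate offspring of a cross
#'
#' Each offspring receives one unit from each parent, drawn from
#' [gametes_of()].
#'
#' @param parent1,parent2 `nav_genotype` objects.
#' @param n_offspring Brood size.
#' @param seed Integer seed.
#' @return As [simulate_population()]: `genotypes` and `phenotypes`.
#' @export
simulate_cross <- function(parent1, parent2, n_offspring, seed) {
  stopifnot(n_offspring > 0)
  g1 <- gametes_of(parent1)
  g2 <- gametes_of(parent2)
  withr::with_seed(as.integer(seed), {
    pick <- function(g, n) {
      idx <- sample.int(length(g), n, replace = TRUE,
                        prob = vapply(g, `[[`, numeric(1), "prob"))
      lapply(idx, function(i) g[[i]]$unit)
    }
    u1 <- pick(g1, n_offspring)
    u2 <- pick(g2, n_offspring)
    genotypes <- lapply(seq_len(n_offspring), function(i) {
      genotype(u1[[i]], u2[[i]])
    })
    phen <- lapply(genotypes, phenotype_of)
    list(
      genotypes = genotypes,
      phenotypes = data.frame(
        call1011 = vapply(phen, `[[`, character(1), "call1011"),
        intron_call = vapply(phen, `[[`, character(1), "intron_call"),
        call1016 = vapply(phen, `[[`, character(1), "call1016"),
        category = vapply(phen, category_of, character(1)),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Simulate sequenced clones of one specimen's amplicons
#'
#' Each clone samples one haplotype uniformly from the haplotype *slots* of
#' the genotype (a single unit holds one slot, a duplicated unit two, so a
#' single/dup specimen yields its three haplotypes in 1:1:... proportion to
#' slot counts).  With probability `error_rate` a clone has one feature,
#' chosen uniformly, flipped to the other value -- a crude model of
#' PCR/cloning artefacts.
#'
#' @param g A `nav_genotype`.
#' @param n_clones Number of clones (>= 1; sequencing studies used >= 8).
#' @param error_rate Per-clone error probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param specimen Specimen id for the records.
#' @return A `nav_clone_records` data frame.
#' @export
simulate_clone_reads <- function(g, n_clones, error_rate = 0, seed,
                                 specimen = "S1") {
  stopifnot(n_clones >= 1L, error_rate >= 0, error_rate < 1)
  slots <- genotype_haplotypes(g)
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(length(slots), n_clones, replace = TRUE)
    haps <- lapply(idx, function(i) slots[[i]])
    err <- stats::runif(n_clones) < error_rate
    which_feat <- sample.int(3L, n_clones, replace = TRUE)
    for (i in which(err)) {
      h <- haps[[i]]
      flipped <- switch(which_feat[i],
        haplotype(setdiff(.ALLELES_1011, h$site1011), h$intron, h$site1016),
        haplotype(h$site1011, setdiff(.INTRON_TYPES, h$intron), h$site1016),
        haplotype(h$site1011, h$intron, setdiff(.ALLELES_1016, h$site1016))
      )
      haps[[i]] <- flipped
    }
    clone_records(specimen, seq_len(n_clones), haps)
  })
}

#' Define a qPCR plate scenario
#'
#' Emulates the published TaqMan design: several independent assays (one
#' pooled-larvae DNA extraction each), each measuring all lineages in
#' replicate wells for both target and reference genes.  CT noise is iid
#' Gaussian per well -- the simplest model consistent with observed
#' replicate SDs of 0.03--0.11 cycles.
#'
#' @param copies Named integer vector: true diploid target copies per
#'   lineage; must include the reference lineage (at `cn_ref` copies).
#' @param reference_lineage Calibrator lineage name (default `"Rock"`).
#' @param cn_ref Calibrator copies (default 2).
#' @param ct_baseline Mean reference-gene CT (default 22, a typical value
#'   for 20 ng genomic DNA).
#' @param dct_offset The calibrator's expected delta-CT (default 0;
#'   absorbs primer/probe efficiency differences between the two genes).
#' @param noise_sd Per-well Gaussian CT noise SD (default 0.05).
#' @param assays,replicates Plate layout (defaults 3 x 3, the published
#'   design).
#' @return A list of class `nav_qpcr_scenario`.
#' @export
qpcr_scenario <- function(copies = c(Rock = 2, EE = 10, Hyb = 6),
                          reference_lineage = "Rock", cn_ref = 2L,
                          ct_baseline = 22, dct_offset = 0,
                          noise_sd = 0.05, assays = 3L, replicates = 3L) {
  stopifnot(all(copies >= 1), noise_sd >= 0, assays >= 1, replicates >= 1)
  if (!reference_lineage %in% names(copies)) {
    stop("copies must include the reference lineage")
  }
  structure(list(copies = copies, reference_lineage = reference_lineage,
                 cn_ref = cn_ref, ct_baseline = ct_baseline,
                 dct_offset = dct_offset, noise_sd = noise_sd,
                 assays = as.integer(assays),
                 replicates = as.integer(replicates)),
            class = "nav_qpcr_scenario")
}

#' Simulate a qPCR plate
#'
#' Reference-gene wells get `ct_baseline + noise`; target wells get
#' `ct_baseline + dct_offset - log2(copies / cn_ref) + noise`, so the
#' calibrator lineage has expected delta-CT `dct_offset` and a lineage with
#' `c` copies has expected delta-delta-CT `-log2(c / cn_ref)` -- the model
#' [analyze_plate()] inverts.
#'
#' @param scenario A `nav_qpcr_scenario`.
#' @param seed Integer seed.
#' @return A long-format data frame as consumed by [analyze_plate()].
#' @examples
#' m <- simulate_qpcr(qpcr_scenario(noise_sd = 0), seed = 1)
#' analyze_plate(m)$per_lineage$cn # 2, 10, 6
#' @export
simulate_qpcr <- function(scenario, seed) {
  stopifnot(inherits(scenario, "nav_qpcr_scenario"))
  s <- scenario
  withr::with_seed(as.integer(seed), {
    grid <- expand.grid(
      replicate = seq_len(s$replicates),
      lineage = names(s$copies),
      assay = seq_len(s$assays),
      stringsAsFactors = FALSE
    )
    n <- nrow(grid)
    mu_target <- s$ct_baseline + s$dct_offset -
      log2(s$copies[grid$lineage] / s$cn_ref)
    ct_ref <- s$ct_baseline + stats::rnorm(n, 0, s$noise_sd)
    ct_tgt <- mu_target + stats::rnorm(n, 0, s$noise_sd)
    rbind(
      data.frame(lineage = grid$lineage, assay = grid$assay,
                 replicate = grid$replicate, gene = "target", ct = ct_tgt,
                 row.names = NULL),
      data.frame(lineage = grid$lineage, assay = grid$assay,
                 replicate = grid$replicate, gene = "reference", ct = ct_ref,
                 row.names = NULL)
    )
  })
}

#' Write a simulated population as a phenotype-count CSV
#'
#' Produces the dialect read by [read_population_csv()].
#'
#' @param sim Output of [simulate_population()].
#' @param path Output CSV path.
#' @param locality,status Labels for the single row.
#' @param haps Declared haplotype set for the category columns.
#' @return `path`, invisibly.
#' @export
write_population_csv <- function(sim, path, locality = "synthetic",
                                 status = "unclassified",
                                 haps = .CANONICAL_HAPS) {
  counts <- population_counts(sim, haps)
  row <- data.frame(locality = locality, status = status,
                    n = sum(counts), check.names = FALSE)
  for (cc in names(counts)) row[[paste0("count_", cc)]] <- counts[[cc]]
  utils::write.csv(row, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
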