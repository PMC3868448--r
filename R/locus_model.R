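#' @keywords internal
"_PACKAGE"

# Allowed feature values for the three haplotype-defining markers.
.ALLELES_1011 <- c("Ile", "Met")
.INTRON_TYPES <- c("A", "B")
.ALLELES_1016 <- c("Val", "Ile")

# The four haplotypes seen in Brazilian field samples; all others carry a
# warning flag but remain constructible so that model violations can be probed.
.OBSERVED_HAPLOTYPES <- c("Ile+B+Val", "Ile+A+Val", "Met+A+Val", "Ile+A+Ile")

#' Construct a sodium-channel haplotype
#'
#' A haplotype is the joint state of one gene copy at three markers of the
#' NaV IIS6 region: the amino acid at site 1011 (Ile or Met), the intron 20
#' sequence class (A or B), and the amino acid at site 1016 (Val or Ile).
#'
#' All eight combinations are constructible.  Haplotypes outside the four
#' classes observed in the field carry `observed_class = FALSE`; the double
#' mutant (1011Met together with 1016Ile) is additionally flagged
#' `model_excluded = TRUE` because the two resistance mutations arose
#' independently on non-recombining backgrounds, so the recombinant is not
#' part of the population model.  Flags never block construction.
#'
#' @param site1011 `"Ile"` or `"Met"`.
#' @param intron `"A"` or `"B"`.
#' @param site1016 `"Val"` or `"Ile"`.
#' @return An object of class `nav_haplotype`.
#' @examples
#' haplotype("Ile", "B", "Val")
#' haplotype("Met", "A", "Val")
#' @export
haplotype <- function(site1011, intron, site1016) {
  site1011 <- match.arg(site1011, .ALLELES_1011)
  intron <- match.arg(intron, .INTRON_TYPES)
  site1016 <- match.arg(site1016, .ALLELES_1016)
  h <- structure(
    list(site1011 = site1011, intron = intron, site1016 = site1016),
    class = "nav_haplotype"
  )
  h
}

#' Short key for a haplotype, e.g. `"Ile+B+Val"`
#' @param h A `nav_haplotype`.
#' @return A single string.
#' @export
hap_key <- function(h) {
  stopifnot(inherits(h, "nav_haplotype"))
  paste(h$site1011, h$intron, h$site1016, sep = "+")
}

#' Validity flags of a haplotype
#'
#' @param h A `nav_haplotype`.
#' @return A list with logical elements `observed_class` (one of the four
#'   field haplotypes) and `model_excluded` (the 1011Met + 1016Ile
#'   recombinant, excluded from the population model).
#' @export
hap_flags <- function(h) {
  stopifnot(inherits(h, "nav_haplotype"))
  list(
    observed_class = hap_key(h) %in% .OBSERVED_HAPLOTYPES,
    model_excluded = h$site1011 == "Met" && h$site1016 == "Ile"
  )
}

#' @export
format.nav_haplotype <- function(x, ...) {
  sprintf("1011%s+%s+1016%s", x$site1011, x$intron, x$site1016)
}

#' @export
print.nav_haplotype <- function(x, ...) {
  flags <- hap_flags(x)
  cat("<haplotype>", format(x))
  if (!flags$observed_class) cat(" [unobserved class]")
  if (flags$model_excluded) cat(" [model-excluded recombinant]")
  cat("\n")
  invisible(x)
}

#' Parse a haplotype string
#'
#' Accepts the canonical syntax `"1011Ile+B+1016Val"` (case-insensitive) and
#' the short form `"Ile+B+Val"`.
#'
#' @param x A character vector.
#' @return A `nav_haplotype` for length-1 input, else a list of them.
#' @export
parse_haplotype <- function(x) {
  parse1 <- function(s) {
    parts <- strsplit(trimws(s), "+", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      stop("haplotype string must have three '+'-separated fields: ", s)
    }
    norm <- function(p, choices, prefix) {
      p <- sub(paste0("(?i)^", prefix), "", trimws(p), perl = TRUE)
      i <- match(tolower(p), tolower(choices))
      if (is.na(i)) stop("cannot parse haplotype field '", p, "' in: ", s)
      choices[i]
    }
    haplotype(
      norm(parts[1], .ALLELES_1011, "1011"),
      norm(parts[2], .INTRON_TYPES, ""),
      norm(parts[3], .ALLELES_1016, "1016")
    )
  }
  out <- lapply(x, parse1)
  if (length(out) == 1L) out[[1]] else out
}

#' All eight constructible haplotypes
#' @return A list of `nav_haplotype`, observed classes first.
#' @export
all_haplotypes <- function() {
  grid <- expand.grid(
    site1016 = .ALLELES_1016, intron = .INTRON_TYPES,
    site1011 = .ALLELES_1011, stringsAsFactors = FALSE
  )
  haps <- lapply(seq_len(nrow(grid)), function(i) {
    haplotype(grid$site1011[i], grid$intron[i], grid$site1016[i])
  })
  obs <- vapply(haps, function(h) hap_flags(h)$observed_class, logical(1))
  c(haps[obs], haps[!obs])
}

#' Construct a transmissible chromosome unit
#'
#' A unit is what one parent passes on intact: either a single haplotype or
#' a tandem duplication carrying two haplotypes in complete linkage.  The
#' within-pair order of a duplicated unit is stored but never used (which
#' copy is upstream is unknown).
#'
#' @param ... One (`single`) or two (`duplicated`) `nav_haplotype` objects,
#'   or strings parseable by [parse_haplotype()].
#' @return An object of class `nav_unit` with fields `kind` and `haplotypes`.
#' @examples
#' single_unit("Ile+B+Val")
#' dup_unit() # the default duplication: 1011Ile+B+1016Val / 1011Met+A+1016Val
#' @export
chromosome_unit <- function(...) {
  haps <- lapply(list(...), function(h) {
    if (is.character(h)) parse_haplotype(h) else h
  })
  if (!all(vapply(haps, inherits, logical(1), "nav_haplotype"))) {
    stop("all arguments must be haplotypes or haplotype strings")
  }
  if (!length(haps) %in% 1:2) {
    stop("a chromosome unit holds 1 (single) or 2 (duplicated) haplotypes")
  }
  structure(
    list(
      kind = if (length(haps) == 1L) "single" else "duplicated",
      haplotypes = haps
    ),
    class = "nav_unit"
  )
}

#' @rdname chromosome_unit
#' @param h A haplotype or haplotype string.
#' @export
single_unit <- function(h) chromosome_unit(h)

#' @rdname chromosome_unit
#' @param h1,h2 The two linked haplotypes of the duplication.  Defaults give
#'   the duplication proposed for Brazilian populations: wild-type
#'   1011Ile+B+1016Val linked to mutant 1011Met+A+1016Val.
#' @export
dup_unit <- function(h1 = "Ile+B+Val", h2 = "Met+A+Val") {
  chromosome_unit(h1, h2)
}

#' Order-insensitive identity key of a chromosome unit
#' @param u A `nav_unit`.
#' @return A single string; duplicated units sort their pair so the key does
#'   not depend on the (unknown) upstream/downstream order.
#' @export
unit_key <- function(u) {
  stopifnot(inherits(u, "nav_unit"))
  keys <- sort(vapply(u$haplotypes, hap_key, character(1)))
  if (u$kind == "single") keys else paste0("dup[", paste(keys, collapse = "; "), "]")
}

#' @export
format.nav_unit <- function(x, ...) unit_key(x)

#' @export
print.nav_unit <- function(x, ...) {
  cat("<chromosome unit>", unit_key(x), "\n")
  invisible(x)
}

#' Construct a diploid genotype
#'
#' An unordered pair of chromosome units.  Equality (via [genotype_key()])
#' ignores both the order of the two units and the within-pair order of any
#' duplication.
#'
#' @param u1,u2 `nav_unit` objects (or haplotype strings, taken as single
#'   units).
#' @return An object of class `nav_genotype`.
#' @examples
#' genotype(single_unit("Ile+B+Val"), dup_unit())
#' @export
genotype <- function(u1, u2) {
  as_unit <- function(u) {
    if (is.character(u) || inherits(u, "nav_haplotype")) single_unit(u) else u
  }
  u1 <- as_unit(u1); u2 <- as_unit(u2)
  stopifnot(inherits(u1, "nav_unit"), inherits(u2, "nav_unit"))
  structure(list(units = list(u1, u2)), class = "nav_genotype")
}

#' @rdname genotype
#' @param g A `nav_genotype`.
#' @export
genotype_key <- function(g) {
  stopifnot(inherits(g, "nav_genotype"))
  paste(sort(vapply(g$units, unit_key, character(1))), collapse = " / ")
}

#' @export
format.nav_genotype <- function(x, ...) genotype_key(x)

#' @export
print.nav_genotype <- function(x, ...) {
  cat("<genotype>", genotype_key(x), "\n")
  invisible(x)
}

# All haplotypes present in a genotype (a duplicated unit contributes both).
genotype_haplotypes <- function(g) {
  stopifnot(inherits(g, "nav_genotype"))
  unlist(lapply(g$units, function(u) u$haplotypes), recursive = FALSE)
}

#' Construct a molecular phenotype
#'
#' The AS-PCR/intron-PCR observable: for each marker, the unordered set of
#' variants present in the insect, blind to dosage.  This masking is the
#' crux of duplication detection: a duplication carrying both 1011 alleles
#' is typed Ile/Met, indistinguishable from a true heterozygote.
#'
#' @param call1011 One of `"Ile/Ile"`, `"Ile/Met"`, `"Met/Met"`.
#' @param intron_call One of `"AA"`, `"AB"`, `"BB"`.
#' @param call1016 One of `"Val/Val"`, `"Val/Ile"`, `"Ile/Ile"`.
#' @return An object of class `nav_phenotype`.
#' @export
molecular_phenotype <- function(call1011, intron_call, call1016) {
  call1011 <- match.arg(call1011, c("Ile/Ile", "Ile/Met", "Met/Met"))
  intron_call <- match.arg(intron_call, c("AA", "AB", "BB"))
  call1016 <- match.arg(call1016, c("Val/Val", "Val/Ile", "Ile/Ile"))
  structure(
    list(call1011 = call1011, intron_call = intron_call, call1016 = call1016),
    class = "nav_phenotype"
  )
}

#' @export
format.nav_phenotype <- function(x, ...) {
  paste(x$call1011, x$intron_call, x$call1016, sep = " + ")
}

#' @export
print.nav_phenotype <- function(x, ...) {
  cat("<molecular phenotype>", format(x), "\n")
  invisible(x)
}

#' Parse a phenotype string such as `"Ile/Met + AB + Val/Val"`
#' @param x A single string.
#' @return A `nav_phenotype`.
#' @export
parse_phenotype <- function(x) {
  parts <- trimws(strsplit(x, "+", fixed = TRUE)[[1]])
  if (length(parts) != 3L) stop("phenotype string needs 3 '+' fields: ", x)
  molecular_phenotype(parts[1], parts[2], parts[3])
}

# Presence/absence call from a set of values, in canonical display order.
.pair_call <- function(values, order) {
  present <- order[order %in% values]
  if (length(present) == 1L) present <- c(present, present)
  paste(present[1], present[2], sep = "/")
}

#' Molecular phenotype of a genotype
#'
#' Applies the AS-PCR masking operator: each call is the set of distinct
#' variants present across *all* haplotypes of both chromosome units (a
#' duplicated unit contributes both of its haplotypes); copy dosage is
#' discarded.  Consequently `dup/dup` and `dup/single-wild` genotypes yield
#' the same Ile/Met phenotype as an ordinary heterozygote.
#'
#' @param g A `nav_genotype`.
#' @return A `nav_phenotype`.
#' @examples
#' phenotype_of(genotype(single_unit("Ile+B+Val"), dup_unit()))
#' @export
phenotype_of <- function(g) {
  haps <- genotype_haplotypes(g)
  molecular_phenotype(
    .pair_call(vapply(haps, `[[`, character(1), "site1011"), .ALLELES_1011),
    {
      it <- sort(unique(vapply(haps, `[[`, character(1), "intron")))
      if (length(it) == 1L) paste0(it, it) else "AB"
    },
    .pair_call(vapply(haps, `[[`, character(1), "site1016"), .ALLELES_1016)
  )
}

#' Gamete (transmitted unit) distribution of a genotype
#'
#' Each of the two chromosome units is transmitted with probability 1/2; a
#' duplicated unit is transmitted intact (complete linkage).  Identical
#' units collapse to a single outcome with probability 1.
#'
#' @param g A `nav_genotype`.
#' @return A list of `list(unit =, prob =)` entries; probabilities sum to 1.
#' @export
gametes_of <- function(g) {
  stopifnot(inherits(g, "nav_genotype"))
  k1 <- unit_key(g$units[[1]])
  k2 <- unit_key(g$units[[2]])
  if (k1 == k2) {
    list(list(unit = g$units[[1]], prob = 1))
  } else {
    list(
      list(unit = g$units[[1]], prob = 0.5),
      list(unit = g$units[[2]], prob = 0.5)
    )
  }
}

# Canonical six-category order of two-site phenotype classes (intron call is
# reported separately): columns of the population frequency table.
.CATEGORY_ORDER <- c(
  "IleIle_ValVal", "IleIle_ValIle", "IleIle_IleIle",
  "IleMet_ValVal", "IleMet_ValIle", "MetMet_ValVal"
)

#' Two-site category code of a phenotype
#'
#' Categories are defined on the 1011 and 1016 calls only; the intron call
#' is carried alongside but does not define the category (population tables
#' report it separately).
#'
#' @param ph A `nav_phenotype`.
#' @return A string such as `"IleMet_ValVal"`.
#' @export
category_of <- function(ph) {
  stopifnot(inherits(ph, "nav_phenotype"))
  paste0(gsub("/", "", ph$call1011), "_", gsub("/", "", ph$call1016))
}

#' Enumerate the phenotype categories of a haplotype set
#'
#' All unordered pairs of (single-unit) haplotypes are mapped through
#' [phenotype_of()] and de-duplicated on their two-site category, in the
#' canonical column order: (Ile/Ile,Val/Val), (Ile/Ile,Val/Ile),
#' (Ile/Ile,Ile/Ile), (Ile/Met,Val/Val), (Ile/Met,Val/Ile), (Met/Met,Val/Val);
#' any category outside these six (possible only with flagged haplotypes)
#' follows in lexicographic order.  With the three canonical haplotypes this
#' yields the six categories of the population frequency table.
#'
#' @param haps A list of 1--4 `nav_haplotype` objects (or strings).
#' @return A character vector of category codes, with attribute
#'   `"phenotypes"` holding one representative `nav_phenotype` per category.
#' @export
enumerate_phenotype_categories <- function(haps) {
  if (is.character(haps)) haps <- lapply(haps, parse_haplotype)
  if (inherits(haps, "nav_haplotype")) haps <- list(haps)
  k <- length(haps)
  if (k < 1L) stop("need at least one haplotype")
  if (k > 4L) stop("at most four haplotypes supported")
  cats <- character(0)
  reps <- list()
  for (i in seq_len(k)) {
    for (j in i:k) {
      ph <- phenotype_of(genotype(single_unit(haps[[i]]), single_unit(haps[[j]])))
      cc <- category_of(ph)
      if (!cc %in% cats) {
        cats <- c(cats, cc)
        reps[[cc]] <- ph
      }
    }
  }
  fixed <- .CATEGORY_ORDER[.CATEGORY_ORDER %in% cats]
  extra <- sort(setdiff(cats, .CATEGORY_ORDER))
  out <- c(fixed, extra)
  attr(out, "phenotypes") <- reps[out]
  out
}
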