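# Per-specimen haplotype profiling from sequenced clones of the IIS6
# amplicon.  A specimen whose clones reveal three distinct haplotypes cannot
# be a plain diploid of single-copy units, so such profiles are flagged as
# duplication evidence.

#' Build a clone-record table
#'
#' @param specimen,clone Identifier vectors (recycled to equal length).
#' @param haplotype A list of `nav_haplotype` (or character keys parseable
#'   by [parse_haplotype()]).
#' @return A data frame of class `nav_clone_records` with one row per clone
#'   and columns `specimen`, `clone`, `site1011`, `intron`, `site1016`;
#'   `(specimen, clone)` must be unique.
#' @export
clone_records <- function(specimen, clone, haplotype) {
  if (is.character(haplotype)) haplotype <- lapply(haplotype, parse_haplotype)
  if (inherits(haplotype, "nav_haplotype")) haplotype <- list(haplotype)
  df <- data.frame(
    specimen = as.character(specimen),
    clone = as.character(clone),
    site1011 = vapply(haplotype, `[[`, character(1), "site1011"),
    intron = vapply(haplotype, `[[`, character(1), "intron"),
    site1016 = vapply(haplotype, `[[`, character(1), "site1016"),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df[c("specimen", "clone")])) {
    stop("(specimen, clone) pairs must be unique")
  }
  class(df) <- c("nav_clone_records", class(df))
  df
}

#' Collapse one specimen's clones into a haplotype profile
#'
#' Haplotypes supported by at least `min_support` clones are retained; the
#' specimen's inferred molecular phenotype is the presence/absence union of
#' calls across the retained haplotypes (the same masking AS-PCR applies to
#' the genotype).  Three or more retained haplotypes set the duplication
#' flag: a diploid of single-copy units can carry at most two.
#'
#' @param records Clone records for a single specimen (rows of
#'   [clone_records()] or a compatible data frame).
#' @param min_support Minimum clone count per retained haplotype (default 1;
#'   raise to 2 to absorb PCR/cloning artefacts).
#' @return A list of class `nav_profile`: `specimen`, `support` (named clone
#'   counts per haplotype key), `n_haplotypes`, `duplication_flag`,
#'   `inferred_phenotype`.
#' @examples
#' recs <- clone_records("UBR-10", 1:8,
#'   c(rep("Met+A+Val", 3), rep("Ile+A+Ile", 2), rep("Ile+B+Val", 3)))
#' collapse_clones(recs)
#' @export
collapse_clones <- function(records, min_support = 1L) {
  stopifnot(nrow(records) >= 1L, min_support >= 1L)
  sp <- unique(records$specimen)
  if (length(sp) != 1L) stop("collapse_clones expects a single specimen")
  keys <- paste(records$site1011, records$intron, records$site1016, sep = "+")
  support <- sort(table(keys), decreasing = TRUE)
  support <- support[support >= min_support]
  if (length(support) == 0L) {
    stop("no haplotype reaches min_support = ", min_support)
  }
  haps <- lapply(names(support), parse_haplotype)
  ph <- molecular_phenotype(
    .pair_call(vapply(haps, `[[`, character(1), "site1011"), .ALLELES_1011),
    {
      it <- sort(unique(vapply(haps, `[[`, character(1), "intron")))
      if (length(it) == 1L) paste0(it, it) else "AB"
    },
    .pair_call(vapply(haps, `[[`, character(1), "site1016"), .ALLELES_1016)
  )
  structure(
    list(
      specimen = sp,
      support = stats::setNames(as.integer(support), names(support)),
      n_haplotypes = length(support),
      duplication_flag = length(support) >= 3L,
      inferred_phenotype = ph
    ),
    class = "nav_profile"
  )
}

#' @export
print.nav_profile <- function(x, ...) {
  cat(sprintf("<specimen %s> %d haplotype(s)%s: %s | phenotype %s\n",
              x$specimen, x$n_haplotypes,
              if (x$duplication_flag) " [duplication evidence]" else "",
              paste(sprintf("%s(x%d)", names(x$support), x$support),
                    collapse = ", "),
              format(x$inferred_phenotype)))
  invisible(x)
}

#' Profiles for every specimen in a clone-record table
#' @inheritParams collapse_clones
#' @return A list of `nav_profile`, one per specimen, in order of first
#'   appearance.
#' @export
specimen_profiles <- function(records, min_support = 1L) {
  sp <- unique(records$specimen)
  lapply(sp, function(s) {
    collapse_clones(records[records$specimen == s, , drop = FALSE],
                    min_support = min_support)
  })
}

#' Tally haplotypes across specimen profiles
#'
#' @param profiles A list of `nav_profile`.
#' @return A list: `specimen_counts` (named, per haplotype key, number of
#'   specimens carrying it), `n_distinct`, `n_flagged` (three-haplotype
#'   specimens), `n_specimens`.
#' @export
tally_haplotypes <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  carried <- unlist(lapply(profiles, function(p) names(p$support)))
  counts <- sort(table(carried), decreasing = TRUE)
  list(
    specimen_counts = stats::setNames(as.integer(counts), names(counts)),
    n_distinct = length(counts),
    n_flagged = sum(vapply(profiles, `[[`, logical(1), "duplication_flag")),
    n_specimens = length(profiles)
  )
}

#' Do carriers of one haplotype always carry another?
#'
#' The duplication composition hypothesis predicts that every specimen
#' carrying the mutant Met+A+Val haplotype also carries its linked wild
#' partner Ile+B+Val.
#'
#' @param profiles A list of `nav_profile`.
#' @param hap A haplotype key, e.g. `"Met+A+Val"`.
#' @param with A second haplotype key, e.g. `"Ile+B+Val"`.
#' @return `TRUE` iff every profile carrying `hap` also carries `with`.
#' @export
always_cooccurs <- function(profiles, hap = "Met+A+Val", with = "Ile+B+Val") {
  all(vapply(profiles, function(p) {
    !(hap %in% names(p$support)) || (with %in% names(p$support))
  }, logical(1)))
}

# ---- sequence classification ----------------------------------------------

#' Call a haplotype from a clone sequence using diagnostic rules
#'
#' The diagnostic nucleotides distinguishing the 1011/1016 codons and the
#' A/B intron classes are assay-specific, so the classifier is driven by a
#' user-supplied rule set rather than hard-coded motifs.  Each feature rule
#' is either `list(type = "motif", <value> = <motif>, ...)` -- exactly one
#' motif must match (fixed-string search), and its name is the call -- or,
#' for the intron, `list(type = "length", threshold = L, ge = , lt = )`,
#' calling `ge` when `nchar(seq) >= L` (the intron classes differ by
#' indels, hence amplicon length).
#'
#' @param seq A nucleotide string (single clone sequence).
#' @param rules A list with elements `site1011`, `intron`, `site1016`.
#'   See [read_rules_json()] for the file format.
#' @return A `nav_haplotype`.  Ambiguous or unmatched features raise an
#'   "uncallable" error.
#' @export
classify_sequence <- function(seq, rules) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(gsub("\\s", "", seq))
  need <- c("site1011", "intron", "site1016")
  if (!all(need %in% names(rules))) {
    stop("rules must define site1011, intron and site1016")
  }
  call_feature <- function(rule, feature) {
    type <- if (is.null(rule$type)) "motif" else rule$type
    if (type == "length") {
      if (nchar(seq) < rule$threshold && is.null(rule$lt)) {
        stop("uncallable ", feature, ": sequence shorter than rule window")
      }
      if (nchar(seq) >= rule$threshold) rule$ge else rule$lt
    } else {
      motifs <- rule[setdiff(names(rule), "type")]
      hits <- vapply(motifs, function(m) {
        grepl(toupper(m), seq, fixed = TRUE)
      }, logical(1))
      if (sum(hits) == 0L) {
        stop("uncallable ", feature, ": no diagnostic motif found")
      }
      if (sum(hits) > 1L) {
        stop("uncallable ", feature, ": ambiguous motif hits (",
             paste(names(motifs)[hits], collapse = ", "), ")")
      }
      names(motifs)[hits]
    }
  }
  haplotype(
    call_feature(rules$site1011, "site1011"),
    call_feature(rules$intron, "intron"),
    call_feature(rules$site1016, "site1016")
  )
}

#' Read a diagnostic rule configuration (JSON)
#'
#' @param path Path to a JSON file with top-level keys `site1011`, `intron`,
#'   `site1016`, each a rule as described in [classify_sequence()].
#' @return The rules list.
#' @export
read_rules_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Read clone calls from CSV
#'
#' Columns: `specimen`, `clone`, `site1011`, `intron`, `site1016`.
#'
#' @param path CSV file path.
#' @return A `nav_clone_records` data frame.
#' @export
read_clone_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "clone", "site1011", "intron", "site1016")
  if (!all(need %in% names(df))) {
    stop("clone CSV needs columns: ", paste(need, collapse = ", "))
  }
  clone_records(df$specimen, df$clone,
                paste(df$site1011, df$intron, df$site1016, sep = "+"))
}

#' Read and classify clone sequences from FASTA
#'
#' One clone per record, ids formatted `"specimen|clone"`; sequences are
#' classified with [classify_sequence()].
#'
#' @param path FASTA file path.
#' @param rules Diagnostic rules (see [classify_sequence()]).
#' @return A `nav_clone_records` data frame.
#' @export
read_clone_fasta <- function(path, rules) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- names(seqs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("FASTA ids must be of the form 'specimen|clone'")
  }
  haps <- lapply(as.character(seqs), classify_sequence, rules = rules)
  clone_records(vapply(parts, `[[`, character(1), 1),
                vapply(parts, `[[`, character(1), 2),
                haps)
}

#' Read specimen haplotype profiles (presence/absence) from CSV
#'
#' For published profile tables that mark each specimen's haplotypes without
#' clone counts: columns `specimen`, `site1011`, `intron`, `site1016`, one
#' row per (specimen, haplotype).  Each mark is treated as support from one
#' clone.
#'
#' @param path CSV file path.
#' @return A `nav_clone_records` data frame.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen", "site1011", "intron", "site1016")
  if (!all(need %in% names(df))) {
    stop("profile CSV needs columns: ", paste(need, collapse = ", "))
  }
  clone <- stats::ave(seq_len(nrow(df)), df$specimen, FUN = seq_along)
  clone_records(df$specimen, clone,
                paste(df$site1011, df$intron, df$site1016, sep = "+"))
}
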