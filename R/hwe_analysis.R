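# Hardy-Weinberg analysis of two-site molecular phenotype tables:
# haplotype-frequency estimation by gene counting / EM, HWE expected
# category proportions, and the chi-square goodness of fit.

# The canonical three-haplotype model behind the six-category table.
.CANONICAL_HAPS <- c("Ile+B+Val", "Ile+A+Ile", "Met+A+Val")

# Map each phenotype category of a haplotype set to the unordered haplotype
# pairs (index pairs) compatible with it.
category_pair_map <- function(haps) {
  if (is.character(haps)) haps <- lapply(haps, parse_haplotype)
  k <- length(haps)
  cats <- enumerate_phenotype_categories(haps)
  map <- stats::setNames(vector("list", length(cats)), cats)
  for (i in seq_len(k)) {
    for (j in i:k) {
      ph <- phenotype_of(genotype(single_unit(haps[[i]]), single_unit(haps[[j]])))
      cc <- category_of(ph)
      map[[cc]] <- rbind(map[[cc]], c(i, j))
    }
  }
  map
}

#' Recover integer counts from printed category proportions
#'
#' Published population tables print phenotype frequencies; analyses need
#' the underlying counts.  Counts are allocated by the largest-remainder
#' method on `freqs * n`, which reproduces the original integers whenever
#' the printed proportions are rounded from counts out of `n`.
#'
#' @param freqs Numeric vector of per-category proportions (possibly named).
#' @param n Total number of individuals.
#' @param tol Largest tolerated deviation of `sum(freqs)` from 1 (printed
#'   tables carry rounding error); default 0.02.
#' @return Integer vector summing to `n`, same names as `freqs`.
#' @examples
#' counts_from_frequencies(c(0.056, 0, 0.222, 0.5, 0.222, 0), 18)
#' @export
counts_from_frequencies <- function(freqs, n, tol = 0.02) {
  stopifnot(is.numeric(freqs), length(freqs) >= 1L, n > 0, n == round(n))
  if (any(freqs < 0 | freqs > 1)) stop("proportions must lie in [0, 1]")
  if (abs(sum(freqs) - 1) > tol) {
    stop(sprintf("proportions sum to %.4f, out of 1 +/- %.3g", sum(freqs), tol))
  }
  raw <- freqs * n
  base <- floor(raw)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(freqs))
}

#' Estimate haplotype frequencies from phenotype category counts
#'
#' When each category decodes to a unique haplotype pair (true for the two-
#' and three-haplotype single-copy models) the estimate is direct gene
#' counting: `freq(h) = (2 * hom_h + sum of het counts involving h) / (2n)`.
#' Otherwise an EM fixed point is used (uniform initialisation, convergence
#' when the largest frequency change drops below `1e-10`, at most 1000
#' iterations); gene counting is its closed-form special case and the two
#' agree to numerical precision whenever both apply.
#'
#' @param counts Named (or positionally ordered) integer counts per category,
#'   in the order of [enumerate_phenotype_categories()] for `haps`.
#' @param haps The declared haplotype set (list of haplotypes or strings);
#'   default is the canonical three-haplotype single-copy model.
#' @param method `"auto"` (gene counting when uniquely decodable, else EM),
#'   `"gene-counting"`, or `"em"`.
#' @return Named numeric vector of haplotype frequencies (by [hap_key()]),
#'   summing to 1.
#' @examples
#' estimate_haplotype_frequencies(c(1, 0, 4, 9, 4, 0)) # 11/36, 12/36, 13/36
#' @export
estimate_haplotype_frequencies <- function(counts,
                                           haps = .CANONICAL_HAPS,
                                           method = c("auto", "gene-counting", "em")) {
  method <- match.arg(method)
  if (is.character(haps)) haps <- lapply(haps, parse_haplotype)
  cats <- enumerate_phenotype_categories(haps)
  counts <- .align_counts(counts, cats)
  if (sum(counts) == 0) stop("all category counts are zero")
  map <- category_pair_map(haps)
  k <- length(haps)
  keys <- vapply(haps, hap_key, character(1))
  decodable <- all(vapply(map, nrow, integer(1)) == 1L)
  if (method == "gene-counting" && !decodable) {
    stop("gene counting requires each category to decode to a unique pair")
  }
  use_gc <- method == "gene-counting" || (method == "auto" && decodable)

  if (use_gc) {
    copies <- numeric(k)
    for (cc in cats) {
      ij <- map[[cc]][1, ]
      copies[ij[1]] <- copies[ij[1]] + counts[[cc]]
      copies[ij[2]] <- copies[ij[2]] + counts[[cc]]
    }
    p <- copies / (2 * sum(counts))
  } else {
    p <- rep(1 / k, k)
    n2 <- 2 * sum(counts)
    for (iter in seq_len(1000)) {
      copies <- numeric(k)
      for (cc in cats) {
        if (counts[[cc]] == 0) next
        prs <- map[[cc]]
        w <- apply(prs, 1, function(ij) {
          (if (ij[1] == ij[2]) 1 else 2) * p[ij[1]] * p[ij[2]]
        })
        if (sum(w) <= 0) w <- rep(1, length(w))
        w <- w / sum(w)
        for (r in seq_len(nrow(prs))) {
          copies[prs[r, 1]] <- copies[prs[r, 1]] + counts[[cc]] * w[r]
          copies[prs[r, 2]] <- copies[prs[r, 2]] + counts[[cc]] * w[r]
        }
      }
      p_new <- copies / n2
      if (max(abs(p_new - p)) < 1e-10) {
        p <- p_new
        break
      }
      p <- p_new
    }
  }
  stats::setNames(p, keys)
}

# Align a count/proportion vector with the category order, by name when named.
.align_counts <- function(x, cats) {
  if (!is.null(names(x)) && all(names(x) != "")) {
    missing <- setdiff(names(x), cats)
    if (length(missing)) {
      stop("unknown categories for this haplotype set: ",
           paste(missing, collapse = ", "))
    }
    full <- stats::setNames(numeric(length(cats)), cats)
    full[names(x)] <- x
    full
  } else {
    if (length(x) != length(cats)) {
      stop(sprintf("expected %d category entries, got %d",
                   length(cats), length(x)))
    }
    stats::setNames(as.numeric(x), cats)
  }
}

#' Hardy-Weinberg expected phenotype-category proportions
#'
#' Random union of single-copy haplotypes: a homozygous category has
#' probability `p_i^2`, a heterozygous category `2 p_i p_j`, accumulated
#' into the two-site categories of the declared haplotype set.
#'
#' @param freqs Named haplotype frequencies as returned by
#'   [estimate_haplotype_frequencies()] (names are [hap_key()] strings), or
#'   an unnamed vector in the order of `haps`.
#' @param haps Declared haplotype set; defaults to the canonical model (or
#'   to the haplotypes named in `freqs`).
#' @return Named proportions per category, summing to 1.
#' @examples
#' expected_phenotype_frequencies(c(11, 12, 13) / 36)
#' @export
expected_phenotype_frequencies <- function(freqs, haps = NULL) {
  if (is.null(haps)) {
    haps <- if (!is.null(names(freqs))) names(freqs) else .CANONICAL_HAPS
  }
  if (is.character(haps)) haps <- lapply(haps, parse_haplotype)
  keys <- vapply(haps, hap_key, character(1))
  if (!is.null(names(freqs))) {
    stopifnot(setequal(names(freqs), keys))
    freqs <- freqs[keys]
  }
  stopifnot(length(freqs) == length(haps))
  if (abs(sum(freqs) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  cats <- enumerate_phenotype_categories(haps)
  out <- stats::setNames(numeric(length(cats)), cats)
  map <- category_pair_map(haps)
  for (cc in cats) {
    prs <- map[[cc]]
    for (r in seq_len(nrow(prs))) {
      i <- prs[r, 1]; j <- prs[r, 2]
      out[cc] <- out[cc] + (if (i == j) freqs[i]^2 else 2 * freqs[i] * freqs[j])
    }
  }
  out
}

#' Chi-square goodness of fit of phenotype counts to HWE expectations
#'
#' `chi2 = sum (O - nE)^2 / (nE)` over categories with positive expectation;
#' a category with zero expected and zero observed contributes 0 but still
#' counts toward the number of categories, so `df = k - 1` always (the
#' convention that reproduces the published p-values; parameters estimated
#' from the data are not subtracted).  The p-value is the upper tail of the
#' chi-square distribution, with no continuity correction.  A category with
#' zero expectation but positive observed count yields an infinite statistic
#' with a warning (p = 0) rather than an error.
#'
#' @param observed Integer counts per category.
#' @param expected Expected proportions per category (same length/order).
#' @param n Total count; defaults to `sum(observed)`.
#' @return A list with `chi2`, `df`, `p`.
#' @export
hwe_chi_square <- function(observed, expected, n = sum(observed)) {
  observed <- unname(observed)
  expected <- unname(expected)
  k <- length(observed)
  stopifnot(k >= 2L, length(expected) == k)
  if (abs(sum(observed) - n) > 1e-9) stop("observed counts must sum to n")
  e_cnt <- n * expected
  chi2 <- 0
  for (i in seq_len(k)) {
    if (e_cnt[i] > 0) {
      chi2 <- chi2 + (observed[i] - e_cnt[i])^2 / e_cnt[i]
    } else if (observed[i] > 0) {
      warning("observed count in a category with zero expectation; ",
              "statistic is infinite")
      chi2 <- Inf
    }
  }
  df <- k - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Full HWE analysis of one population sample
#'
#' Chains haplotype-frequency estimation, HWE expectations and the
#' chi-square test for one row of a population phenotype table.
#'
#' @param counts Phenotype category counts (see
#'   [estimate_haplotype_frequencies()]); alternatively pass `freqs` plus `n`
#'   to recover counts via [counts_from_frequencies()].
#' @param haps Declared haplotype set.
#' @param freqs Optional printed category proportions (used with `n` when
#'   `counts` is missing).
#' @param n Sample size, required with `freqs`.
#' @inheritParams estimate_haplotype_frequencies
#' @return A list of class `nav_hwe` with elements `counts`, `n`,
#'   `haplotype_freqs`, `expected` (proportions), `chi2`, `df`, `p`.
#' @examples
#' analyze_population(c(4, 12, 0), haps = c("Ile+B+Val", "Met+A+Val"))
#' @export
analyze_population <- function(counts = NULL, haps = .CANONICAL_HAPS,
                               freqs = NULL, n = NULL,
                               method = c("auto", "gene-counting", "em")) {
  if (is.null(counts)) {
    if (is.null(freqs) || is.null(n)) {
      stop("provide counts, or printed freqs together with n")
    }
    counts <- counts_from_frequencies(freqs, n)
  }
  if (is.character(haps)) haps <- lapply(haps, parse_haplotype)
  cats <- enumerate_phenotype_categories(haps)
  counts <- .align_counts(counts, cats)
  hf <- estimate_haplotype_frequencies(counts, haps, method = match.arg(method))
  exp_p <- expected_phenotype_frequencies(hf, haps)
  gt <- if (length(cats) >= 2L) {
    hwe_chi_square(counts, exp_p)
  } else {
    list(chi2 = 0, df = 0L, p = 1) # monomorphic sample: vacuous fit
  }
  structure(
    list(counts = counts, n = sum(counts), haplotype_freqs = hf,
         expected = exp_p, chi2 = gt$chi2, df = gt$df, p = gt$p),
    class = "nav_hwe"
  )
}

#' @export
print.nav_hwe <- function(x, ...) {
  cat("Hardy-Weinberg analysis (n =", x$n, ")\n")
  tab <- data.frame(
    category = names(x$counts),
    observed = round(as.numeric(x$counts) / x$n, 3),
    expected = round(as.numeric(x$expected), 3)
  )
  print(tab, row.names = FALSE)
  cat(sprintf("chi2 = %.1f, df = %d, P = %.4f\n", x$chi2, x$df, x$p))
  invisible(x)
}

# ---- population table I/O -------------------------------------------------

#' Read a population phenotype table
#'
#' Expects columns `locality`, `status`, `n` and either six `count_<cat>` or
#' six `freq_<cat>` columns named after the canonical categories, e.g.
#' `count_IleIle_ValVal`.  Empty/`NA` cells mark categories absent from that
#' locality's haplotype model (printed as dashes); the declared haplotype
#' set of each row is inferred from which columns are present.
#'
#' @param path CSV file path.
#' @return A data frame with one row per sample and an attribute-free layout
#'   suitable for [hwe_table()].
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("locality", "status", "n")
  if (!all(need %in% names(df))) {
    stop("population CSV needs columns: ", paste(need, collapse = ", "))
  }
  has_counts <- any(grepl("^count_", names(df)))
  has_freqs <- any(grepl("^freq_", names(df)))
  if (!has_counts && !has_freqs) {
    stop("population CSV needs count_<category> or freq_<category> columns")
  }
  df
}

# Haplotype model of one table row: the wild B haplotype is always present;
# 1016Ile-bearing and 1011Met-bearing haplotypes are included when any of
# their categories is typed (non-NA) in that row.
.row_hap_model <- function(vals) {
  cats <- .CATEGORY_ORDER
  typed <- !is.na(vals)
  haps <- "Ile+B+Val"
  if (any(typed[cats %in% c("IleIle_ValIle", "IleIle_IleIle", "IleMet_ValIle")])) {
    haps <- c(haps, "Ile+A+Ile")
  }
  if (any(typed[cats %in% c("IleMet_ValVal", "IleMet_ValIle", "MetMet_ValVal")])) {
    haps <- c(haps, "Met+A+Val")
  }
  haps
}

#' HWE analysis of every sample in a population table
#'
#' @param df Data frame from [read_population_csv()].
#' @return A data frame mirroring the published layout: one row per sample
#'   with observed and expected proportions per category, `chi2`, `df`, `p`.
#'   Full-precision analyses are attached as attribute `"analyses"`.
#' @export
hwe_table <- function(df) {
  cats <- .CATEGORY_ORDER
  use_counts <- any(grepl("^count_", names(df)))
  prefix <- if (use_counts) "count_" else "freq_"
  out <- list()
  analyses <- list()
  for (r in seq_len(nrow(df))) {
    vals <- stats::setNames(rep(NA_real_, length(cats)), cats)
    for (cc in cats) {
      col <- paste0(prefix, cc)
      if (col %in% names(df)) vals[cc] <- suppressWarnings(as.numeric(df[[col]][r]))
    }
    haps <- .row_hap_model(vals)
    row_cats <- enumerate_phenotype_categories(haps)
    v <- vals[row_cats]
    v[is.na(v)] <- 0
    res <- if (use_counts) {
      analyze_population(counts = v, haps = haps)
    } else {
      analyze_population(freqs = v, n = df$n[r], haps = haps)
    }
    analyses[[r]] <- res
    obs_p <- stats::setNames(rep(NA_real_, length(cats)), cats)
    exp_p <- obs_p
    obs_p[row_cats] <- as.numeric(res$counts) / res$n
    exp_p[row_cats] <- as.numeric(res$expected)
    out[[r]] <- data.frame(
      locality = df$locality[r], status = df$status[r], n = res$n,
      as.list(stats::setNames(round(obs_p, 3), paste0("obs_", cats))),
      as.list(stats::setNames(round(exp_p, 3), paste0("exp_", cats))),
      chi2 = round(res$chi2, 1), df = res$df, p = round(res$p, 4),
      check.names = FALSE
    )
  }
  res <- do.call(rbind, out)
  attr(res, "analyses") <- analyses
  res
}
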