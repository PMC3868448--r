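# Segregation analysis of Ile/Ile x Ile/Met crosses: expected offspring
# phenotype distributions under the single-copy and duplication hypotheses,
# exact Fisher comparison of observed vs expected, and per-cross verdicts.

#' Standard cross hypotheses for an Ile/Ile x Ile/Met mating
#'
#' The Ile/Met parent's true constitution is unobservable by AS-PCR; three
#' hypotheses cover it: `H1`, a plain heterozygote of single-copy haplotypes
#' (no duplication); `H2a`, homozygous for the duplicated unit; `H2b`,
#' heterozygous single-wild / duplicated.  The Ile/Ile parent is homozygous
#' wild-type in all three.  H1 and H2b predict identical 50:50 offspring at
#' site 1011, so only the 100% Ile/Met outcome of H2a is discriminating.
#'
#' @param label `"H1"`, `"H2a"` or `"H2b"`.
#' @param dup The duplicated unit for H2a/H2b (default [dup_unit()]).
#' @param wild Wild-type haplotype (default `"Ile+B+Val"`).
#' @param mut Mutant haplotype for H1 (default `"Met+A+Val"`).
#' @return A list of class `nav_hypothesis` with `label`, `parent1`,
#'   `parent2`.
#' @export
cross_hypothesis <- function(label = c("H1", "H2a", "H2b"),
                             dup = dup_unit(), wild = "Ile+B+Val",
                             mut = "Met+A+Val") {
  label <- match.arg(label)
  p1 <- genotype(single_unit(wild), single_unit(wild))
  p2 <- switch(label,
    H1 = genotype(single_unit(wild), single_unit(mut)),
    H2a = genotype(dup, dup),
    H2b = genotype(single_unit(wild), dup)
  )
  structure(list(label = label, parent1 = p1, parent2 = p2),
            class = "nav_hypothesis")
}

#' Custom cross hypothesis from explicit parental genotypes
#' @param parent1,parent2 `nav_genotype` objects.
#' @param label Free-text label.
#' @return A `nav_hypothesis`.
#' @export
custom_hypothesis <- function(parent1, parent2, label = "custom") {
  stopifnot(inherits(parent1, "nav_genotype"), inherits(parent2, "nav_genotype"))
  structure(list(label = label, parent1 = parent1, parent2 = parent2),
            class = "nav_hypothesis")
}

#' Offspring phenotype distribution of a cross
#'
#' Convolves the two parental gamete distributions ([gametes_of()]), maps
#' each offspring genotype through [phenotype_of()], and aggregates the
#' probabilities by the site-1011 call (the assayed marker in the cross
#' experiments).
#'
#' @param hyp A `nav_hypothesis` (or a list with `parent1`, `parent2`).
#' @param n Optional brood size: also return real expected counts and an
#'   integer rendering by largest remainder.
#' @return A list with `proportions` (named over Ile/Ile, Ile/Met, Met/Met
#'   calls that occur) and, when `n` is given, `expected_real` and
#'   `expected_int`.
#' @examples
#' expected_offspring(cross_hypothesis("H2a"), n = 20)
#' @export
expected_offspring <- function(hyp, n = NULL) {
  g1 <- gametes_of(hyp$parent1)
  g2 <- gametes_of(hyp$parent2)
  probs <- numeric(0)
  for (a in g1) {
    for (b in g2) {
      ph <- phenotype_of(genotype(a$unit, b$unit))
      key <- ph$call1011
      probs[key] <- (if (key %in% names(probs)) probs[[key]] else 0) +
        a$prob * b$prob
    }
  }
  order_1011 <- c("Ile/Ile", "Ile/Met", "Met/Met")
  probs <- probs[order_1011[order_1011 %in% names(probs)]]
  out <- list(proportions = probs)
  if (!is.null(n)) {
    stopifnot(n > 0)
    out$expected_real <- probs * n
    out$expected_int <- largest_remainder(probs, n)
  }
  out
}

#' Largest-remainder integer apportionment
#'
#' Renders real-valued expected counts `props * n` to integers summing to
#' `n`: floor each, then hand the remaining units to the largest fractional
#' remainders.  Ties go to the earlier category (so a 1:3 split of 30 gives
#' 8 and 22).
#'
#' @param props Proportions (need not be exactly normalised).
#' @param n Total.
#' @return Integer vector summing to `n`.
#' @export
largest_remainder <- function(props, n) {
  raw <- props / sum(props) * n
  base <- floor(raw)
  left <- as.integer(round(n - sum(base)))
  if (left > 0) {
    rem <- raw - base
    # ties broken toward earlier categories: stable order by -rem
    extra <- order(-rem, seq_along(rem))[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value is the sum of point
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed that of the observed table, with a small relative
#' tolerance on the comparison to absorb floating-point noise.
#'
#' @param tab A 2x2 matrix (or something coercible) of non-negative integers.
#' @return The p-value in (0, 1].  A table with a zero margin is degenerate:
#'   p = 1 with a warning.
#' @examples
#' fisher_exact_2x2(rbind(c(0, 20), c(10, 10)))
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("table entries must be non-negative integers")
  }
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate 2x2 table (zero margin); p = 1")
    return(1)
  }
  m <- cs[1]; nn <- cs[2]; k <- rs[1]
  support <- max(0, k - nn):min(k, m)
  d <- stats::dhyper(support, m, nn, k)
  d_obs <- stats::dhyper(tab[1, 1], m, nn, k)
  p <- sum(d[d <= d_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Significance code for a p-value
#' @param p p-value.
#' @param alpha Thresholds for `*`, `**`, `***` (descending).
#' @return One of `"NS"`, `"*"`, `"**"`, `"***"`.
#' @export
significance_code <- function(p, alpha = c(0.05, 0.01, 0.001)) {
  alpha <- sort(alpha, decreasing = TRUE)
  if (p < alpha[3]) "***" else if (p < alpha[2]) "**"
  else if (p < alpha[1]) "*" else "NS"
}

# Build the observed-vs-expected 2x2 and test it.  Categories where both
# rows are zero are dropped; the result must be 2x2 (true for all crosses in
# this model, where Met/Met is unreachable).
.obs_vs_exp_test <- function(observed, expected_int) {
  keep <- !(observed == 0 & expected_int == 0)
  if (sum(keep) < 2L) return(list(p = 1, table = NULL))
  if (sum(keep) > 2L) {
    stop("more than two non-empty phenotype categories; the exact test ",
         "is defined for 2x2 observed-vs-expected tables")
  }
  tab <- rbind(observed[keep], expected_int[keep])
  list(p = fisher_exact_2x2(tab), table = tab)
}

#' Test an observed F1 brood against cross hypotheses
#'
#' For each hypothesis, expected counts for the brood size are rendered to
#' integers (largest remainder) and compared with the observed counts in a
#' 2x2 exact Fisher test over the non-empty site-1011 categories.
#'
#' @param observed Named or ordered counts over `Ile/Ile`, `Ile/Met` (and
#'   optionally `Met/Met`) at site 1011.
#' @param hypotheses List of `nav_hypothesis`; default the standard three.
#' @param alpha Significance thresholds (see [significance_code()]).
#' @return A list of class `nav_cross_verdict`: per-hypothesis `expected`,
#'   `p` and `code`, plus `not_rejected`, the labels with p >= alpha.
#' @examples
#' classify_cross(c(`Ile/Ile` = 0, `Ile/Met` = 20))
#' @export
classify_cross <- function(observed,
                           hypotheses = lapply(c("H1", "H2a", "H2b"),
                                               cross_hypothesis),
                           alpha = c(0.05, 0.01, 0.001)) {
  observed <- .as_1011_counts(observed)
  n <- sum(observed)
  stopifnot(n > 0)
  per <- list()
  for (hyp in hypotheses) {
    eo <- expected_offspring(hyp, n = n)
    exp_int <- stats::setNames(rep(0L, length(observed)), names(observed))
    common <- intersect(names(eo$expected_int), names(exp_int))
    exp_int[common] <- eo$expected_int[common]
    if (any(!names(eo$expected_int) %in% names(observed) &
              eo$expected_int > 0)) {
      stop("hypothesis ", hyp$label,
           " expects phenotype categories absent from the observation")
    }
    tst <- .obs_vs_exp_test(observed, exp_int)
    per[[hyp$label]] <- list(
      expected = exp_int, p = tst$p,
      code = significance_code(tst$p, alpha)
    )
  }
  structure(
    list(observed = observed, n = n, hypotheses = per,
         not_rejected = names(per)[vapply(per, function(x)
           x$p >= max(alpha), logical(1))]),
    class = "nav_cross_verdict"
  )
}

.as_1011_counts <- function(observed) {
  labels <- c("Ile/Ile", "Ile/Met", "Met/Met")
  if (is.null(names(observed))) {
    stopifnot(length(observed) %in% 2:3)
    names(observed) <- labels[seq_along(observed)]
  }
  stopifnot(all(names(observed) %in% labels), all(observed >= 0))
  observed
}

#' Test F2 segregation against the 1:3 duplication expectation
#'
#' An F1 x F1 cross of two single-wild/duplicated heterozygotes is expected
#' to throw 1/4 Ile/Ile (wild homozygotes) and 3/4 Ile/Met (one or two
#' duplicated units) offspring; this checks observed F2 counts against that
#' ratio with the same integer-rendered exact Fisher machinery.
#'
#' @param observed Counts over `Ile/Ile`, `Ile/Met`.
#' @inheritParams classify_cross
#' @return A `nav_cross_verdict` with a single `F2_duplication` hypothesis.
#' @examples
#' f2_segregation_test(c(`Ile/Ile` = 5, `Ile/Met` = 25))
#' @export
f2_segregation_test <- function(observed, alpha = c(0.05, 0.01, 0.001)) {
  observed <- .as_1011_counts(observed)
  n <- sum(observed)
  stopifnot(n > 0)
  props <- c(`Ile/Ile` = 0.25, `Ile/Met` = 0.75)
  exp_int <- largest_remainder(props, n)
  full_exp <- stats::setNames(rep(0L, length(observed)), names(observed))
  full_exp[names(exp_int)] <- exp_int
  tst <- .obs_vs_exp_test(observed, full_exp)
  per <- list(F2_duplication = list(
    expected = full_exp, p = tst$p, code = significance_code(tst$p, alpha)
  ))
  structure(
    list(observed = observed, n = n, hypotheses = per,
         not_rejected = names(per)[per$F2_duplication$p >= max(alpha)]),
    class = "nav_cross_verdict"
  )
}

#' @export
print.nav_cross_verdict <- function(x, ...) {
  cat("Cross segregation (n =", x$n, ")\n observed:",
      paste(sprintf("%s=%d", names(x$observed), x$observed), collapse = ", "),
      "\n")
  for (lab in names(x$hypotheses)) {
    h <- x$hypotheses[[lab]]
    cat(sprintf("  %-14s expected (%s)  P = %.4g  %s\n", lab,
                paste(h$expected, collapse = ", "), h$p, h$code))
  }
  cat(" not rejected:",
      if (length(x$not_rejected)) paste(x$not_rejected, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Read a cross observation table
#'
#' Columns: `cross_id`, `parent1_phenotype`, `parent2_phenotype`,
#' `n_IleIle`, `n_IleMet`, `n_MetMet` (optional), `generation` (`F1`/`F2`).
#'
#' @param path CSV file path.
#' @return The parsed data frame.
#' @export
read_cross_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cross_id", "n_IleIle", "n_IleMet", "generation")
  if (!all(need %in% names(df))) {
    stop("cross CSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' Classify every cross in a table
#'
#' F1 rows are tested against the three standard hypotheses; F2 rows against
#' the 1:3 duplication expectation.
#'
#' @param df Data frame from [read_cross_csv()].
#' @return A data frame with one row per cross and per-hypothesis expected
#'   counts, p-values and significance codes; verdict objects attached as
#'   attribute `"verdicts"`.
#' @export
cross_table <- function(df) {
  out <- list()
  verdicts <- list()
  for (r in seq_len(nrow(df))) {
    obs <- c(`Ile/Ile` = df$n_IleIle[r], `Ile/Met` = df$n_IleMet[r])
    if ("n_MetMet" %in% names(df) && !is.na(df$n_MetMet[r]) &&
        df$n_MetMet[r] > 0) {
      obs <- c(obs, `Met/Met` = df$n_MetMet[r])
    }
    v <- if (toupper(df$generation[r]) == "F2") f2_segregation_test(obs)
         else classify_cross(obs)
    verdicts[[as.character(df$cross_id[r])]] <- v
    row <- data.frame(cross_id = df$cross_id[r],
                      generation = df$generation[r],
                      n = v$n, obs_IleIle = obs[["Ile/Ile"]],
                      obs_IleMet = obs[["Ile/Met"]])
    for (lab in names(v$hypotheses)) {
      h <- v$hypotheses[[lab]]
      row[[paste0(lab, "_exp_IleIle")]] <- h$expected[["Ile/Ile"]]
      row[[paste0(lab, "_exp_IleMet")]] <- h$expected[["Ile/Met"]]
      row[[paste0(lab, "_p")]] <- h$p
      row[[paste0(lab, "_code")]] <- h$code
    }
    out[[r]] <- row
  }
  # F1 and F2 rows carry different hypothesis columns; pad to the union
  cols <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(row) {
    for (cc in setdiff(cols, names(row))) row[[cc]] <- NA
    row[cols]
  })
  res <- do.call(rbind, out)
  attr(res, "verdicts") <- verdicts
  res
}
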