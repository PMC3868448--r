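# TaqMan relative copy-number arithmetic (comparative CT).  Per-replicate
# delta-CT normalises the target (NaV) by the single-copy reference gene
# (RP49); delta-delta-CT compares a test lineage with the calibrator
# lineage; copies = cn_ref * 2^(-mean ddCT).
#
# Sign convention: the assay reports *fewer* cycles for more template, so a
# lineage with extra copies has a *negative* delta-delta-CT, and recovering
# its copy number requires the exponent -ddCT (a ddCT of -2.3 against a
# 2-copy calibrator gives 2 * 2^2.3 ~ 10 copies).

#' Per-replicate delta-CT
#' @param ct_target CT of the target gene (NaV amplicon).
#' @param ct_reference CT of the single-copy reference gene, same well/
#'   replicate.
#' @return `ct_target - ct_reference` (vectorised).
#' @export
delta_ct <- function(ct_target, ct_reference) {
  if (any(is.na(ct_target)) || any(is.na(ct_reference))) {
    stop("both target and reference CT must be present for each replicate")
  }
  ct_target - ct_reference
}

#' Delta-delta-CT of a test lineage against the calibrator
#' @param mu_dct_test Mean delta-CT of the test lineage in one assay.
#' @param mu_dct_ref Mean delta-CT of the calibrator lineage, same assay.
#' @return `mu_dct_test - mu_dct_ref` (vectorised).
#' @export
delta_delta_ct <- function(mu_dct_test, mu_dct_ref) {
  if (any(is.na(mu_dct_test)) || any(is.na(mu_dct_ref))) {
    stop("delta-delta-CT needs both lineages measured in the same assay")
  }
  mu_dct_test - mu_dct_ref
}

#' Diploid copy number from mean delta-delta-CT
#'
#' `cn_real = cn_ref * 2^(-mu_ddct)`, assuming 100% amplification efficiency
#' (one cycle = factor 2); `cn_integer` rounds half away from zero.
#'
#' @param mu_ddct Mean delta-delta-CT across assays.
#' @param cn_ref Copy number of the target in the calibrator (2 for a
#'   diploid single-copy gene).
#' @return A list with `cn_real` and `cn_integer`.
#' @examples
#' copy_number(-2.3) # ~9.85 -> 10
#' @export
copy_number <- function(mu_ddct, cn_ref = 2L) {
  stopifnot(cn_ref >= 1)
  cn_real <- cn_ref * 2^(-mu_ddct)
  list(cn_real = cn_real, cn_integer = as.integer(sign(cn_real) *
                                                    floor(abs(cn_real) + 0.5)))
}

#' Summarise a qPCR plate into relative copy numbers
#'
#' Input is long-format well data: one row per (lineage, assay, replicate,
#' gene role).  Per replicate, delta-CT = target - reference; per lineage x
#' assay, the mean and SD of delta-CT; per assay, delta-delta-CT against the
#' calibrator lineage; per lineage, the mean and SD of delta-delta-CT across
#' assays and the resulting copy number.
#'
#' @param measurements Data frame with columns `lineage`, `assay`,
#'   `replicate`, `gene` (`"target"`/`"reference"`), `ct` (a `pool` column
#'   is allowed and ignored: in the published design each assay ran one
#'   pool).
#' @param reference_lineage Calibrator lineage id (default `"Rock"`).
#' @param cn_ref Calibrator copy number (default 2).
#' @return A list of class `nav_qpcr`: `per_assay` (data frame of mu_dct,
#'   sd_dct, ddct), `per_lineage` (mu_ddct, sd_ddct, cn_real, cn), and the
#'   inputs' lineage order.
#' @export
analyze_plate <- function(measurements, reference_lineage = "Rock",
                          cn_ref = 2L) {
  df <- as.data.frame(measurements)
  need <- c("lineage", "assay", "replicate", "gene", "ct")
  if (!all(need %in% names(df))) {
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$ct <= 0)) stop("CT values must be positive")
  if (!reference_lineage %in% df$lineage) {
    stop("reference lineage '", reference_lineage, "' absent from the plate")
  }
  wide <- merge(
    df[df$gene == "target", c("lineage", "assay", "replicate", "ct")],
    df[df$gene == "reference", c("lineage", "assay", "replicate", "ct")],
    by = c("lineage", "assay", "replicate"), suffixes = c("_t", "_r")
  )
  if (nrow(wide) * 2 != nrow(df)) {
    stop("each (lineage, assay, replicate) needs exactly one target and ",
         "one reference CT")
  }
  wide$dct <- delta_ct(wide$ct_t, wide$ct_r)
  agg <- stats::aggregate(dct ~ lineage + assay, data = wide,
                          FUN = function(x) c(mu = mean(x), sd = stats::sd(x)))
  per_assay <- data.frame(lineage = agg$lineage, assay = agg$assay,
                          mu_dct = agg$dct[, "mu"], sd_dct = agg$dct[, "sd"])
  summarize_ddct(per_assay, reference_lineage = reference_lineage,
                 cn_ref = cn_ref,
                 lineage_order = unique(df$lineage))
}

#' Copy-number summary from per-assay mean delta-CT values
#'
#' The entry point matching a published summary table: given mu[delta-CT]
#' per lineage x assay (raw CTs not needed), compute per-assay
#' delta-delta-CT against the calibrator, the across-assay mean and SD, and
#' the copy number.
#'
#' @param per_assay Data frame with columns `lineage`, `assay`, `mu_dct`
#'   (optionally `sd_dct`).
#' @inheritParams analyze_plate
#' @param lineage_order Optional output ordering of lineages.
#' @return A `nav_qpcr` list (see [analyze_plate()]).
#' @examples
#' tab <- data.frame(
#'   lineage = rep(c("Rock", "EE", "Hyb"), each = 3), assay = rep(1:3, 3),
#'   mu_dct = c(-0.4, 0, -0.7, -2.7, -2.4, -3.0, -2.0, -1.7, -2.4))
#' summarize_ddct(tab)
#' @export
summarize_ddct <- function(per_assay, reference_lineage = "Rock",
                           cn_ref = 2L, lineage_order = NULL) {
  stopifnot(all(c("lineage", "assay", "mu_dct") %in% names(per_assay)))
  if (!reference_lineage %in% per_assay$lineage) {
    stop("reference lineage '", reference_lineage, "' missing")
  }
  ref <- per_assay[per_assay$lineage == reference_lineage, ]
  per_assay$ddct <- NA_real_
  for (r in seq_len(nrow(per_assay))) {
    i <- match(per_assay$assay[r], ref$assay)
    if (is.na(i)) {
      stop("assay ", per_assay$assay[r], " lacks the reference lineage")
    }
    per_assay$ddct[r] <- delta_delta_ct(per_assay$mu_dct[r], ref$mu_dct[i])
  }
  lineages <- if (is.null(lineage_order)) unique(per_assay$lineage)
              else lineage_order
  per_lineage <- do.call(rbind, lapply(lineages, function(l) {
    d <- per_assay$ddct[per_assay$lineage == l]
    cn <- copy_number(mean(d), cn_ref)
    data.frame(lineage = l, mu_ddct = mean(d),
               sd_ddct = if (length(d) > 1) stats::sd(d) else 0,
               cn_real = cn$cn_real, cn = cn$cn_integer)
  }))
  structure(list(per_assay = per_assay, per_lineage = per_lineage,
                 reference_lineage = reference_lineage, cn_ref = cn_ref),
            class = "nav_qpcr")
}

#' @export
print.nav_qpcr <- function(x, ...) {
  cat("Relative copy number (calibrator:", x$reference_lineage,
      "=", x$cn_ref, "copies)\n")
  pa <- x$per_assay
  pa$mu_dct <- round(pa$mu_dct, 1)
  if ("sd_dct" %in% names(pa)) pa$sd_dct <- round(pa$sd_dct, 2)
  pa$ddct <- round(pa$ddct, 1)
  print(pa, row.names = FALSE)
  pl <- x$per_lineage
  pl$mu_ddct <- round(pl$mu_ddct, 1)
  pl$sd_ddct <- round(pl$sd_ddct, 2)
  pl$cn_real <- round(pl$cn_real, 2)
  print(pl, row.names = FALSE)
  invisible(x)
}

#' Read a qPCR CT table
#'
#' Columns: `lineage`, `assay`, `pool` (optional), `replicate`, `gene`
#' (`target`/`reference`), `ct`.
#'
#' @param path CSV file path.
#' @return The parsed data frame.
#' @export
read_qpcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lineage", "assay", "replicate", "gene", "ct")
  if (!all(need %in% names(df))) {
    stop("qPCR CSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}
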