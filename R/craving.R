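#' Within-case correlations between regional volume and craving score
#'
#' Pearson (or Spearman) correlation between the symptom-severity (craving)
#' score and each region's gray-matter volume across subjects of the case
#' group, with Bonferroni correction p_bonf = min(1, m * p_raw) over the m
#' regions tested. By default all regions form the correction family; pass
#' \code{regions} to restrict (e.g. to subcortical regions only). An
#' optional partial correlation controlling for TIV is available but off by
#' default.
#'
#' @param g a \code{gmv_table} with craving scores for all case subjects.
#' @param regions optional integer indices or region names restricting the
#'   tested (and corrected) family.
#' @param alpha significance level on the Bonferroni-adjusted p.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param partial_tiv if TRUE, partial correlation controlling TIV
#'   (correlation of residuals after regressing both variables on TIV).
#' @return data.frame (region, r, p_raw, p_bonf, significant) sorted by r
#'   descending.
#' @export
craving_correlations <- function(g, regions = NULL, alpha = 0.05,
                                 method = c("pearson", "spearman"),
                                 partial_tiv = FALSE) {
  stopifnot(inherits(g, "gmv_table"))
  method <- match.arg(method)
  keep <- g$group == "case"
  if (sum(keep) < 4) stop("need at least 4 case subjects")
  if (is.null(g$craving)) stop("no craving scores in table")
  cr <- g$craving[keep]
  if (anyNA(cr))
    stop("missing craving for subjects: ",
         paste(g$subject_ids[keep][is.na(cr)], collapse = ", "))
  if (stats::sd(cr) == 0) stop("craving score is constant")
  Y <- g$values[keep, , drop = FALSE]
  region_names <- colnames(Y)
  if (is.null(region_names)) region_names <- paste0("R", seq_len(ncol(Y)))
  idx <- seq_len(ncol(Y))
  if (!is.null(regions)) {
    idx <- if (is.character(regions)) match(regions, region_names) else regions
    if (anyNA(idx)) stop("unknown region in 'regions'")
  }
  if (partial_tiv) {
    tiv <- g$tiv[keep]
    cr <- stats::resid(stats::lm(cr ~ tiv))
    Y <- stats::resid(stats::lm(Y ~ tiv))
  }
  m <- length(idx)
  res <- lapply(idx, function(j) {
    ct <- suppressWarnings(
      stats::cor.test(cr, Y[, j], method = method, exact = FALSE))
    data.frame(region = region_names[j], r = unname(ct$estimate),
               p_raw = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_bonf <- pmin(1, out$p_raw * m)
  out$significant <- out$p_bonf < alpha
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}
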