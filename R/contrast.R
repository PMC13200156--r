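#' Construct a subject-by-region gray-matter-volume table
#'
#' @param values numeric S x N matrix of regional volumes (e.g. cm^3 of
#'   modulated gray matter per atlas region).
#' @param group character/factor S-vector with levels \code{case} and
#'   \code{control}; both groups must be non-empty.
#' @param tiv numeric S-vector of total intracranial volumes (strictly
#'   positive), the head-size nuisance covariate.
#' @param subject_ids optional subject labels.
#' @param craving optional numeric S-vector of symptom-severity scores
#'   (NA allowed outside the case group).
#' @return object of class \code{gmv_table}.
#' @export
gmv_table <- function(values, group, tiv, subject_ids = NULL, craving = NULL) {
  values <- as.matrix(values)
  s <- nrow(values)
  group <- as.character(group)
  if (!all(group %in% c("case", "control")))
    stop("group must contain only 'case' and 'control'")
  if (!all(c("case", "control") %in% group))
    stop("both groups must be non-empty")
  if (length(group) != s || length(tiv) != s)
    stop("group/tiv length must match number of subjects")
  if (any(tiv <= 0)) stop("tiv must be strictly positive")
  if (!is.null(craving) && length(craving) != s)
    stop("craving length must match number of subjects")
  if (is.null(subject_ids)) subject_ids <- paste0("S", seq_len(s))
  structure(list(values = values, subject_ids = as.character(subject_ids),
                 group = group, tiv = as.numeric(tiv), craving = craving,
                 n_subjects = s, n_regions = ncol(values)),
            class = "gmv_table")
}

#' Read a cohort volume table from CSV
#'
#' Expected columns: \code{subject_id}, \code{group}, \code{tiv}, optional
#' \code{craving}, then one column per region named by atlas label. When a
#' connectome is supplied, region columns are reordered to its region order
#' (the single source of truth).
#'
#' @param path CSV path.
#' @param connectome optional \code{ndm_connectome} whose region order the
#'   columns must match.
#' @return a \code{gmv_table}.
#' @export
read_gmv_table <- function(path, connectome = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- intersect(c("subject_id", "group", "tiv", "craving"), names(df))
  region_cols <- setdiff(names(df), meta_cols)
  if (!is.null(connectome)) {
    missing <- setdiff(connectome$region_ids, region_cols)
    if (length(missing) > 0)
      stop("cohort table lacks region columns: ",
           paste(utils::head(missing, 5), collapse = ", "))
    region_cols <- connectome$region_ids
  }
  gmv_table(as.matrix(df[, region_cols]), group = df$group, tiv = df$tiv,
            subject_ids = df$subject_id, craving = df$craving)
}

#' @export
print.gmv_table <- function(x, ...) {
  cat("GMV table: ", x$n_subjects, " subjects (",
      sum(x$group == "case"), " case / ", sum(x$group == "control"),
      " control) x ", x$n_regions, " regions",
      if (!is.null(x$craving)) ", with craving scores", "\n", sep = "")
  invisible(x)
}

#' Per-region case-control contrast with TIV covariate
#'
#' For each region independently, fits the ordinary-least-squares model
#' volume ~ intercept + group + TIV and returns the group coefficient, its
#' t-statistic and two-sided p-value, plus Benjamini-Hochberg FDR-adjusted
#' p-values across regions. Under the default \code{"loss_positive"}
#' convention the group term is coded control-minus-case, so a positive
#' estimate/t means LOWER volume in cases (atrophy); half-wave rectifying
#' the map then yields the atrophy pattern directly.
#'
#' Since the design matrix is shared by all regions, the fit is solved once
#' by QR and applied to the whole S x N response matrix.
#'
#' @param g a \code{gmv_table} with at least 3 subjects per group.
#' @param direction \code{"loss_positive"} (default; positive = volume loss
#'   in cases) or \code{"gain_positive"}.
#' @return object of class \code{regional_contrast}: list with N-vectors
#'   \code{estimate} (volume units), \code{tvalue}, \code{pvalue},
#'   \code{p_fdr}, plus \code{df}, \code{direction_convention},
#'   \code{region_ids}.
#' @export
fit_regional_glm <- function(g, direction = c("loss_positive", "gain_positive")) {
  stopifnot(inherits(g, "gmv_table"))
  direction <- match.arg(direction)
  if (min(table(g$group)) < 3)
    stop("need at least 3 subjects per group")
  # loss_positive: indicator 1 for controls, so the coefficient is the
  # control-minus-case adjusted mean difference
  ind <- if (direction == "loss_positive") as.numeric(g$group == "control")
         else as.numeric(g$group == "case")
  X <- cbind(intercept = 1, group = ind, tiv = g$tiv)
  qx <- qr(X)
  if (qx$rank < 3)
    stop("design is rank-deficient (group and TIV collinear or constant)")
  Y <- g$values
  coefs <- qr.coef(qx, Y)                       # 3 x N
  res <- Y - X %*% coefs
  df <- nrow(X) - 3L
  sigma2 <- colSums(res^2) / df
  # floor the residual variance at a machine-precision multiple of the
  # response scale so perfectly fitting (noise-free) regions keep a finite
  # statistic proportional to the estimate instead of 0/0
  sigma2 <- pmax(sigma2, 1e-16 * mean(Y^2))
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  est <- coefs["group", ]
  tval <- est / se
  const <- apply(Y, 2, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant region(s): t set to 0, p to 1")
    tval[const] <- 0
    est[const] <- 0
  }
  tval[!is.finite(tval)] <- 0
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(list(estimate = unname(est), tvalue = unname(tval),
                 pvalue = unname(pval), p_fdr = fdr_correct(unname(pval)),
                 df = df, direction_convention = direction,
                 region_ids = colnames(Y)),
            class = "regional_contrast")
}

#' @export
print.regional_contrast <- function(x, ...) {
  cat("Regional contrast (", length(x$tvalue), " regions, df = ", x$df,
      ", convention: ", x$direction_convention, ")\n", sep = "")
  cat("  FDR < 0.05 in", sum(x$p_fdr < 0.05), "regions;",
      "t range [", signif(min(x$tvalue), 3), ",",
      signif(max(x$tvalue), 3), "]\n")
  invisible(x)
}

#' @export
summary.regional_contrast <- function(object, ...) {
  data.frame(region = object$region_ids %||% seq_along(object$tvalue),
             estimate = object$estimate, tvalue = object$tvalue,
             pvalue = object$pvalue, p_fdr = object$p_fdr,
             direction = object$direction_convention,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone nondecreasing in raw-p rank and
#' capped at 1.
#'
#' @param pvalues numeric vector in [0, 1]; NA is an error.
#' @return adjusted p-values, same length.
#' @export
fdr_correct <- function(pvalues) {
  if (anyNA(pvalues))
    stop("NaN/NA p-value at index ", which(is.na(pvalues))[1])
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Rectified atrophy or expansion pattern from a regional contrast
#'
#' Under the loss-positive convention, \code{mode = "atrophy"} keeps the
#' positive part of the statistic map (volume loss in cases) and
#' \code{mode = "expansion"} the positive part of its negation (volume
#' gain). By default the t-value map is rectified; the coefficient-estimate
#' map is available via \code{statistic = "estimate"}. All regions enter the
#' pattern; FDR is reporting-only.
#'
#' @param rc a \code{regional_contrast}.
#' @param mode \code{"atrophy"} or \code{"expansion"}.
#' @param statistic \code{"tvalue"} (default) or \code{"estimate"}.
#' @return nonnegative N-vector; error if identically zero.
#' @export
rectify_contrast <- function(rc, mode = c("atrophy", "expansion"),
                             statistic = c("tvalue", "estimate")) {
  stopifnot(inherits(rc, "regional_contrast"))
  mode <- match.arg(mode)
  statistic <- match.arg(statistic)
  v <- rc[[statistic]]
  out <- if (mode == "atrophy") pmax(v, 0) else pmax(-v, 0)
  if (all(out == 0))
    stop("no signal in requested direction (", mode, ")")
  names(out) <- rc$region_ids
  out
}

#' Write a regional contrast to TSV
#' @param rc a \code{regional_contrast}.
#' @param path output path.
#' @export
write_contrast <- function(rc, path) {
  utils::write.table(summary(rc), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
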