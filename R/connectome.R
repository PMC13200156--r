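#' Construct a structural connectome object
#'
#' Validates and packages a weighted, undirected region-by-region structural
#' connectivity matrix together with its region metadata. The region order of
#' the labels is the single source of truth for every vector downstream
#' (contrast maps, diffusion states, rankings).
#'
#' @param weights numeric N x N matrix of nonnegative connection strengths
#'   (arbitrary tractography units). Small asymmetries (relative magnitude
#'   below \code{asym_tol}) are symmetrized by averaging; larger asymmetries
#'   are an error. Nonzero diagonal entries (self-loops) are stripped with a
#'   warning.
#' @param region_ids character vector of N region labels. Defaults to
#'   dimnames or \code{"R1"..."RN"}.
#' @param region_meta optional data.frame with one row per region and columns
#'   \code{name}, \code{hemisphere} (\code{"L"}, \code{"R"} or \code{"BL"})
#'   and \code{tier} (\code{"cortical"} or \code{"subcortical"}).
#' @param asym_tol relative asymmetry tolerance (default \code{1e-9}).
#' @return an object of class \code{ndm_connectome}: a list with elements
#'   \code{weights}, \code{region_ids}, \code{region_meta}, \code{n_regions}
#'   and \code{log} (a character vector of modifications applied on load).
#' @examples
#' w <- matrix(c(0, 1, 1, 1, 0, 2, 1, 2, 0), 3, 3)
#' ndm_connectome(w, region_ids = c("A", "B", "C"))
#' @export
ndm_connectome <- function(weights, region_ids = NULL, region_meta = NULL,
                           asym_tol = 1e-9) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("weights must be a numeric matrix")
  if (nrow(weights) != ncol(weights))
    stop("weights must be square, got ", nrow(weights), " x ", ncol(weights))
  n <- nrow(weights)
  bad <- which(is.na(weights), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("NaN/NA weight at cell (", bad[1, 1], ", ", bad[1, 2], ")")
  neg <- which(weights < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop("negative weight at cell (", neg[1, 1], ", ", neg[1, 2], "): ",
         weights[neg[1, 1], neg[1, 2]])

  log <- character(0)
  mx <- max(abs(weights))
  asym <- max(abs(weights - t(weights)))
  if (asym > 0) {
    if (mx > 0 && asym > asym_tol * mx)
      stop("matrix asymmetric beyond tolerance (max |w_ij - w_ji| = ",
           signif(asym, 4), "); refusing to symmetrize")
    weights <- (weights + t(weights)) / 2
    log <- c(log, sprintf("symmetrized asymmetry of max %.3g by averaging", asym))
  }
  if (any(diag(weights) != 0)) {
    warning("self-loops stripped from diagonal")
    log <- c(log, "stripped nonzero diagonal")
    diag(weights) <- 0
  }

  if (is.null(region_ids)) {
    region_ids <- rownames(weights)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(n))
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != n)
    stop("label/matrix dimension mismatch: ", length(region_ids),
         " labels for ", n, " regions")
  if (is.null(region_meta)) {
    region_meta <- data.frame(name = region_ids,
                              hemisphere = "BL",
                              tier = "cortical",
                              stringsAsFactors = FALSE)
  }
  if (nrow(region_meta) != n)
    stop("region_meta has ", nrow(region_meta), " rows for ", n, " regions")
  stopifnot(all(c("name", "hemisphere", "tier") %in% names(region_meta)))

  dimnames(weights) <- list(region_ids, region_ids)
  structure(list(weights = weights, region_ids = region_ids,
                 region_meta = region_meta, n_regions = n, log = log),
            class = "ndm_connectome")
}

#' Read a connectome matrix and region labels from delimited text files
#'
#' The matrix file is a whitespace- or comma-delimited N x N numeric matrix,
#' either headerless or with a header row whose names match the labels file.
#' The labels file is a CSV with columns \code{index} (1-based),
#' \code{name}, \code{hemisphere} and \code{tier}.
#'
#' @param path path to the matrix file.
#' @param labels_path path to the region-labels CSV; optional.
#' @inheritParams ndm_connectome
#' @return an \code{ndm_connectome}; region order follows the labels file.
#' @export
read_connectome <- function(path, labels_path = NULL, asym_tol = 1e-9) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- !grepl("^[-0-9.,eE+ \t]+$", first)
  m <- utils::read.table(path, sep = sep, header = has_header,
                         row.names = if (has_header) 1 else NULL,
                         check.names = FALSE)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  meta <- NULL
  ids <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    stopifnot(all(c("index", "name", "hemisphere", "tier") %in% names(lab)))
    lab <- lab[order(lab$index), , drop = FALSE]
    ids <- lab$name
    meta <- lab[, c("name", "hemisphere", "tier")]
    if (has_header) {
      if (!setequal(colnames(m), ids))
        stop("matrix header does not match labels file")
      m <- m[ids, ids]  # labels define the canonical order
    }
  }
  ndm_connectome(m, region_ids = ids, region_meta = meta, asym_tol = asym_tol)
}

#' @export
print.ndm_connectome <- function(x, ...) {
  nz <- sum(x$weights > 0) / 2
  cat("Structural connectome:", x$n_regions, "regions,", nz, "edges\n")
  cat("  weight range: [", signif(min(x$weights[x$weights > 0]), 4), ", ",
      signif(max(x$weights), 4), "]\n", sep = "")
  if (length(x$log)) cat("  load notes:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' Symmetric normalized graph Laplacian and its eigendecomposition
#'
#' Builds H = I - D^{-1/2} W D^{-1/2}, where D is the diagonal matrix of node
#' strengths (total weighted connections per node), and returns the full
#' eigendecomposition with eigenvalues in ascending order. Eigenmodes with
#' small eigenvalues are the persistent diffusion patterns of the network.
#'
#' H is invariant to a global rescaling of the weights, and for a connected
#' graph has exactly one zero eigenvalue with nullspace direction
#' D^{1/2} 1; all eigenvalues lie in [0, 2].
#'
#' @param c an \code{ndm_connectome}.
#' @return an object of class \code{ndm_laplacian}: list with \code{H}
#'   (N x N), \code{eigenvalues} (ascending), \code{eigenvectors}
#'   (orthonormal columns, column k paired with eigenvalue k), \code{degree}
#'   (node strengths), \code{region_ids}, \code{region_meta},
#'   \code{n_components}.
#' @export
build_laplacian <- function(c) {
  stopifnot(inherits(c, "ndm_connectome"))
  w <- c$weights
  d <- rowSums(w)
  iso <- which(d <= 0)
  if (length(iso) > 0)
    stop("isolated regions (zero degree): ",
         paste(c$region_ids[iso], collapse = ", "))
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  ncomp <- igraph::components(g)$no
  if (ncomp > 1)
    warning("connectome is disconnected (", ncomp,
            " components); diffusion conserves within components")
  s <- 1 / sqrt(d)
  H <- -w * tcrossprod(s)       # -D^{-1/2} W D^{-1/2}
  diag(H) <- diag(H) + 1
  H <- (H + t(H)) / 2           # guard symmetry against rounding
  e <- eigen(H, symmetric = TRUE)
  ord <- seq(length(e$values), 1)  # eigen() returns descending
  structure(list(H = H,
                 eigenvalues = e$values[ord],
                 eigenvectors = e$vectors[, ord, drop = FALSE],
                 degree = d,
                 region_ids = c$region_ids,
                 region_meta = c$region_meta,
                 n_regions = c$n_regions,
                 n_components = ncomp),
            class = "ndm_laplacian")
}

#' @export
print.ndm_laplacian <- function(x, ...) {
  cat("Normalized graph Laplacian:", x$n_regions, "regions\n")
  cat("  eigenvalue range: [", signif(min(x$eigenvalues), 4), ", ",
      signif(max(x$eigenvalues), 4), "]; components:", x$n_components, "\n")
  invisible(x)
}
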