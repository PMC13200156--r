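#' Specification for a synthetic connectome-and-cohort study
#'
#' Bundles every parameter of the synthetic generator: a modular weighted
#' connectome, a two-group cohort of regional volumes with a TIV confound
#' and Gaussian noise, a group-difference map planted by running the
#' diffusion forward model from a known seed region, and craving scores
#' linearly coupled to designated (subcortical) regions. Because the
#' planted effect IS the diffusion forward model, recovering the true seed
#' is a genuine inverse problem, not a smoke test.
#'
#' Defaults describe a desk-scale study: 46 regions in 4 modules, 60 cases
#' vs 40 controls, the case group losing volume along the diffusion
#' pattern of region 7 at model time 3 (early-transient, so the planted
#' map is still seed-specific rather than near the degree-weighted steady
#' state), regional volumes of a few cm^3 with measurement noise of
#' 0.25 cm^3 and a TIV confound.
#'
#' @param n_regions,n_modules connectome size and community count.
#' @param intra_density,inter_density edge probability within / between
#'   modules (in (0, 1]).
#' @param weight_meanlog,weight_sdlog lognormal edge-weight parameters.
#' @param n_cases,n_controls group sizes (>= 3 each).
#' @param true_seed planted epicenter (region index).
#' @param plant_time model time at which the planted diffusion pattern is
#'   taken (should lie on the analysis time grid).
#' @param effect_scale volume loss per unit diffusion load (cm^3); 0 gives
#'   a null study.
#' @param noise_sd per-region measurement noise SD (cm^3).
#' @param tiv_mean,tiv_sd total intracranial volume distribution (cm^3).
#' @param tiv_loading regional volume gained per cm^3 of TIV.
#' @param craving_regions indices whose volumes drive the craving score;
#'   NULL picks the first two subcortical regions.
#' @param craving_effect target correlation between craving and the
#'   driver-region volume signal.
#' @param rng_seed master seed; all randomness flows through derived
#'   substreams (graph / cohort / noise / craving) so fixtures are
#'   bit-reproducible.
#' @return object of class \code{synthetic_spec} (a validated list).
#' @export
synthetic_spec <- function(n_regions = 46, n_modules = 4,
                           intra_density = 0.6, inter_density = 0.08,
                           weight_meanlog = 0, weight_sdlog = 0.75,
                           n_cases = 60, n_controls = 40,
                           true_seed = 7, plant_time = 3,
                           effect_scale = 3.5, noise_sd = 0.25,
                           tiv_mean = 1450, tiv_sd = 120,
                           tiv_loading = 0.004,
                           craving_regions = NULL, craving_effect = 0.3,
                           rng_seed = 42) {
  stopifnot(intra_density > 0, intra_density <= 1,
            inter_density > 0, inter_density <= 1,
            n_cases >= 3, n_controls >= 3,
            true_seed >= 1, true_seed <= n_regions,
            noise_sd >= 0, plant_time >= 0, n_modules >= 1)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a modular weighted connectome with known community structure
#'
#' Weighted stochastic-block-style graph: dense lognormally weighted edges
#' within modules, sparse edges between them; the last module is labelled
#' subcortical, the rest cortical. Connectivity is guaranteed (bridge edges
#' of median weight are added between components if needed). Deterministic
#' under the spec's seed.
#'
#' @param spec a \code{synthetic_spec}.
#' @return an \code{ndm_connectome} with a \code{module} column in its
#'   region metadata.
#' @export
generate_connectome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_regions
  set.seed(substream_seed(spec$rng_seed, 1L))  # graph substream
  module <- sort(rep_len(seq_len(spec$n_modules), n))
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  same <- module[ut[, 1]] == module[ut[, 2]]
  dens <- ifelse(same, spec$intra_density, spec$inter_density)
  on <- stats::runif(nrow(ut)) < dens
  wts <- stats::rlnorm(sum(on), spec$weight_meanlog, spec$weight_sdlog)
  w[ut[on, , drop = FALSE]] <- wts
  w <- w + t(w)
  # bridge any disconnected components with median-weight edges
  repeat {
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    comp <- igraph::components(g)
    if (comp$no == 1) break
    a <- sample(which(comp$membership == 1), 1)
    b <- sample(which(comp$membership == 2), 1)
    w[a, b] <- w[b, a] <- stats::median(w[w > 0])
  }
  tier <- ifelse(module == spec$n_modules, "subcortical", "cortical")
  hemi <- rep_len(c("L", "R"), n)
  name <- sprintf("%s_M%d_%02d_%s",
                  ifelse(tier == "cortical", "Ctx", "Sub"), module,
                  seq_len(n), hemi)
  meta <- data.frame(name = name, hemisphere = hemi, tier = tier,
                     module = module, stringsAsFactors = FALSE)
  ndm_connectome(w, region_ids = name, region_meta = meta)
}

#' Generate a two-group cohort with a planted diffusion-shaped group effect
#'
#' Regional volumes are region-specific baselines plus a TIV confound plus
#' Gaussian noise; case subjects additionally LOSE
#' \code{effect_scale * x(plant_time)} where x is the heat-kernel diffusion
#' from \code{true_seed} on the supplied connectome (set
#' \code{direction = "expansion"} to plant a volume gain instead). Craving
#' scores (cases only) are a linear function of the designated regions'
#' volumes plus noise, standardized so the planted coupling approximates
#' \code{craving_effect} and mapped to a questionnaire-like scale
#' (mean 50, SD 10).
#'
#' @param spec a \code{synthetic_spec}.
#' @param c an \code{ndm_connectome} (typically from
#'   \code{\link{generate_connectome}}).
#' @param direction \code{"atrophy"} (cases lose volume along the planted
#'   pattern; default) or \code{"expansion"}.
#' @return a \code{gmv_table}; the planted pattern is attached as attribute
#'   \code{"planted_pattern"} and the seed as \code{"true_seed"}.
#' @export
generate_cohort <- function(spec, c, direction = c("atrophy", "expansion")) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(c, "ndm_connectome"))
  direction <- match.arg(direction)
  n <- c$n_regions
  s <- spec$n_cases + spec$n_controls
  L <- build_laplacian(c)
  x0 <- numeric(n); x0[spec$true_seed] <- 1
  planted <- drop(diffuse(L, x0, beta = 1, times = spec$plant_time)$trajectory)

  set.seed(substream_seed(spec$rng_seed, 2L))  # cohort substream
  mu <- stats::runif(n, 4, 10)                 # baseline regional volumes, cm^3
  tiv <- stats::rnorm(s, spec$tiv_mean, spec$tiv_sd)
  group <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))

  set.seed(substream_seed(spec$rng_seed, 3L))  # noise substream
  values <- matrix(mu, s, n, byrow = TRUE) +
    spec$tiv_loading * tiv +
    matrix(stats::rnorm(s * n, 0, spec$noise_sd), s, n)
  sgn <- if (direction == "atrophy") -1 else 1
  is_case <- group == "case"
  values[is_case, ] <- values[is_case, ] +
    sgn * spec$effect_scale * matrix(planted, sum(is_case), n, byrow = TRUE)
  colnames(values) <- c$region_ids

  set.seed(substream_seed(spec$rng_seed, 4L))  # craving substream
  cr_idx <- spec$craving_regions
  if (is.null(cr_idx)) {
    sub <- which(c$region_meta$tier == "subcortical")
    cr_idx <- utils::head(if (length(sub) >= 2) sub else seq_len(n), 2)
  }
  drv <- rowSums(values[is_case, cr_idx, drop = FALSE])
  z <- (drv - mean(drv)) / stats::sd(drv)
  lat <- spec$craving_effect * z +
    sqrt(max(0, 1 - spec$craving_effect^2)) * stats::rnorm(sum(is_case))
  craving <- rep(NA_real_, s)
  craving[is_case] <- 50 + 10 * lat

  out <- gmv_table(values, group = group, tiv = tiv, craving = craving)
  attr(out, "planted_pattern") <- planted
  attr(out, "true_seed") <- spec$true_seed
  out
}

#' Write a synthetic study to the on-disk formats the pipeline reads
#'
#' @param spec a \code{synthetic_spec}.
#' @param dir output directory (created if needed). Writes
#'   \code{connectome.tsv}, \code{labels.csv}, \code{cohort.csv} and
#'   \code{spec.json}.
#' @return invisibly, the directory.
#' @export
write_synthetic_study <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- generate_connectome(spec)
  g <- generate_cohort(spec, cm)
  utils::write.table(cm$weights, file.path(dir, "connectome.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  lab <- cbind(index = seq_len(cm$n_regions),
               cm$region_meta[, c("name", "hemisphere", "tier")])
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  df <- data.frame(subject_id = g$subject_ids, group = g$group,
                   tiv = g$tiv, craving = g$craving,
                   g$values, check.names = FALSE)
  utils::write.csv(df, file.path(dir, "cohort.csv"), row.names = FALSE,
                   na = "")
  jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
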