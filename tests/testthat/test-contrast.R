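test_that("a null contrast yields t = 0, p = 1 in every region", {
  set.seed(1)
  s <- 12
  values <- matrix(rep(c(5, 6, 7), each = s), s, 3)   # constant regions
  g <- gmv_table(values, group = rep(c("case", "control"), each = 6),
                 tiv = rnorm(s, 1450, 100))
  expect_warning(rc <- fit_regional_glm(g), "constant region")
  expect_equal(rc$tvalue, rep(0, 3))
  expect_equal(rc$pvalue, rep(1, 3))
})

test_that("GLM coefficients and t-values match the closed-form OLS oracle", {
  g <- toy_cohort(s = 20, n = 5, seed = 11)
  rc <- fit_regional_glm(g)
  X <- cbind(1, as.numeric(g$group == "control"), g$tiv)
  xtx_inv <- solve(t(X) %*% X)
  for (j in 1:5) {
    y <- g$values[, j]
    beta <- xtx_inv %*% t(X) %*% y           # normal equations
    res <- y - X %*% beta
    s2 <- sum(res^2) / (20 - 3)
    tj <- beta[2] / sqrt(s2 * xtx_inv[2, 2])
    expect_equal(rc$estimate[j], beta[2], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(rc$tvalue[j], tj, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(rc$pvalue[j], 2 * pt(-abs(tj), 17), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  expect_true(all(sign(rc$estimate) == sign(rc$tvalue)))
  expect_true(all(rc$p_fdr >= rc$pvalue))
})

test_that("the sign convention makes positive t mean volume loss in cases", {
  set.seed(8)
  s <- 40
  group <- rep(c("case", "control"), each = 20)
  tiv <- rnorm(s, 1450, 100)
  values <- matrix(7 + 0.004 * tiv + rnorm(s, 0, 0.1), s, 1)
  values[group == "case", 1] <- values[group == "case", 1] - 1  # cases lower
  g <- gmv_table(values, group, tiv)
  rc <- fit_regional_glm(g)
  expect_gt(rc$tvalue[1], 0)
  expect_equal(rc$direction_convention, "loss_positive")
  rc2 <- fit_regional_glm(g, direction = "gain_positive")
  expect_equal(rc2$tvalue[1], -rc$tvalue[1], tolerance = 1e-12)
})

test_that("the TIV covariate absorbs an added TIV-proportional confound", {
  g <- toy_cohort(s = 30, n = 4, seed = 9)
  rc1 <- fit_regional_glm(g)
  g2 <- gmv_table(g$values + 0.123 * g$tiv, g$group, g$tiv)
  rc2 <- fit_regional_glm(g2)
  expect_equal(rc1$tvalue, rc2$tvalue, tolerance = 1e-8)
})

test_that("degenerate designs are rejected", {
  set.seed(2)
  g <- gmv_table(matrix(rnorm(12), 6, 2),
                 group = rep(c("case", "control"), 3),
                 tiv = rep(1450, 6))            # constant TIV: collinear
  expect_error(fit_regional_glm(g), "rank-deficient")
  g2 <- gmv_table(matrix(rnorm(8), 4, 2),
                  group = c("case", "case", "control", "control"),
                  tiv = rnorm(4, 1450, 50))
  expect_error(fit_regional_glm(g2), "at least 3")
})

test_that("BH adjustment matches hand values and a brute-force oracle", {
  expect_equal(fdr_correct(0.5), 0.5)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  set.seed(33)
  for (i in 1:10) {
    p <- runif(100)
    expect_equal(fdr_correct(p), bh_bruteforce(p), tolerance = 1e-12)
  }
  expect_error(fdr_correct(c(0.1, NA)), "index 2")
  expect_error(fdr_correct(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("rectification splits the statistic map into atrophy and expansion", {
  rc <- structure(list(tvalue = c(2, -1, 0), estimate = c(0.2, -0.1, 0),
                       region_ids = c("a", "b", "c")),
                  class = "regional_contrast")
  expect_equal(rectify_contrast(rc, "atrophy"), c(a = 2, b = 0, c = 0))
  expect_equal(rectify_contrast(rc, "expansion"), c(a = 0, b = 1, c = 0))
  set.seed(4)
  t <- rnorm(20)
  rc2 <- structure(list(tvalue = t, region_ids = NULL),
                   class = "regional_contrast")
  expect_equal(rectify_contrast(rc2, "atrophy") +
                 rectify_contrast(rc2, "expansion"), abs(t))
  rc3 <- structure(list(tvalue = c(-1, -2), region_ids = NULL),
                   class = "regional_contrast")
  expect_error(rectify_contrast(rc3, "atrophy"), "no signal")
  expect_equal(rectify_contrast(rc2, "expansion", statistic = "tvalue"),
               pmax(-t, 0), ignore_attr = TRUE)
})

test_that("group-test type-I error is nominal under the null", {
  set.seed(77)
  s <- 60
  group <- rep(c("case", "control"), c(36, 24))
  tiv <- rnorm(s, 1450, 120)
  n_reg <- 1500
  values <- matrix(rnorm(s * n_reg, 7, 0.5), s, n_reg) + 0.004 * tiv
  g <- gmv_table(values, group, tiv)
  rc <- fit_regional_glm(g)
  rej <- mean(rc$pvalue < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / n_reg)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})

test_that("cohort shapes at study scale produce full-length outputs", {
  spec <- synthetic_spec(n_cases = 288, n_controls = 165, rng_seed = 3)
  cm <- generate_connectome(spec)
  g <- generate_cohort(spec, cm)
  expect_equal(g$n_subjects, 453)
  rc <- fit_regional_glm(g)
  expect_length(rc$tvalue, spec$n_regions)
  expect_length(rc$p_fdr, spec$n_regions)
})

test_that("contrast tables round-trip through CSV and TSV", {
  d <- withr::local_tempdir()
  spec <- synthetic_spec(rng_seed = 6)
  cm <- generate_connectome(spec)
  g <- generate_cohort(spec, cm)
  df <- data.frame(subject_id = g$subject_ids, group = g$group,
                   tiv = g$tiv, craving = g$craving, g$values,
                   check.names = FALSE)
  write.csv(df, file.path(d, "cohort.csv"), row.names = FALSE, na = "")
  g2 <- read_gmv_table(file.path(d, "cohort.csv"), cm)
  expect_equal(g2$values, g$values, tolerance = 1e-12, ignore_attr = TRUE)
  rc <- fit_regional_glm(g2)
  write_contrast(rc, file.path(d, "contrast.tsv"))
  back <- read.delim(file.path(d, "contrast.tsv"))
  expect_equal(back$tvalue, rc$tvalue, tolerance = 1e-6)
})
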