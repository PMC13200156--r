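test_that("a noise-free planted pattern is traced back to its seed", {
  spec <- synthetic_spec(n_regions = 40, rng_seed = 17)
  L <- build_laplacian(generate_connectome(spec))
  x0 <- numeric(40); x0[7] <- 1
  pattern <- drop(diffuse(L, x0, times = 20)$trajectory)
  fit <- fit_epicenter(L, pattern)
  expect_equal(fit$ranking[1], 7)
  expect_gte(fit$peak_r[7], 0.999)
  expect_equal(fit$peak_t[7], 20)
  # the per-seed curve API agrees with the matrix fit
  cc <- correlation_curve(L, 7, pattern)
  expect_equal(cc$r, unname(fit$curves[7, ]), tolerance = 1e-10)
})

test_that("t = 0 correlations equal the hand-computed one-hot correlation", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 2
  w[3, 4] <- w[4, 3] <- 1; w[1, 4] <- w[4, 1] <- 0.5
  L <- build_laplacian(ndm_connectome(w))
  pattern <- c(3, 1, 2, 0.5)
  fit <- fit_epicenter(L, pattern, times = c(0, 1))
  for (s in 1:4) {
    onehot <- numeric(4); onehot[s] <- 1
    expect_equal(fit$curves[s, 1], cor(onehot, pattern), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("curves are bounded, peaks are exact maxima, ranking is a permutation", {
  set.seed(50)
  L <- build_laplacian(rand_connectome(15, seed = 50))
  pattern <- abs(rnorm(15))
  fit <- fit_epicenter(L, pattern)
  expect_true(all(fit$curves >= -1 & fit$curves <= 1))
  expect_equal(fit$peak_r, apply(fit$curves, 1, max), ignore_attr = TRUE)
  expect_setequal(fit$ranking, 1:15)
  expect_true(all(diff(fit$peak_r[fit$ranking]) <= 1e-15))
})

test_that("region relabeling permutes the ranking equivariantly", {
  spec <- synthetic_spec(n_regions = 20, n_modules = 3, rng_seed = 23)
  cm <- generate_connectome(spec)
  set.seed(23)
  pattern <- abs(rnorm(20))
  fit <- fit_epicenter(build_laplacian(cm), pattern)
  perm <- sample(20)
  w2 <- cm$weights[perm, perm]
  cm2 <- ndm_connectome(w2, region_ids = cm$region_ids[perm],
                        region_meta = cm$region_meta[perm, ])
  fit2 <- fit_epicenter(build_laplacian(cm2), pattern[perm])
  # seed s in the original appears as match(s, perm) after relabeling
  expect_equal(fit2$peak_r[match(fit$ranking, perm)[1]],
               fit$peak_r[fit$ranking[1]], tolerance = 1e-10)
  expect_equal(cm2$region_ids[fit2$ranking[1]],
               cm$region_ids[fit$ranking[1]])
})

test_that("planted epicenters are recovered at the prescribed noise level", {
  # moderate-noise regime calibrated so the rectified t-map correlates
  # ~0.6 with the planted truth; the true seed must stay in the top 3
  ranks <- vapply(1:100, function(i) {
    sp <- synthetic_spec(effect_scale = 2, rng_seed = 5000 + i)
    cm <- generate_connectome(sp)
    g <- generate_cohort(sp, cm)
    pat <- rectify_contrast(fit_regional_glm(g), "atrophy")
    fit <- fit_epicenter(build_laplacian(cm), pat)
    which(fit$ranking == sp$true_seed)
  }, numeric(1))
  expect_gte(mean(ranks <= 3), 0.9)
})

test_that("seed exclusion is available as a sensitivity flag", {
  L <- build_laplacian(rand_connectome(12, seed = 31))
  set.seed(31)
  pattern <- abs(rnorm(12))
  f1 <- fit_epicenter(L, pattern, times = c(1, 2))
  f2 <- fit_epicenter(L, pattern, times = c(1, 2), exclude_seed = TRUE)
  expect_false(isTRUE(all.equal(f1$curves, f2$curves)))
  cc <- correlation_curve(L, 3, pattern, times = c(1, 2),
                          exclude_seed = TRUE)
  expect_equal(cc$r, unname(f2$curves[3, ]), tolerance = 1e-10)
})

test_that("invalid patterns and seeds are rejected", {
  L <- build_laplacian(rand_connectome(6, seed = 1))
  expect_error(fit_epicenter(L, c(-1, rep(1, 5))), "nonnegative")
  expect_error(fit_epicenter(L, rep(0, 6)), "all zero")
  expect_error(fit_epicenter(L, rep(1, 3)), "length")
  expect_error(correlation_curve(L, 9, rep(1, 6)), "invalid seed")
})

test_that("the robustness sweep is invariant on noise-free planted data", {
  spec <- synthetic_spec(noise_sd = 0, rng_seed = 44)
  cm <- generate_connectome(spec)
  g <- generate_cohort(spec, cm)
  pat <- rectify_contrast(fit_regional_glm(g), "atrophy")
  L <- build_laplacian(cm)
  sw <- robustness_sweep(L, pat, betas = c(0.8, 1, 1.2),
                         horizons = c(30, 40, 50))
  expect_equal(nrow(sw), 9)
  expect_true(attr(sw, "invariant"))
  expect_equal(unique(sw$top_seed), spec$true_seed)
  # the discrete unit-step grid only approximates the rescaled peak time,
  # so peak r agrees across beta at reporting precision
  expect_lt(diff(range(sw$peak_r)), 0.02)

  # exact beta degeneracy: plant at t* = 12 so the rescaled peak times
  # 12/0.8 = 15 and 12/1.2 = 10 both lie on the unit grid
  x0 <- numeric(spec$n_regions); x0[spec$true_seed] <- 1
  pat12 <- drop(diffuse(L, x0, times = 12)$trajectory)
  sw12 <- robustness_sweep(L, pat12, betas = c(0.8, 1, 1.2), horizons = 30)
  expect_equal(diff(range(sw12$peak_r)), 0, tolerance = 1e-9)
  expect_equal(sw12$peak_t, c(15, 12, 10))

  single <- robustness_sweep(L, pat, betas = 1, horizons = 50)
  fit <- fit_epicenter(L, pat, beta = 1, times = 0:50)
  expect_equal(single$top_seed, fit$ranking[1])
  expect_equal(single$peak_r, fit$peak_r[fit$ranking[1]], tolerance = 1e-12)
})

test_that("epicenter methods expose the fit the way a model object should", {
  spec <- synthetic_spec(rng_seed = 2)
  cm <- generate_connectome(spec)
  g <- generate_cohort(spec, cm)
  pat <- rectify_contrast(fit_regional_glm(g), "atrophy")
  fit <- fit_epicenter(build_laplacian(cm), pat, pattern_mode = "atrophy")
  expect_s3_class(fit, "ndm_epicenter")
  expect_output(print(fit), "top epicenter")
  sm <- summary(fit, n_top = 5)
  expect_equal(nrow(sm), 5)
  expect_equal(sm$seed[1], fit$ranking[1])
  expect_length(coef(fit), spec$n_regions)
  pred <- predict(fit)
  expect_length(pred, spec$n_regions)
  expect_equal(cor(pred, pat), fit$peak_r[fit$ranking[1]], tolerance = 1e-8)
  expect_length(residuals(fit), spec$n_regions)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})
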