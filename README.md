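# ndmap — network diffusion mapping of disease epicenters

`ndmap` asks a simple question about a disorder's gray-matter alteration
map: *if the alteration had spread through the brain's white-matter
network from a single origin, which region is the most plausible origin?*
It is written for researchers who have (i) a weighted structural
connectome over an atlas parcellation and (ii) a subject × region
gray-matter-volume table for a case and a control group, and who want the
full epicenter-mapping analysis — group contrast, diffusion simulation,
seed ranking, eigenmode analysis, randomized-network null, and
symptom-severity correlations — as tested, reproducible R functions.

## The model

Pathology load **x**(t) diffuses on the connectome according to the
network heat equation

    dx/dt = -β H x,        H = I − D^(−1/2) W D^(−1/2),

where W holds connection strengths, D node strengths, and H is the
symmetric normalized graph Laplacian. The closed-form solution
x(t) = U e^(−Λβt) Uᵀ x₀ (with H = UΛUᵀ) is evaluated from one cached
eigendecomposition. The analysis then:

1. fits `volume ~ group + TIV` per region (OLS; group coded so positive =
   volume loss in cases) and rectifies the t-map into atrophy
   (max(t, 0)) and expansion (max(−t, 0)) patterns;
2. seeds every region with a unit load, diffuses over t = 0…50 (β = 1),
   and ranks seeds by the peak Pearson correlation between predicted and
   observed patterns — the top seed is the candidate **epicenter**;
3. correlates the first five Laplacian eigenmodes (|eigenvector|,
   Spearman, p < 0.01) with the observed patterns;
4. compares the empirical peak correlation against 1,000 degree-preserving
   rewired networks (95th percentile, add-one empirical p);
5. correlates craving scores with regional volumes within cases
   (Bonferroni over the region family).

A synthetic-study generator plants a known epicenter by running the same
forward model on a modular connectome, so every stage is testable with a
recoverable ground truth and no external data.

## Worked example

```r
library(ndmap)

spec <- synthetic_spec(rng_seed = 42)   # 46 regions, 60 cases / 40 controls
cm   <- generate_connectome(spec)       # modular weighted connectome
L    <- build_laplacian(cm)
g    <- generate_cohort(spec, cm)       # planted epicenter: region 7

rc  <- fit_regional_glm(g)
rc
#> Regional contrast (46 regions, df = 97, convention: loss_positive)
#>   FDR < 0.05 in 7 regions; t range [ -1.01 , 8.87 ]

pat <- rectify_contrast(rc, "atrophy")
fit <- fit_epicenter(L, pat, pattern_mode = "atrophy")
fit
#> Network diffusion epicenter fit (atrophy)
#>   46 seeds, t in [0, 50], beta = 1, pearson correlation
#>   top epicenter: Ctx_M1_07_L (peak r = 0.888 at t = 2)

head(summary(fit), 3)
#>   rank seed      region    peak_r peak_t
#> 1    1    7 Ctx_M1_07_L 0.8881744      2
#> 2    2    2 Ctx_M1_02_R 0.7933520      3
#> 3    3   10 Ctx_M1_10_R 0.7534367      4

nd <- null_distribution(cm, pat, candidate_seed = fit$ranking[1],
                        n_nulls = 200, rng_seed = 1)
nd
#> Rewired-network null distribution (200 networks, scope: all_seeds)
#>   empirical peak r = 0.888; null 95th percentile = 0.654; empirical p = 0.00498
```

The fit recovers the planted seed (region 7) as the top epicenter: the
diffusion pattern seeded there correlates r = 0.888 with the observed
atrophy map at its peak time, the next-best seeds trail it, and the fit
is specific to the real network's architecture — on degree-preserving
rewired surrogates the best achievable correlation is below 0.66 in 95%
of networks, giving an empirical p of about 0.005.

`plot(fit)` draws the correlation-over-time curves for the top seeds;
`coef`, `predict` and `residuals` expose the per-seed peaks, the
best-seed predicted pattern and its standardized misfit. The whole
analysis (both directions, eigenmodes, null, craving) runs as one call
via `run_pipeline()`, from an in-memory config or a YAML/JSON file, and
can write a TSV/JSON report bundle with a checksum manifest.

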