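# phepart

Isotopic-tracer flux analysis that partitions phenylalanine biosynthesis
between its two parallel routes, for plant metabolism groups running
¹⁵N-tyrosine feeding experiments (and for anyone who wants a tested,
simulation-backed reference implementation of the method).

## The method

Phenylalanine is made both in the plastid via arogenate (flux *v₁*) and
in the cytosol via phenylpyruvate with tyrosine as amino donor (flux
*v₂*). Fed ¹⁵N-tyrosine labels only the cytosolic route, so time courses
of the phenylalanine pool size *C(t)*, its ¹⁵N fractional abundance
*f(t)*, the tyrosine labelling fraction *f*<sub>Tyr</sub>, and cumulative
emission of phenylalanine-derived volatiles (consumption flux *v_c*)
determine both pathway fluxes. Over a 0–6 h window the observables are
linear in time, so each series is summarised by a fixed-intercept
least-squares slope, and the mass balances

    dC/dt   = v1 + v2 − vc
    d(fC)/dt = v2·fTyr − vc·f

are inverted on a 6-minute grid:

    v2(t) = [d(fC)/dt + vc·f(t)] / fTyr
    v1(t) = dC/dt − v2(t) + vc

Slope variances propagate to flux variances by the delta method (with a
seeded Monte-Carlo cross-check), and genotypes are compared with
Bonferroni-corrected Welch t-tests on absolute fluxes plus a test on the
*v₂* trend slopes. A synthetic-data generator (exact-linear and
mechanistic RK4 modes) provides datasets with known ground-truth fluxes,
so the whole pipeline is testable end to end.

## Worked example

Simulate a control vs transporter-knockdown experiment (3 vs 6
biological replicates, sampled 0/2/4/6 h) and fit the flux model:

```r
library(phepart)

pair <- make_rnai_pair(flux_scenario(noise_cv_pool = 0.02,
                                     noise_cv_emission = 0.02,
                                     noise_sd_frac = 0.004), seed = 1)
fit <- phepart(pair$data)
summary(fit)
```

```
Flux summary (control: control; times t0 = 0 h, t_end = 6 h)
  control (n=3):
    v1:  14.066 +/- 0.158 (t0)    12.790 +/- 0.148 (t_end)
    v2:   1.074 +/- 0.021 (t0)     2.350 +/- 0.051 (t_end)
    vc:   9.989    v2/v1 at t_end: 0.184
  rnai (n=6):
    v1:   9.438 +/- 0.107 (t0)     7.393 +/- 0.097 (t_end)
    v2:   2.110 +/- 0.030 (t0)     4.154 +/- 0.063 (t_end)
    vc:   6.470    v2/v1 at t_end: 0.562
    v1 vs control: 32.9% lower (t0), 42.2% lower (t_end)
Comparisons (Bonferroni-corrected, alpha = 0.05):
  control vs rnai        v1         t=0 h p = 0.0005162 *
  control vs rnai        v1         t=6 h p = 0.0001062 *
  control vs rnai        v2_slope          p = 8.235e-05 *
```

Reading it: fluxes are in nmol gFW⁻¹ h⁻¹ with propagated standard
errors. The knockdown's plastidial flux *v₁* is about a third lower than
control at the start of feeding and further behind by 6 h, its
consumption rate is rescaled by the configured emission fractions
(0.65 × control), and the cytosolic route's share of synthesis
(*v₂*/*v₁* at 6 h) rises from ~0.18 to ~0.56 — the flux redistribution
pattern the method is designed to detect. All three contrasts are
significant after Bonferroni correction.

`predict()`, `plot()`, `coef()`, `residuals()` and `simulate()` work on
the fitted object as usual; `run_pipeline(data, config, out_dir)` runs
the same analysis file-in/file-out (TSV tables, text report, provenance
log), and `read_flux_config()` reads the YAML configuration.

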