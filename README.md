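# phrelay

Analysis toolkit for inferring **pH-relay mechanisms of Ca²⁺ release** in
C-type lectins — receptors such as langerin that bind pathogens through a
Ca²⁺ cofactor at neutral pH and must release both in the mildly acidic
endosome. A moderate pH drop (7 → 6) protonates an allosteric sensor
histidine; the perturbed hydrogen-bond network moves a lysine proton donor
next to the Ca²⁺-coordinating carboxylates, weakening the coordination and,
after proton transfer, accelerating the unfolding of the loop that would
otherwise let Ca²⁺ rebind.

`phrelay` implements the complete quantitative chain of evidence for such a
mechanism, as a set of composable estimators in the classic R modelling
style (each `fit_*`/`estimate_*` returns a classed object with
`print`/`summary`/`coef`/`predict`/`plot` methods):

| stage | functions |
|---|---|
| synthetic data with known ground truth | `generate_langevin()`, `generate_rupture_traces()`, `generate_unfolding_times()`, `generate_itc_thermogram()`, `generate_hbond_toy()`, `generate_pka_records()` |
| trajectory featurization | `load_trajectory()`, `superpose()`, `compute_distances()`, `detect_hbonds()`, `rmsf()`, `rmsd_timeseries()`, `histogram_with_bootstrap()`, `population_fraction()` |
| dimensionality reduction | `fit_pca()`, `fit_tica()`, `predict()`, `energy_surface()`, `difference_density()` |
| conformational states | `fit_commonnn()` (common-nearest-neighbours density clustering), `select_cores()`, `cluster_report()` |
| core-set Markov models | `milestone_assign()`, `count_transitions()`, `estimate_msm()`, `implied_timescales()` |
| rupture-force statistics | `detect_rupture()`, `notched_box_stats()`, `summarize_ruptures()` |
| unfolding kinetics | `classify_unfolding()`, `survival_curve()`, `fit_exponential()`, `percent_unfolded()` |
| ensemble pKa | `parse_propka()`, `aggregate_pka()` |
| binding thermodynamics | `delta_g()`, `delta_delta_g()`, `fit_one_site()`, `binding_energy_table()` |
| orchestration | `make_demo()`, `run_pipeline()` |

The key statistics, in the field's standard notation:

- **Implied timescales** of a core-set Markov model at lag τ:
  *tᵢ = −τ / ln λᵢ₊₁*, from the eigenvalues of the reversible transition
  matrix estimated on milestoned core-set trajectories; lag-independence of
  the tᵢ certifies Markovianity.
- **tICA**: the generalized eigenproblem *C(τ) v = λ C(0) v* with the
  symmetrized time-lagged covariance, extracting the slowest linear
  coordinates.
- **CNN clustering**: points a, b are density-connected iff they lie within
  *r* of each other and share at least *n_c* common r-neighbours.
- **Censored exponential kinetics**: *k̂ = n_events / Σ tᵢ* over event and
  censoring times alike; *t₁/₂ = ln 2 / k̂*, *σ_k = k̂ / √n_events*.
- **Binding free energy**: *ΔG = RT ln K_d* (1 M standard state,
  R = 8.314 J mol⁻¹ K⁻¹), and the pH sensitivity
  *ΔΔG = ΔG(pH 6) − ΔG(pH 7)*.

## Worked example

Binding thermodynamics from the bundled ITC dissociation constants:

```r
library(phrelay)
binding_energy_table()
#>         variant pH Kd_uM    dG ddG
#> 1            WT  7   105 -22.9  NA
#> 2            WT  6   800 -17.8 5.1
#> 3         H294A  7    35 -25.6  NA
#> 4         H294A  6   125 -22.4 3.2
#> 5         E261D  7   108 -22.8  NA
#> 6         E261D  6   742 -18.0 4.8
#> 7 WT_remeasured  7   113 -22.7  NA
#> 8 WT_remeasured  6   802 -17.8 4.9
```

The wildtype loses 5.1 kJ/mol of Ca²⁺ binding free energy between pH 7 and
pH 6; removing the pH-sensor histidine (H294A) leaves a residual 3.2 kJ/mol
— the signature of a second pH sensor — while the E261D control keeps the
wildtype sensitivity.

A full conformational-dynamics round trip on synthetic double-well dynamics
whose exact slowest relaxation time is known from an independent grid
transfer operator:

```r
kB <- 0.0083144621                                  # kJ/(mol K)
pot <- double_well_potential(5 * kB * 300, 1)       # 5 kT barrier, wells at +/-1 nm
tr  <- generate_langevin(pot, 2e6, 5e-4, seed = 7, stride = 10)
x   <- matrix(tr[, 1], ncol = 1)

sub   <- x[seq(1, nrow(x), length.out = 1500), , drop = FALSE]
cl    <- fit_commonnn(sub, r = 0.1, n_c = 5, min_members = 30)
cl
#> <cnn_labels> 1500 points, 2 clusters, 15 noise (r = 0.1, n_c = 5, min 30)
#> sizes: 765, 720

cores <- select_cores(cl, sub)
ct    <- milestone_assign(list(x), cores)
implied_timescales(ct, lags = c(2, 5, 10, 20), dt_ns = attr(tr, "dt_ns"),
                   n_processes = 1)
#> <implied_timescales>
#>  lag_ns    t1_ns
#>   0.010 7.339565
#>   0.025 7.331956
#>   0.050 7.319263
#>   0.100 7.293834
#> converged (tol 0.2 ): TRUE

attr(tr, "ground_truth")$timescale_ns
#> [1] 7.219973
```

The Markov model recovers the 7.2 ns barrier-crossing timescale within 2%
and is lag-independent. Unfolding kinetics with right-censoring:

```r
d <- generate_unfolding_times(log(2) / 93, t_max = 220, n = 60, seed = 3)
fit_exponential(d)
#> <decay_fit> k = 0.007017 /ns, t_1/2 = 98.78 +/- 14 ns (47 events, 13 censored, mle)
#> KS distance to single exponential: 0.096
```

`make_demo(dir, seed)` writes a complete miniature study (two Langevin
ensembles, 80 pulling traces, 120 censored unfolding records, PROPKA-style
pKa files, the Kd table) plus a `config.yaml`; `run_pipeline(config)`
executes all stages and writes deterministic CSV/TSV/JSON outputs.

## Documentation

The methods vignette (`vignettes/ph-relay-analysis.Rmd`) describes the
models, their assumptions, the defaults and the known limitations; every
exported function carries full reference documentation.
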