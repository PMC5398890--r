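# preactive

Kinetic detection of **pre-active intermediate states** in pentameric
ligand-gated ion channel gating, built around the proton-gated channel GLIC.

Between resting and open, several channels of this family visit short-lived
intermediates in which the extracellular domain has already rearranged while
the pore is still closed.  Such a state is detectable without ever resolving
it directly: measure the pH dependence of a *conformational* readout
(fluorescence quenching of engineered bimane/tryptophan pairs, ΔF) and of a
*functional* readout (Tl⁺ flux through liposome-reconstituted channels, ΔIf)
on the same receptors.  If

pH50(ΔF) − pH50(ΔIf) ≥ 1

— the conformational change half-completes an order of magnitude (in proton
concentration) before ion flux does — the population must pass through a
rearranged-but-closed, *pre-active* state.

The package provides, as tested R code:

* a four-state gating scheme **R ⇌ P ⇌ O ⇌ D** with Hill-type proton
  dependence of the forward rates, propagated by matrix exponentials
  (`gating_scheme()`, `simulate_occupancies()`), plus a concerted
  (no-intermediate) control topology;
* simulators for every readout with realistic instrument effects:
  stopped-flow fluorescence traces with mixing dead time, multi-regime
  sampling, noise and drift (`simulate_sf_trace()`), voltage-clamp currents
  (`simulate_tevc_current()`), and a heterogeneous-liposome ANTS/Tl⁺ flux
  assay (`simulate_flux_assay()`);
* the analysis chain: pH-8 reference normalization and 1–3 component
  multi-exponential decomposition with dead-time phase accounting
  (`fit_multiexp()`, `decompose_phases()`), log-binned clustering of time
  constants into kinetic phases (`log_bin_taus()`, `identify_phases()`),
  stretched-exponential flux fits with the 2 ms quench rate
  k(2 ms) = (β/τ₀)(2 ms/τ₀)^(β−1) (`fit_stretchexp()`), Hill dose-response
  fits in proton-concentration space (`fit_hill()`) and the ΔpH50 comparison
  (`compare_curves()`);
* a structural companion: PDB parsing, Cβ–Cβ and minimal
  fluorophore–quencher distances, Trp/Tyr quenching-radius classification
  (≤ 15 Å / ≤ 10 Å) and Kabsch superposition RMSD (`read_structure()`,
  `min_group_distance()`, `superpose_rmsd()`).

## Worked example

```r
library(preactive)
rep <- run_pipeline(run_config(seed = 1))
print(rep)
```

```
Kinetic phase partition (very fast: tau < 5 ms)
        label t_low_ms t_high_ms count
         fast     5.00     12.56     6
 intermediate    31.55    199.10    12
         slow   500.00   7924.00    12

Hill fits:
  dF  136-101  pH50 = 5.96, nH = 1.44
  ...
  dI  (TEVC)   pH50 = 5.01, nH = 1.76
  dIf (flux)   pH50 = 4.80, nH = 2.09

pH50 dF = 5.960 vs dIf = 4.802: delta = 1.157 (threshold 1.00)
-> separated: consistent with a pre-active intermediate state
```

Reading the report: the fitted time constants of all sensors and pH values
cluster into three kinetic phases (fast ≈ 5–13 ms, intermediate ≈ 30–200 ms,
slow ≈ 0.5–8 s), while the dead-time ("very fast", < 2 ms) step carries the
largest share of the fluorescence change — e.g. 90.6% for the loop-2 sensor
33–160 at pH 4 — so the global conformational change is essentially complete
before the instrument can see it.  The fluorescence pH50 (5.96) sits more
than one pH unit above the flux pH50 (4.80): the intermediate flag is set.
Re-running with `run_config(topology = "concerted", ...)` removes the
pre-active state and the separation collapses to ≈ 0.

Single estimators work standalone, e.g.

```r
f <- fit_stretchexp(simulate_flux_assay(gating_scheme(), flux_config(),
                                        pH = 4.2, delay = 0.015, seed = 1))
f$k2ms          # ~ 80 /s: quench rate under strong activation
quench_rate_at(list(tau0 = 0.0125, beta = 1))   # 80, the analytic identity
```

## Package layout

* `R/` — scheme & simulators (`scheme.R`, `sensors.R`, `protocol.R`,
  `simulate.R`, `flux.R`), fitting (`multiexp.R`, `phases.R`,
  `activation.R`, `stretched.R`, `hill.R`, `binning.R`), structure
  (`structure.R`), orchestration (`pipeline.R`);
* `vignettes/gating-kinetics.Rmd` — the model, its calibration anchors,
  numerical choices and known limitations;
* `tests/testthat/` — unit, property and end-to-end acceptance tests
  (fixtures are generated in code; synthetic PDB files are built by the
  test helpers).
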