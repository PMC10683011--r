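# dpdmicelle

Mesoscale modelling of a multicompartment-micelle (MCM) nanoreactor in R.

Amphiphilic multiblock copolymers that carry an L-proline organocatalyst
self-assemble in water into micelles whose hydrophobic interior shields the
catalyst from the bulk. The quantity that controls the catalysis is the
*local dielectric environment* of the proline block. `dpdmicelle` implements
the complete mesoscale pipeline that estimates it, for computational
chemists and soft-matter modellers who want a scriptable, fully tested,
reproducible version of this workflow:

1. **Flory–Huggins coarse-graining** — χ parameters for the five bead
   species (`H` ethylene oxide, `L` styrene, `F` pentafluorostyrene,
   `Proline`, `W` water) from pairwise mixing-energy records,
   `χ_AB = V_ref ΔE^mix_AB / (RT)`, with a packaged reference χ table;
   mapped to DPD repulsions by the Groot–Warren density-3 relation
   `a_ij = 25 + 3.27 χ_ij`.
2. **Dissipative particle dynamics** — bead–spring chains
   (H₁₂-L₃-Proline₇-F₃, 5% polymer / 95% water, bead density 3) integrated
   with the modified velocity-Verlet scheme; pairwise forces
   `F_ij = F^C + F^D + F^R` with `F^C = a_ij (1 − r) r̂`,
   `F^D = −γ w²(r)(r̂·v_ij) r̂`, `F^R = σ w(r) θ_ij dt^{-1/2} r̂`,
   `σ² = 2γk_BT` (compiled cell-list kernels, counter-based pair noise,
   bit-reproducible runs).
3. **Structure analysis** — density-weighted pair correlations `ρᵢg(r)`,
   coordination numbers `Z = ∫ ρᵢg(r) 4πr² dr` up to `r = 3.45`,
   single-linkage compartment clustering.
4. **Dielectric microenvironment** — the coordination-weighted linear mix
   `ε_eff = Σᵢ Zᵢ εᵢ / Σᵢ Zᵢ` over the first coordination sphere of the
   catalyst block.

Results come back as tibbles, fitted objects have `tidy()` / `glance()`
methods, and profiles/runs have `autoplot()` methods.

## Worked example

The headline estimate — the effective dielectric constant of the proline
microenvironment from the packaged per-block coordination numbers and
dielectric constants of the assembled micelle:

```r
library(dpdmicelle)
est <- effective_dielectric(mcm_dielectric_inputs())
est
#> <dielectric_estimate> epsilon_eff = 20.3480
#> # A tibble: 4 x 5
#>   species     Z epsilon weight contribution
#>   <chr>   <dbl>   <dbl>  <dbl>        <dbl>
#> 1 L        1.65    2.55  0.336        0.857
#> 2 H        0.86   13.5   0.175        2.37
#> 3 F        1.36    1.86  0.277        0.515
#> 4 W        1.04   78.4   0.212       16.6
```

The weighted mean of the component dielectrics is **20.35**: the catalyst
sits in a markedly low-dielectric pocket (compare bulk water, 78.4),
because the lipophilic and fluorophilic blocks dominate its first
coordination sphere. Water, although only ~21% of the sphere, still
contributes most of the residual polarity.

A scaled-down end-to-end simulation (10³ box, 3000 beads, ~25 s):

```r
cfg <- list(seed = 1, system = list(box_edge = 10),
            integrator = list(n_steps = 20000L, traj_interval = 1000L),
            analysis = list(r_cut = 3.45))
rep <- run_pipeline(cfg, output_dir = "mcm-demo")
rep
#> <pipeline_report> epsilon_eff = 74.9582
#> coordination: H=16.363, L=4.625, F=4.256, W=479.726
```

At this demonstration scale the chains remain dispersed (water dominates
the coordination sphere, so `ε_eff ≈ 75`): the scaled 25-bead chain is
only weakly amphiphilic under the density-3 mapping, and the methods
vignette discusses why full burial needs the production-scale system.
The output directory holds the trajectory (extended XYZ), thermo log,
RDF/coordination tables, dielectric JSON, and a markdown/JSON report
annotated with the reference solvent constants and reaction barriers.

A shell entry point wrapping the same functions lives in
`inst/scripts/dpd-pipeline.R`
(`Rscript dpd-pipeline.R pipeline --config run.yaml --out outdir`).

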