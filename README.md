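# mprasim

Massively parallel reporter assays (MPRAs) measure the expression of
thousands of mutagenized promoter variants at once; the standard way to find
transcription-factor binding sites in such data is the **information
footprint** — the per-position mutual information between mutation status and
binned expression. Interpreting these footprints is hard: a missing peak may
mean "no binding site" or merely weak binding, titrated-away repressors,
un-induced regulators, or hitch-hiking noise from a small library.

`mprasim` builds the experiment *in silico* so these effects can be studied
with a known ground truth. Promoter variants are scored with sequence-specific
thermodynamic (states-and-weights) models: with an energy matrix giving the
additive per-base binding-energy change ε<sub>i,b</sub> (kBT), a simple
repression promoter has occupancy

```
p_bound = (P/N_NS) e^{-βΔε_pd} / (1 + (P/N_NS) e^{-βΔε_pd} + (R/N_NS) e^{-βΔε_rd})
```

where P and R are polymerase and repressor copy numbers, N_NS the number of
non-specific genomic sites, and Δε = ε_wt + Σ_i ε<sub>i,b_i</sub> the
variant's total binding energy. Expected mRNA counts follow the occupancy
hypothesis, m\* = α·p_bound, and the counts feed the footprint statistics
(mutual information, expression shift Δs_l, expression-shift matrices,
per-site average information S and signal-to-noise ratio σ).

The package covers, behind one generic state-enumeration engine:

- the six common regulatory architectures (constitutive, simple
  repression/activation, repression–activation, double repression with
  AND/OR/XOR logic, double activation), plus mutation-rate (κ) analysis;
- MWC allosteric induction of a repressor;
- binding-site copy-number titration via chemical potential (fugacity);
- genome-wide non-specific polymerase binding and engineered TATA-like
  motifs;
- extrinsic (log-normal copy-number) noise and sequencing-style resampling;
- non-equilibrium steady states of promoter kinetic graphs via the Matrix
  Tree Theorem, with detailed-balance-breaking drives.

## Worked example

Simulate a 5,000-variant simple-repression library at a 10% mutation rate
and footprint it:

```r
library(mprasim)
library(dplyr)

res <- run_mpra(mpra_config(preset = "simple_repression",
                            n = 5000, theta = 0.1, seed = 42))
res$footprint |> filter(position %in% c(-60, -35, -10, 5))
#> # A tibble: 4 × 5
#>   position        mi    shift sign           no_variation
#>      <int>     <dbl>    <dbl> <chr>          <lgl>
#> 1      -60 0.0000842  0.00270 repressor-like FALSE
#> 2      -35 0.0285    -0.0478  activator-like FALSE
#> 3      -10 0.0295    -0.0462  activator-like FALSE
#> 4        5 0.00530    0.0219  repressor-like FALSE

glance(res$footprint, sites = unlist(res$sites))
#> # A tibble: 1 × 6
#>   n_positions mean_mi max_mi n_no_variation mean_site   snr
#>         <int>   <dbl>  <dbl>          <int>     <dbl> <dbl>
#> 1         160 0.00310 0.0358              0    0.0148  85.5
```

The −35 and −10 polymerase elements carry high mutual information with a
negative expression shift (mutations lower expression), the repressor
operator just downstream of the TSS carries signal with a positive shift
(mutations relieve repression), and a background position like −60 carries
essentially none — an in-site to off-site signal-to-noise ratio of ~86.
`autoplot(res$footprint)` draws the footprint;
`autoplot(res$shift_matrix)` the base-resolved shift matrix. Parameter
sweeps (`sweep_mpra()`) replicate any of these experiments over grids of
mutation rate, library size, binding energies, copy numbers, inducer
concentration or drive energy. A thin command-line wrapper lives at
`inst/scripts/run_mpra.R`.

See the methods vignette (`vignettes/mpra-simulation.Rmd`) for the models,
parameter conventions and numerical choices.

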