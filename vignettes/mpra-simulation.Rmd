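---
title: "Simulating MPRAs from thermodynamic models: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating MPRAs from thermodynamic models: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprasim)
```

`mprasim` generates synthetic RNA-Seq-style MPRA datasets — mutant promoter
libraries with model-predicted expression — and the summary statistics used
to infer regulatory architecture from such data. This vignette records the
models, the parameter conventions the package fixes where the underlying
theory leaves choices open, and the numerical decisions a maintainer should
know about.

## The occupancy model

The core assumption is the occupancy hypothesis: the transcription rate of a
promoter variant is proportional to the equilibrium probability that RNA
polymerase occupies it. That probability comes from a states-and-weights
enumeration: every combination of bound factors is a state whose weight is
the product over bound factors of $(X/N_\mathrm{NS})\,e^{-\beta\varepsilon}$
(copy number $X$, binding energy $\varepsilon$ relative to the non-specific
genomic background of $N_\mathrm{NS}$ sites), times $e^{-\beta\omega}$ for
each interacting pair bound together. Throughout the package $\beta = 1$ and
all energies are in units of $k_BT$.

Sequence specificity enters through energy matrices: the binding energy of a
factor on a variant window is assumed additive,
$\Delta\varepsilon = \varepsilon_\mathrm{wt} + \sum_i \varepsilon_{i,b_i}$,
with $\varepsilon_{i,b_i}$ read from an $l \times 4$ matrix that is zero at
the wild-type base (wild-type-normalized form). The additive model ignores
epistasis within binding sites; that is a deliberate scope limit, matching
how such matrices are measured and used in practice.

Expected counts are $m^* = \alpha\, p_\mathrm{bound}$ with
$\alpha = r/\gamma = 100$ by default (transcription rate over mRNA
degradation rate). All downstream statistics are invariant to $\alpha$; the
default merely puts counts on the scale of real sequencing data.

The generic engine (`pbound()`) enumerates occupancy states for arbitrary
site sets; states in which polymerase co-occurs with a "repressing" set of
bound repressors are excluded. The repression logic is configurable:

* **independent / OR** — any bound repressor represses;
* **AND** — only the complete repressor set represses (single-repressor +
  polymerase states are allowed; the repressors bind weakly,
  $-12\,k_BT$ each by default, but cooperatively, $\omega_{RR} = -5\,k_BT$);
* **XOR** — exactly one bound repressor represses; the doubly bound state
  does not.

Every state with polymerase bound is transcriptionally active, with one
shared rate — the active-state rule is uniform across architectures. The
engine is checked against independently hand-written closed-form
$p_\mathrm{bound}$ expressions for all six architecture classes to
$10^{-12}$ relative in the test suite.

## The synthetic-data generator and its defaults

The generator's defaults define the package's reference conditions, chosen
once:

| Parameter | Default | Meaning |
|---|---|---|
| promoter length | 160 bp | display coordinates −115..+44 (TSS at 0) |
| library size n | 5000 | variants per dataset |
| mutation rate θ | 0.1 | per-base, independent Bernoulli |
| P, R, A | 1000, 10, 100 | copy numbers (minimal-media scale) |
| $\varepsilon_{pd}, \varepsilon_{rd}, \varepsilon_{ad}$ | −5, −15, −13 | wild-type binding energies ($k_BT$) |
| $N_\mathrm{NS}$ | $4\times 10^6$ | E. coli genome size |
| α | 100 | count scale |
| ω (act–pol, rep–rep) | −5 | interaction energies ($k_BT$) |

The default wild type is a fixed 160-bp sequence with canonical sigma-70
elements planted on a seeded random background: TTGACA at −36..−31, TATAAT
at −12..−7, and the 20-bp O1 operator sequence at +1..+20. The polymerase
"site" is a 30-bp matrix whose two hexamers carry the mutant penalty and
whose 18-bp spacer is energetically neutral; the repressor site is 20 bp at
+1..+20, activator sites 20 bp at −66..−47 (and −92..−73 for a second
activator). Synthetic matrices use the 0-at-wild-type / 1-$k_BT$-at-mutant
convention. Site placements, $\varepsilon_{ad}$ and the interaction energies
are package conventions (the corresponding measured quantities exist only as
figure heatmaps elsewhere); externally measured matrices can be supplied as
TSV files via `read_energy_matrix()`.

Mutagenesis is an independent per-base Bernoulli(θ) process — matching the
"mutation rate" language of MPRA library design, not a fixed per-variant
mutation count — with the target base drawn from a 4×4 row-stochastic
mutation spectrum (uniform by default; transition-only and G→A/C→T-only
spectra are built in, with immutable bases silently skipped). The wild type
is not automatically part of the library; `include_wild_type = TRUE` adds
it. Every stochastic operation takes an explicit seed, and the pipeline
derives all stage seeds from one master seed by counter, so a configuration
plus seed reproduces outputs byte-for-byte.

What the generator does *not* emulate: intrinsic (bursting) transcription
noise, PCR amplification at the fragment level (only multinomial/Poisson
resampling of final counts), epistatic energy terms, indels,
reverse-strand sites, sigma-factor competition, and regulatory interactions
across genes. Passing tests therefore demonstrate correct behaviour of the
modeled physics, not fidelity to every noise source of a wet-lab MPRA.

## Footprint statistics

Mutual information at each position is computed with plug-in empirical
frequencies between a base variable and a binned expression variable. Two
conventions matter:

* the base variable is coarse-grained to wild-type vs mutated by default
  (4-base identity is available), which raises the footprint's
  signal-to-noise ratio by removing spurious states;
* expression is split into **two** bins at the mean count; counts exactly
  equal to the mean go to the high bin (a fixed tie rule the theory does not
  dictate). More bins (equal-count quantiles) are supported but add
  artificial off-site noise.

$0\log 0$ terms contribute zero. A position never mutated in the library has
undefined association and is reported as 0 bits with a `no_variation` flag
rather than an error. Under the 2×2 coarse-graining the estimate is bounded
by 1 bit, and permuting counts across variants drives it to the plug-in bias
floor (below 0.005 bits at n = 5000), both enforced by tests.

The expression shift $\Delta s_l = \frac1n\sum_i \xi_{i,l}(c_i - \langle
c\rangle)$ signs each peak: positive = repressor-like, negative =
polymerase/activator-like. The base-resolved shift matrix uses relative
deviations $c_i/\langle c\rangle - 1$ and is exactly zero at wild-type
entries. Site-level signal is the mean information $S$ over a site's
informative positions, and footprint quality is the ratio $\sigma$ of
in-site to off-site mean information; a zero off-site mean (the noiseless
analytic limit, realized exactly by the minimal-promoter fixture) reports
$\sigma = \infty$ with a flag.

### The minimal-promoter fixture

`minimal_promoter_library()` builds the analytic hitch-hiking example: a
2-bp constitutive promoter over a binary alphabet whose second position is
the specific site. The complete 4-sequence library yields exactly 0 bits at
the non-binding position and 1 bit at the site; the reduced 2-sequence
library yields 1 bit at both — chance co-occurrence of mutations
masquerading as signal. These exact values anchor the acceptance checks.

## Mutation-rate (κ) analysis

The ratio of repressor to polymerase Boltzmann weights after mutations,
$\kappa = (R/P)e^{-\beta(\Delta\varepsilon_{rd} - \Delta\varepsilon_{pd} +
m_r\Delta\Delta\varepsilon_{rd} - m_p\Delta\Delta\varepsilon_{pd})}$,
predicts which site's signal survives: κ ≫ 1 starves the polymerase signal,
κ ≪ 1 the repressor signal, and κ(θ) = 1 defines the optimal mutation rate
in closed form. One discrepancy is documented rather than hidden: with the
commonly quoted copy numbers (R = 10, P = 1000), wild-type energies (−15,
−5 $k_BT$) and the 37.6-$k_BT$ site-length energy combination, the closed
form gives θ\* ≈ 0.14, not the ≈ 0.10 sometimes quoted alongside these
inputs; the package exposes the closed form (verified against a bisection
root of κ(θ) − 1) and leaves the choice of operating θ to the user, with
0.1 as the conventional default. `repressor_energy_for_kappa()` inverts κ
for the binding energy at a detectability threshold (κ = 0.1 gives
≈ −11 $k_BT$ at the default parameters).

## Titration via chemical potential

With $n$ identical copies of a binding site (a plasmid system), enumerating
joint states is exponential; instead the factor is treated
grand-canonically. `solve_fugacity()` finds λ such that specific-site
occupancies $\frac{\lambda e^{-\beta\varepsilon_j}}{1 + \lambda
e^{-\beta\varepsilon_j}}$ plus a reservoir of $N_\mathrm{NS}$ zero-energy
non-specific sites average to the copy number; the partition function then
factorizes over sites. The root is bracketed and solved on the log-fugacity
scale to $10^{-10}$ relative tolerance; `copies = 0` short-circuits to
λ = 0, and an average exceeding the total site capacity is an explicit
infeasibility error.

Two ensemble caveats are deliberate and tested rather than papered over.
First, grand-canonical and canonical (fixed-copy) treatments agree only
where ensemble equivalence holds: the enumeration oracle is checked in the
dilute large-reservoir regime, and saturation corrections of order the
occupancy itself appear outside it. Second, at the strong-binding defaults
($\varepsilon_{rd} = -15$, R = 10) the single-copy grand-canonical
$p_\mathrm{bound}$ sits a few percent above the canonical two-state value,
because the one bound repressor is removed from the reservoir of ten; the
two routes converge (within 1%) for weak binding or large copy numbers.
Reporter occupancy uses the grand-canonical weight $\lambda
e^{-\beta\varepsilon_r}$ in place of the canonical Boltzmann weight, so
$p_\mathrm{bound} \to$ the constitutive value as site copies titrate the
repressor away.

## Induction, non-specific binding, extrinsic noise

**MWC induction.** An inducible repressor is a two-state (active/inactive)
allosteric molecule with two inducer sites:
$p_\mathrm{active}(c) = (1+c/K_A)^2 / [(1+c/K_A)^2 +
e^{-\beta\Delta\varepsilon_{AI}}(1+c/K_I)^2]$, defaults
$K_A = 139\,\mu M$, $K_I = 0.53\,\mu M$,
$\Delta\varepsilon_{AI} = 4.5\,k_BT$ (the LacI/IPTG parameterization). The
pool splits into $p_\mathrm{active} R$ active and the rest inactive
molecules; both conformations read the same operator matrix but from
different wild-type energies (inactive = weak, $-2\,k_BT$ by default, a
package convention).

**Non-specific binding.** `pbound_nonspecific()` adds one mutually
exclusive polymerase-bound state per start index along the promoter, scored
by sliding the polymerase matrix; the repressor excludes polymerase
exactly as in the single-site model, which makes the degenerate limit (all
non-canonical windows at enormous energy) collapse to the single-site
formula identically. All windows count as transcriptionally active by
default; a declared start-site set can restrict activity.

The TATA-like-motif demonstration needs two ingredients the
wild-type-anchored synthetic matrices cannot provide (a wild type *at* the
matrix optimum can never be out-competed by an insertion): a
consensus-anchored polymerase matrix (`sigma70_consensus_matrix()`, weak
−35 element at 0.35 $k_BT$/base, strong −10 element at 2 $k_BT$/base —
mirroring the relative element strengths of measured matrices) and a wild
type whose −10 element lies two mismatches off consensus. Under those
conventions, substituting TAGAAT (one mismatch from the TATAAT consensus)
at −80 creates a spurious window that rivals the canonical site and an
off-canonical information-footprint peak emerges at the motif.

**Extrinsic noise.** Cell-to-cell copy-number variability is modeled as one
independent log-normal draw per library variant per factor (each variant's
measurement standing for one cell/aggregate), parameterized by mean and
coefficient of variation with $\sigma^2 = \ln(1+v^2)$ and location
$\ln m - \sigma^2/2$, so the arithmetic mean is exact. Defaults: mean 5000
polymerases, 100 repressors. Counts may additionally be resampled to a
sequencing depth (multinomial or Poisson); fragment-level PCR bias is out
of scope.

## Non-equilibrium steady states

Promoter kinetics are a strongly connected directed graph of occupancy
states. Steady-state probabilities follow the Matrix Tree Theorem — each
state's weight is the sum over spanning trees rooted there of the product
of edge rates — enumerated exactly for up to six states (the reference
graphs have four) with a Laplacian null-space solve as the large-graph
fallback; the two routes agree to $10^{-12}$ on random graphs in the tests.

Sequence enters through off-rates: on-rates are diffusion-limited and
shared, $K_d = c_0 e^{\beta\Delta\varepsilon}$ with $c_0 = 1\,M$, and
$k_\mathrm{off} = k_\mathrm{on} K_d$, scaled by $e^{\beta U}$ on a driven
edge. Copy numbers map to concentrations as $X/N_\mathrm{NS}$ (in units of
$c_0$), which makes the undriven ($U = 0$) steady state reproduce the
thermodynamic engine's occupancies exactly (per-variant counts agree to
$10^{-6}$ relative in the tests, and to machine precision in practice).

Two active-state conventions coexist and are both exposed. The printed
convention for the simple-activation square graph counts {A, AP} as active;
the package default follows it. The activator-to-repressor role reversal
under drive, however, is a statement about RNAP occupancy — investing
$U > 0$ on the AP→A edge ejects polymerase whenever the activator is bound,
so with the activator's site saturated, expression (RNAP-bound states
{P, AP}) *falls* with activator binding and the activator site's expression
shift flips sign to repressor-like. The demonstrations and tests of the
flip therefore use `active = c("P", "AP")`; both sets are one argument away.
Absolute on-rates and concentrations behind the driven regime are free
parameters; the packaged demonstration uses $U = 10\,k_BT$ at the default
activator copy number (site occupancy already near-saturated, $w_A
\approx 11$).

## Numerical choices and problem sizes

* State weights are accumulated in log space and normalized by the largest
  exponent (`logsumexp`), so deeply repressed or strongly driven regimes do
  not overflow.
* Ties at the mean-count threshold go to the high bin; design ties in
  `design_overlap_promoter()` go to the alphabetically first base. Both
  rules are arbitrary but fixed.
* The fugacity root uses bracketed bisection on the log scale
  (tolerance $10^{-10}$ relative); spanning-tree enumeration switches to the
  linear solve above six states.
* Reference simulations in the tests and documentation use libraries of
  1000–5000 variants on the 160-bp promoter, with medians over five seeds
  for library-size comparisons and single fixed-seed datasets elsewhere;
  these sizes put the hitch-hiking noise floor well below the site signals
  while keeping any single dataset inexpensive.

## Known limitations

Additive (non-epistatic) energies; at most two regulated factors per
promoter in the equilibrium engine; single-strand matrices (no
reverse-complement sites); extrinsic noise only; steady states only (no
transient kinetics or Gillespie trajectories); and no automatic
binding-site calling — footprints are meant to be read, as in practice, by
locating contiguous runs of high-information positions with a consistent
shift sign.
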