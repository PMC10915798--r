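---
title: "Methods: buffer-ion adsorption, screening and bridging statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: buffer-ion adsorption, screening and bridging statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionbridge)
```

## The problem

Therapeutic protein formulations are buffered with small molecular ions —
phosphate, citrate, histidine — that exist as mixtures of charge states and
adsorb on the protein surface. Where and how strongly they adsorb, how long
they stay, and whether a single ion can tether two protein surfaces at once
("ionic bridging") all bear on protein–protein association and ultimately on
aggregation. `ionbridge` implements the statistics needed to quantify these
effects from simulation trajectories, plus synthetic generators with known
ground truth so that every estimator can be validated without running
molecular dynamics.

## Models and estimators

### Charge-state speciation

A buffer species is modelled in its two dominant charge states. The
deprotonated fraction follows the Henderson–Hasselbalch relation

$$f = \frac{1}{1 + 10^{\,\mathrm{p}K_a - \mathrm{pH}}},$$

so the protonated:deprotonated ratio is $10^{\mathrm{p}K_a-\mathrm{pH}}$.
Molecule totals come from $N = c\,N_A L^3$ (concentration $c$, cubic box edge
$L$) and are split over states by largest-remainder apportionment, with
remainder ties resolved toward the state of smaller $|q|$. Minor charge
states are deliberately ignored: near the formulation pH the third state's
population is at the percent level and would add bookkeeping without
signal. The citrate pKa is a *user input*: the commonly tabulated
pKa$_3$ = 6.40 gives a 2.5:1 state ratio at pH 6, while a 4:3 ratio
corresponds to pKa$_3 \approx 6.125$; because the appropriate effective pKa
depends on ionic strength, the package refuses to hard-code one.

### Surface radial distributions

`surface_rdf()` bins, per frame, the minimum-image distance from each target
atom to the *nearest* atom of the reference (protein) group, and divides the
counts by `n_frames * bin_width`. This is an unnormalised, surface-referenced
rdf in counts/nm: its bin-sum up to $r$ (`cumulative_count()`) equals the
mean number of target atoms within surface distance $r$, which is exactly
the $n_i(r)$ needed by the charge-compensation profile. Defaults: 0.005 nm
bins to 2.5 nm, with the first 5 % of frames dropped as equilibration
(mirroring the discard-the-early-ns convention of production analyses).

### Contact counts and the Buffer Adsorption Index

A contact is *any* protein–buffer atomic pair within 0.4 nm (minimum image),
hydrogens included; the per-residue count is the number of such pairs, not
the number of distinct buffer molecules. Counts are time-averaged within
each trajectory, then averaged with equal weight across independent
trajectories ($N^i_\mathrm{avg}$). The Buffer Adsorption Index is

$$\mathrm{BAI}_i = -k_BT \,\ln\!\frac{N^i_\mathrm{avg}}{N_\mathrm{max}},$$

reported in $k_BT$ units, where $N_\mathrm{max}$ is the largest
$N^i_\mathrm{avg}$ over *all charge states* of the species, so all states of
one buffer share a single free-energy origin. BAI is invariant under a
common rescaling of all counts. Residues with zero contacts have undefined
BAI; they are flagged, reported as `Inf` and excluded from species averages
and distributions. Species averages (`species_average_bai()`) are further
gated on nonzero time-averaged solvent-accessible surface area, so buried
residues cannot dilute a surface species' mean.

### SASA

Shrake–Rupley quadrature with a deterministic golden-spiral point set
(default 960 points) and a 0.14 nm water-size probe; per-atom accessible
fractions times $4\pi(r+r_p)^2$, summed per residue. The isolated-atom error
at 960 points is well below 1 %. Hydrogens, when present, are included for
consistency with the all-atom contact criterion. No analytic-arc SASA is
attempted; quadrature accuracy is the stated contract.

### Effective charge and screening length

$$Z_\mathrm{eff}(r) = Z_\mathrm{protein} + \sum_i n_i(r)\, q_i,$$

with $n_i(r)$ the surface-distance cumulative counts above (not
centre-of-mass radial counts — consistent with how the rdfs are built).
$Z_\mathrm{eff}(0) = Z_\mathrm{protein}$ by construction, and with all ions
counted the profile saturates at the total system charge (zero for a
neutralised box). The tail is fitted to $a\,e^{-r/\xi}$ by nonlinear least
squares (port algorithm; deterministic start $a_0 = Z_\mathrm{eff}(r_{lo})$,
$\xi_0 = 1$ nm). The default window 0.5–3.0 nm starts beyond the ~0.5 nm
adsorbed-ion layer so the fit sees the diffuse-layer decay; the window is
configurable because the exact choice is a judgement call on real profiles.
Sign changes inside the window are an error (a single exponential cannot
represent charge reversal); overscreening is instead *detected* by
`detect_overscreening()` as a dip of $Z_\mathrm{eff}$ below $-0.1\,e$ under
a nonnegative protein charge.

### Survival kinetics

Contact channels (ion–protein or ion–residue) carry boolean occupancy per
frame. The survival probability pools all (channel, origin) pairs:

$$S(t) = \frac{\#\{\text{origins occupied and continuously occupied to } t\}}
             {\#\{\text{origins occupied}\}},$$

with every frame that leaves room for the full lag window serving as an
origin. Pooled normalisation was chosen over per-origin averaging for
variance; strict continuity (`gap_tolerance = 0`) is the default, with the
tolerance exposed because intermittency conventions differ between studies.
For a memoryless off-process this estimator is unbiased and
$S(t) = e^{-k_\mathrm{off} t}$ exactly under the generator's
discretisation. Note that pooled origins inside one bound interval are
perfectly correlated: error bars must be based on independent units
(channels or fresh intervals), which is what `interval_survival()` provides
for bridges — records whose observation window covers the lag form the
at-risk set, so right-censoring at the trajectory end does not bias it.

### Bridges and dimer profiles

An ion bridges two proteins in a frame when its minimum atomic distance to
*both* surfaces is below 0.4 nm; bridge identity is per buffer molecule.
Maximal bridging intervals become records with anchor residues (the residue
on each protein holding the atom nearest the ion; ties go to the lower
residue index). Dimer stability uses the per-frame minimum interprotein
atomic-pair distance $d_\mathrm{min}$: per-run histograms are averaged with
equal run weight, renormalised and Boltzmann-inverted,
$F(d) = -k_BT\ln p(d)$, min-shifted to zero. No Jacobian/volume correction
is applied to $p(d_\mathrm{min})$ — the raw distribution is inverted, a
deliberate faithful-reproduction choice. Default bins: 0.025 nm over
0–3 nm.

## The synthetic world

The generators state a world once; their defaults are not tuned to tests.

* **Equilibrium mode.** Point ions around a fixed 24-bead golden-spiral
  shell protein (one bead = one residue, classes ARG +1e / ASP −1e / LEU 0e,
  class counts honouring a target net charge). Energy in $k_BT$: a square
  well of the bead class's depth within 0.4 nm of each bead, plus a
  screened-Coulomb pair term with Bjerrum length 0.7 nm and decay length
  0.8 nm (the magnitude of a ~150 mM 1:1 electrolyte, so charge profiles
  show realistic curvature). Sampling is single-ion-move Metropolis on one
  long chain (default burn-in 200 sweeps, thinning 5 sweeps, step 1 nm);
  thinned frames are treated as independent, which holds to good
  approximation at this step size because the target is nearly uniform.
  The bead shell radius (1.4 nm) keeps adsorption wells disjoint, so the
  contact-count ratio between two classes is exactly the Boltzmann factor
  of their depth difference — that is the designed ground truth the BAI
  recovery test checks ($\Delta\mathrm{BAI} = 1.0 \pm 0.3\ k_BT$ at 2,000
  frames; the fixture uses a 6 nm box and 30 neutral ions so the shallow
  class accrues ~25 counts per bead, putting the estimator's SE near
  0.1 $k_BT$). For dilute, uncharged fixtures the acceptance rate
  necessarily approaches 1 and the sampler's (0.1, 0.9) tuning warning
  fires; that is a property of the stated world, not a fault to tune away.
* **Telegraph mode.** Independent two-state Markov channels with per-step
  persistence $e^{-k\,\mathrm{d}t}$ and stationary initial states; requires
  $\mathrm{d}t\,k \le 0.1$. Survival of the bound state is exactly
  exponential by construction.
* **Two-protein mode.** Two four-bead "arrow" proteins face tip-to-tip so
  the designed tip separation *is* the minimum atomic-pair distance. Ions
  hop between a midpoint bridging site (geometrically within 0.4 nm of both
  tips for separations < 0.8 nm, jitter ±0.03 nm) and a distant bulk site
  with telegraph rates. Alternatively a `double_well` landscape draws the
  separation from a piecewise-flat two-well density with designed
  $\Delta F$, giving the free-energy recovery tests an exact target.

What a green test does **not** establish: the generators have no water, no
force field, no ion–ion structure beyond screened Coulomb, no protein
flexibility, and equilibrium frames carry no dynamics. They validate the
*estimators* — binning, counting, normalisation, survival and inversion
arithmetic — not the physics of any particular protein/buffer system.

## Numerical choices

* Units: nm, ps, $k_BT$ (default temperature 300 K), elementary charges.
  PDB files (Å) are converted at the reader/writer boundary; atom ids are
  1-based throughout, R's native convention.
* Only cubic periodic boxes; minimum-image distances are exact (no cell
  lists), so results are independent of any acceleration structure.
* Histogram bins are left-closed; cumulative counts sum whole bins (no
  partial-bin interpolation), matching the histogram construction.
* `nls` port algorithm for the screening fit: the default Gauss–Newton
  criterion cannot certify 1e-6 recovery on noiseless (zero-residual) data.
* Tie-breaks are deterministic and documented: lowest atom id pair for
  minimum distances, lower residue index for anchors, smaller |charge| for
  apportionment remainders.
* Degenerate inputs error loudly: empty groups, all-zero $N_\mathrm{avg}$,
  sign-changing or constant fit windows, empty histogram bins at the
  reference distance.

## Known limitations

* The Metropolis sampler is pure R; it is sized for fixture-scale systems
  (tens of beads/ions, thousands of frames in seconds), not for all-atom
  trajectories.
* Binary trajectory formats are out of scope; the plain-text dialect is the
  interchange format, and adapters are expected to wrap it.
* No activity corrections to pKa, no Poisson–Boltzmann reference, no
  second-virial machinery — these are comparison context, not computed
  statistics.
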