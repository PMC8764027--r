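---
title: "Methods: antibiotic ramping on an obligate cross-feeding mutualism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antibiotic ramping on an obligate cross-feeding mutualism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muevolab)
```

## The experimental design the package implements

`muevolab` implements the computational side of a serial-transfer evolution
experiment that asks whether bacteria locked into an obligate mutualism can
adapt to environmental stress as well as autonomous bacteria can. The study
system is a pair of *Escherichia coli* amino-acid auxotrophs — a tryptophan
auxotroph (TRP) and a tyrosine auxotroph (TYR) — that feed each other the
amino acid the partner cannot make. Three cultures are propagated: the
unsupplemented coculture (CO), in which growth is only possible through
cross-feeding, and the two monocultures, each supplemented with 100 µM of
both amino acids so that growth is autonomous.

Every 72 h, 40 µl of each culture is transferred into 960 µl of fresh
medium (a 1/25 dilution), and the optical density (OD600) is recorded at
each transfer. A culture whose OD600 falls strictly below 0.01 is scored
dead and discontinued. The antibiotic concentration follows a *ramp*:
transfers 0–1 are antibiotic-free, transfers 2–5 double the concentration
from one-eighth of the sub-MIC up to the sub-MIC, and from transfer 6 the
increment is linear until the final transfer ends slightly above the
working concentration. Sixteen founder lineages per treatment are split
into five technical replicates, giving 80 replicates per culture type ×
antibiotic cell, over four antibiotics: ampicillin and kanamycin
(bactericidal), chloramphenicol and tetracycline (bacteriostatic).

### Sub-MIC determination

The ramp is anchored at the *sub-MIC*: the concentration at which growth is
still sustainable but antibiotic pressure is maximal, operationalised as an
OD600 threshold zone of 0.05 ± 0.005 (inclusive endpoints). Scanning an
increasing dose–response grid, `determine_sub_mic()` applies, in order:

1. one concentration with **all** replicate ODs inside the zone → that
   concentration;
2. several concentrations fully inside → their arithmetic mean;
3. a concentration with **some** ODs inside followed by one with none → the
   mean of the two (a contiguous run of partial overlaps is averaged);
4. partial overlap at the **last** measured concentration → that
   concentration.

If no OD intersects the zone the plate is unresolvable and an error reports
the nearest OD, rather than guessing.

### Ramp generation

`build_ramp(s, w)` needs one quantification decision: "slightly above the
working concentration" is taken as `end_conc = 1.1 * w` (the `end_factor`
argument), the smallest round margin consistent with the phrase. The
doubling phase is fixed at four steps (`s/8, s/4, s/2, s` at transfers
2–5), which places the first transfer *above* sub-MIC at transfer 6; the
linear phase then uses the constant increment `(1.1 w − s)/(n − 5)`. The
schedule is monotone, hits `s` exactly once, and scales linearly in
`(s, w)`.

## The synthetic-data generator

No kinetic constants for the evolved strains are published, so the
simulator's defaults are calibration choices, made once, documented here and
frozen in `inst/extdata/sim-params-default.yaml`. The generator exists so
that the entire analysis pipeline can be exercised end to end at desk scale,
with data whose qualitative structure matches the experiment.

### Model

Within a 72-h batch, each genotype class — strain (TRP/TYR) × discrete
resistance level ℓ (MIC = m₀λ^ℓ, λ = 2, ℓ ≤ 8) × prototrophy flag — grows
at

r · g_aa · g_ab · (1 − N_tot/C)

with Monod amino-acid limitation `g_aa = [AA]/(K_aa + [AA])` for
auxotrophs (prototrophs are unconstrained but pay a synthesis cost, below)
and pharmacodynamic suppression `g_ab = 1/(1 + (conc/MIC)^κ)`. Bactericidal
antibiotics additionally kill at `δ_max (conc/MIC)^κ/(1 + (conc/MIC)^κ)`.
Dividing cells release the partner's amino acid (ρ per 10⁹ new cells/ml)
and consume their own requirement (q per 10⁹ new cells/ml); a small basal
leakage (ρ_leak per 10⁹ cells/ml per hour) is released from standing
biomass. Mutations are sampled per 0.1-h step as Poisson counts of mutant
divisions (τ-leap style): resistance steps with probability 2×10⁻⁶ per
division and reversion to prototrophy with a per-strain probability
(tyrosine auxotroph 2×10⁻⁶, tryptophan auxotroph 0, emulating that only
TYR regained autonomy in the study system — the deleted *trpB* leaves no
comparable route). The OD readout is α·N/10⁹ with multiplicative lognormal
noise (σ = 0.05); a deterministic mode (expected mutation counts, no noise)
supports exact checks.

### Two structural choices worth flagging

**Prototrophy carries a growth cost (`cost_rev = 0.5`).** The model's
coculture is amino-acid-limited; a cost-free revertant would enjoy a large
growth advantage at all times and reversion would sweep even without
antibiotics — the mutualism could never persist, contradicting the system
being modelled. With the cost, reversion is disfavoured while the partner
supplies amino acids generously and favoured exactly when that supply
deteriorates.

**Basal leakage scales with `g_ab`.** Antibiotic-suppressed cells
synthesise less of everything, including the leaked amino acids. This makes
amino-acid scarcity — and with it selection for metabolic autonomy —
specific to stressed cocultures: unstressed cocultures remain comfortably
cross-fed (revertant frequency stays near mutation–selection balance,
~10⁻³, below the 1% colony-screen detection floor), while under a
bacteriostatic ramp the amino-acid economy collapses and revertants sweep.

The division-coupled release alone cannot start an unsupplemented coculture
from washed cells (no growth → no release → no growth); the basal leakage
term plus a small carried-over pool (2 µM) bootstrap it, which mirrors real
inocula carrying conditioned medium.

### Calibration

The frozen file was calibrated once against four qualitative behaviours of
the experimental system, then not revisited:

* unsupplemented cocultures grow visibly slower than supplemented
  monocultures, with the maximum-slope interval shifted from ~12–15 h to
  ~24 h or later (the 72-h yield difference is marginal, since any
  serially-transferable culture ends near carrying capacity; the rate
  difference carries the signal);
* a bactericidal (kanamycin) ramp extinguishes every coculture around the
  transfer where the concentration jumps above sub-MIC, while monocultures
  escape by stepwise resistance evolution;
* a bacteriostatic (chloramphenicol) ramp leaves a subset of cocultures
  surviving, and the tyrosine-auxotroph side of the survivors is dominated
  by prototrophic revertants, while surviving monocultures stay
  auxotrophic;
* antibiotic-free cocultures keep revertants below the screen's detection
  floor indefinitely.

Key values: r = 0.45 h⁻¹ both strains, K_aa = 2 µM, ρ = 16, q = 5,
ρ_leak = 0.5, C = 10⁹ cells/ml (α = 1, so carrying capacity ≈ OD 1.0),
κ = 2, δ_max = 0.5 h⁻¹, ancestral MIC per antibiotic = 2 × its sub-MIC.

### What the generator does *not* emulate

Spatial structure and cell–cell contact (the mechanism thought to underlie
the real consortium's exchange), genome-scale metabolism, horizontal gene
transfer, density-dependent mutation rates, and any fitness structure among
resistance levels beyond the MIC multiplier. Passing the direction-of-effect
checks therefore shows the *pipeline* behaves correctly on data with the
right causal structure; it is not evidence about the biological system
itself.

## Analysis modules

**Growth metrics.** `max_growth_rate()` follows the bench procedure
literally: the interval of maximal increase is found on the *mean* curve
(raw CFU increase between consecutive sampled time points), then each
replicate's rate is computed over that shared interval. Because the
procedure is stated in terms of CFU increase but rates are conventionally
specific, both the raw slope (CFU ml⁻¹ h⁻¹) and the log-slope (h⁻¹) are
reported.

**MIC calling.** First concentration with OD600 < 0.01; right-censored at
the top of the grid when growth never fails. ΔMIC subtracts the ancestral
group *median* from each derived replicate (replicates are unpaired across
the evolution experiment); censored values are excluded with a warning,
never imputed.

**Group comparison.** Two-sided Mann–Whitney U (exact enumeration when both
samples have ≤ 8 untied observations, continuity-corrected normal
approximation otherwise), Benjamini–Hochberg step-up correction, and a
compact letter display built by insert-and-absorb so that two groups share
a letter exactly when their adjusted p ≥ α (default 0.05).

**Survival.** Extinction events at the first transfer with OD < 0.01
(an OD exactly at threshold is alive — "fell below" is strict); lineages
alive at the final transfer are right-censored. Kaplan–Meier curves and
two-group log-rank tests use the `survival` package, with transfer index as
the (discrete) time scale and the standard tied-event hypergeometric
variance; the test suite cross-checks both against hand product-limit
arithmetic and a brute-force accumulation oracle.

**Trajectory clustering.** Lineage × transfer OD profiles, with
post-extinction transfers imputed at OD 0 (a dead culture has no density;
this keeps extinct lineages in the tree, as the experimental trees include
all replicates). Profiles are clustered on the raw OD scale — absolute
density differences are the signal — by diagonal-covariance Gaussian
mixtures with BIC model selection (via `mclust`, model `"VVI"`); the
conjugate prior serves as a variance floor, without which the zero-variance
columns of all-dead lineages make every K > 1 model singular. The
clustering tree is Ward linkage on Euclidean distances, serialised as
Newick.

**Cluster-composition test.** The experiment's question is whether
cocultures occupy clusters of their own. The statistic is our construction:
over clusters of size ≥ 5 (a floor that prevents singleton-purity
artefacts), T = max of (focal count × focal fraction). The null permutes
group labels uniformly over lineages; since T depends only on which
lineages carry the focal label, per-cluster focal counts follow a
multivariate hypergeometric law that is sampled directly (largest cluster
first, so the seeded result is invariant to cluster relabelling), making
10⁶ permutations take seconds. The add-one estimator
p = (1 + #{T* ≥ T})/(1 + N) never returns 0 and has floor 1/(N+1) —
with N = 10⁶ a perfectly separated coculture cluster yields
p ≈ 9.99999×10⁻⁷ < 10⁻⁶.

**Reversion.** Colony patterns on MMAB / MMAB+Trp / MMAB+Tyr / LB map to
prototrophic revertant (grows on all four), TRP or TYR auxotroph (grows
only on its supplemented plate and LB), or ambiguous (anything else;
excluded from denominators but counted). Zero revertants are reported as
"below the lower detection limit (2.5×10⁴ CFU/ml)", never as frequency 0.
Group ratios are compared by plain two-sided Pearson χ² (df = 1, no
continuity correction). The five-plate coculture-separation variant adds a
MMAB+Trp+Tyr plate that does not change any call, so the same classifier
handles it.

## Numerical and testing choices

* Fixed-step integration at dt = 0.1 h; halving the step changes
  deterministic 72-h densities by < 0.5%.
* One master seed; every stochastic operation derives a child seed from
  (seed, operation, replicate) via a 31-bit string hash, so results are
  independent of execution order.
* Desk-scale problem sizes, chosen once: direction-of-effect checks run 12
  replicates per treatment cell over 20 seeds (pass bar ≥ 90% of seeds);
  planted-partition recovery uses two 80-row Gaussian blobs in 8
  dimensions at 5σ centre separation over 50 seeds; permutation-test
  type-I-error calibration uses 1000 null simulations at N = 999
  permutations.

## Known limitations

The ΔMIC module assumes a shared dose grid between ancestral and derived
assays. The composition statistic is one reasonable choice among several
(e.g. a χ²-type statistic over the full cluster × group table would also
work); its size floor of 5 is a tuning constant. The simulator's
amino-acid economy is well-mixed and linear in biomass, so it cannot
reproduce spatial privatisation of metabolites; and resistance is a ladder
of MIC doublings with no epistasis or cost, so long-term resistance
dynamics beyond the ramp horizon are not meaningful.
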