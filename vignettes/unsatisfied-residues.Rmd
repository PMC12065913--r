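---
title: "Predicting co-translational chaperone binding from unsatisfied residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting co-translational chaperone binding from unsatisfied residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpfold)
library(dplyr)
```

## The model

During translation, a nascent protein emerges vectorially from the
ribosomal exit tunnel and can begin to fold long before its C terminus is
synthesized. A tunnel-emerged residue whose native contact partners are
still untranslated, or still buried in the tunnel, is *unsatisfied*: it
sits exposed on a partial fold and cannot complete its native environment.
serpfold implements the hypothesis that the main *E. coli*
co-translational chaperones read exactly this signal — Trigger Factor (TF)
engaging unsatisfied residues whose missing partners lie *within* the same
domain, and DnaK engaging those whose partners lie in *another* domain —
and provides the ribosome-profiling statistics needed to test such
predictions against selective ribosome profiling (SeRP) data.

The pipeline has four stages.

**1. Native contacts from a predicted structure.** Two residues are in
contact when any pair of their atoms lies within `max_atom_dist` (6 Å).
Atoms of residues with predicted confidence (pLDDT) below 70 are ignored,
residue pairs with predicted aligned error above 5 Å are ignored, and
pairs closer than 6 positions on the chain are ignored, which removes most
contacts internal to a single α-helix. The contact weight ("interaction
strength") is the number of atoms involved in the contacting pair — by
default the count of distinct atoms across both residues that participate
in at least one qualifying atom pair. Whether "atoms involved" should
count atoms or atom pairs is genuinely ambiguous; we default to distinct
atoms (the closest literal reading) and expose
`contact_params(strength_mode = "pairs")` as the alternative. The PAE
matrix is asymmetric; we conservatively exclude a pair when the *larger*
of its two entries exceeds the threshold (`pae_rule = "max"`).

**2. Vectorial emergence.** For each nascent length $L = 1 \dots N$ the 30
C-terminal residues (`tunnel_len`) are masked as tunnel-occluded. Every
contact $(i, j)$, $i < j$, falls into exactly one category:

* **I** — $i$ not yet emerged: ignored;
* **II** — $i$ emerged, $j$ tunnel-masked or untranslated: residue $i$ is
  unsatisfied and the contact contributes to binding;
* **III** — both emerged: part of compacted, native-like structure.

The mask applies at every $L$ including $L = N$: profiles are per-codon
snapshots during translation, so C-terminal contacts never leave category
II. Category II contacts are further gated by a *delayed folding* rule:
per residue, the summed strength of its category-III contacts is computed
(residues below `res_strength_min = 20` contribute nothing), the running
sum is taken from residue $L$ toward the N terminus, and only residues
where this cumulative compacted strength strictly exceeds
`cum_threshold = 750` atom-count units may report unsatisfied contacts.
This encodes that small scattered contacts do not constitute a stable
partial fold for a chaperone to grip. The cumulative sum runs over
*residues* (not contacts) and the comparison is strict; both choices are
config switches (`model_params(cum_strict = )`) because the alternative
readings are equally literal. Eligibility is tested on the emerged
(N-terminal) residue of a category-II contact — that is the residue that
is physically exposed.

**3. Three binding models.** At each $L$,

* `tf_raw` — sum of strengths of eligible category-II contacts with both
  residues in the same annotated domain;
* `dnak_raw` — same for contacts split between two domains, with the key
  difference that inter-domain contacts are *never* promoted to category
  III: native interfaces are assumed to form only post-translationally
  (pearl-necklace picture), so they stay unsatisfied until termination;
* `mg_raw` — a molten-globule alternative in which every emerged residue
  of a domain contributes its total native contact strength until the
  domain's last residue is attached to the chain (tunnel included), at
  which point the whole domain is satisfied at once. "Available" here
  means translated, not tunnel-emerged: completion of synthesis is the
  natural trigger for immediate satisfaction.

Contacts touching residues outside every accepted domain contribute to
neither TF nor DnaK scores. Domains are accepted greedily by similarity
rank: candidates longer than 10 residues are taken in rank order and a
candidate is rejected when its overlap with already-accepted domains
exceeds 5% of its own length; rank ties go to the longer candidate, then
the smaller start, so the assignment is order-independent.

**4. Comparison with SeRP.** Model output is compared to the
SeRP-derived lower confidence bound by normalized cross-correlation at
zero lag (`ncc()`), computed in mean-subtracted Pearson form. NCC is
invariant to affine rescaling of either signal, so all science-level
comparisons run on *raw* profiles; `normalize_profile()` — which maps the
raw range onto `[0.25, engagement score]` — is purely presentational.

## SeRP enrichment statistics

Footprint counts of the chaperone-selected and total translatome are
summed per codon over a sliding window, treated as a binomial split
$a$ vs $a + b$, and the Agresti–Coull 95% interval on the proportion is
mapped through $r = p/(1-p)$ and the library-size ratio to an enrichment
ratio with CI. Windows are truncated at gene ends; windows with no reads
are masked missing; ratios are clamped at `ratio_cap = 100` (far above
every decision threshold, so calls are unaffected). Replicates are
averaged on the ratio/bound scale.

**Window alignment.** The window assigned to codon $c$ covers the codons
$c - 14 \dots c$ (`align = "trailing"`), not a symmetric neighborhood.
This is a deliberate choice: a ribosome observed at codon $c$ has been
bound by the chaperone while traversing the *preceding* codons only, so a
trailing window never attributes downstream enrichment to an earlier
codon. It also keeps the windowed profile causal for onset calling: with
centered windows, an enrichment step is flagged several codons before it
begins. `serp_params(align = "centered")` restores symmetric windows.
With trailing windows the onset estimator still lags a sharp enrichment
step by about 3 codons — the lower CI can only clear the 1.5 threshold
once roughly $\lceil 0.5 \cdot 15 / 3 \rceil = 3$ enriched codons are
inside the window — a resolution limit worth keeping in mind when
interpreting onsets (about 1 nm of nascent chain).

Derived statistics:

* **Engagement score** — per-replicate CI profiles with a 45-codon
  window, averaged, then the maximum lower bound excluding the first 30
  and last 10 codons (initiation artifacts; reads from downstream genes).
  Note that windows positioned just inside the trimmed range still
  *overlap* the trimmed codons, so a very strong head peak attenuates
  rather than disappears.
* **Binding onset** — per codon: 1 if the lower bound exceeds 1.5, 0.2 if
  the CI straddles it, 0 otherwise; replicate-averaged values strictly
  above 0.6 are bound (both replicates must be confident); runs shorter
  than 6 codons are discarded; the onset is the 5′-most surviving codon.
* **Metagene** — start/stop-aligned, optionally shifted 30 aa toward the
  5′ end (tunnel exit), binned at 6 codons with exact (mass-conserving)
  bin means, across-gene mean ± 1.96 SEM. The across-gene CI estimator is
  a normal approximation; nothing downstream depends on this choice.
* **Domain-wise metagene** — each accepted domain resampled to 30 bins
  and each inter-domain linker to 10; linkers over 40 aa excluded.
  Segments shorter than the bin count are linearly interpolated,
  otherwise bins are contiguous index ranges (exact means).
* **Occupancy statistics** (single-molecule assays) — per-fragment event
  counts divided by molecules and measurement time, normalized to sum to
  one, with standard error $\sqrt{p(1-p)/N}$.

## Clustering and substrate ranking

Lower-CI profiles (genes ≥ 50 codons, trimmed 30/10) are compared
pairwise by unconstrained dynamic time warping with absolute-difference
local cost (a squared-Euclidean variant matching the tslearn default is
available), costs are clipped at 500, and the clipped matrix is clustered
with Ward linkage and cut at $k = 2$; the cluster with the higher median
engagement score is labelled A (high affinity). Two caveats are inherited
from the method, not the implementation: Ward linkage on a non-Euclidean
cost matrix is a heuristic, and DTW can warp away *positional* differences
between profiles — two equal-amplitude peaks at different codons align
cheaply — so the clustering separates profiles chiefly by amplitude and
shape, not peak location.

## The synthetic-data generator

`make_structure()` plants a known architecture: each domain is a compact
cloud of residues (uniform in a 4.5 Å ball, 5 pseudo-atoms per residue),
linkers are placed far from everything with sub-threshold pLDDT (60), PAE
is 2 Å within domains and 15 Å across, and each adjacent domain pair
shares exactly one interface contact of configurable strength (default
40, realized by extra atoms at a site between the clouds with PAE 3 Å).
Contact extraction on these toys is verified against a brute-force
all-atom-pair oracle, so the planted truth is honest rather than assumed.

`simulate_serp()` draws a per-codon dwell factor
$\lambda(c) \sim \Gamma(\phi, \phi)$ *shared* between the selected and
total libraries and across replicates, then Poisson counts around
$\mu\lambda$ (total) and $\mu\,e(c)\,s\,\lambda$ (selected, $s$ the
library-size ratio). Totals are therefore marginally negative binomial
with mean $\mu$ and dispersion $\phi$, and — because real ribosome
dwell-time variation affects both libraries of one sample identically —
the enrichment ratio remains well calibrated, which is the premise of
ratio-based SeRP statistics. Defaults $\mu = 50$, $\phi = 5$ (strong
codon-level overdispersion) were fixed once as realistic study
conditions. `shared_dispersion = FALSE` gives independent negative
binomial totals instead. What the generator does *not* emulate: realistic
protein geometry, sequence-dependent dwell signatures, initiation ramps,
multi-mapping artifacts, or chaperone-induced changes in elongation — so
green tests demonstrate that the statistics recover planted truth under a
fair noise model, not that the biology of any particular gene is
captured.

`end_to_end_fixture()` closes the loop: the truth enrichment of each
synthetic gene *is* its own TF model prediction (affinely mapped to
baseline 1, peak 4), so NCC between model and recovered SeRP profile, and
onset recovery against the first codon with $e > 1.5$, have known
targets.

## Numerical choices and degenerate inputs

* 95% z fixed at `qnorm(0.975)`; Agresti–Coull bounds clamped to [0, 1]
  before the ratio transform; zero-read windows masked, not zero-filled.
* Constant raw profiles normalize to the 0.25 floor everywhere; constant
  signals have NCC 0 by convention.
* DTW of empty series, empty profiles, genes shorter than the trims, and
  zero-molecule fragments are errors, not silent results.
* All generators are deterministic given their seed; identical config and
  seed reproduce byte-identical tables.

## Problem sizes used in the test suite

The suite exercises the pipeline at deliberately small scale: 20 random
structures of ≤ 50 residues for the contact oracle, 50 random contact
maps for category properties, 200 planted-step genes of 300 codons at
$\mu = 50$ for onset recovery, a 10-gene end-to-end panel for NCC
recovery, 50 seeds of a 10-gene two-family panel for clustering, and
10,000 replicates per cell for CI calibration. These sizes give stable
statistics for every property while keeping a full run in minutes on one
CPU.

## Known limitations

* The binding model is equilibrium-free and kinetics-free: no folding
  rates, no ribosome-surface effects, no steric occlusion of the TF
  docking site for C-terminal domains.
* The Agresti–Coull interval is mildly conservative at small window
  counts and extreme proportions (exact coverage ≈ 97.4% at $n = 30$,
  $p = 0.1$); this is a property of the interval itself.
* Onset calls inherit the window's resolution limit (~3 codons late on a
  sharp step, more under strong overdispersion).
* Ward-on-DTW clustering and the $k = 2$ cut are heuristics; the A/B
  split is only as meaningful as the separation in the cost matrix.

## A minimal run

```{r example, eval = FALSE}
st <- make_structure(n_domains = 2, residues_per_domain = 60, seed = 1)
prediction <- predict_gene(st$model, st$pae, st$candidates)

fx <- end_to_end_fixture(seed = 1, n_genes = 10, mu = 50)
profiles <- average_replicates(windowed_enrichment(fx$counts))
scores <- engagement_score(fx$counts)
onsets <- binding_onset(windowed_enrichment(fx$counts))

D <- profile_distance_matrix(profiles)
clusters <- cluster_ab(D, scores)
tidy(clusters)
```
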