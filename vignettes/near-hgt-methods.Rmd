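---
title: "Detecting intra-clade horizontal gene transfer: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intra-clade horizontal gene transfer: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nearhgt)
```

## The detection problem

Horizontal gene transfer between distant bacteria is found either by gene
trees that contradict the species tree or by segments whose nucleotide
composition looks foreign. Both signals vanish when donor and recipient
are strains of one species: the sequences are nearly identical and so are
the genomic signatures. This package targets exactly that regime —
*intra-clade* transfer — with two signals that survive it: a transferred
gene sits in a **new genomic neighborhood**, and its sequence shows the
**wrong amount of divergence** between the strains.

## Stage 1: the synteny-index screen

A genome is modeled as an ordered (by default circular) sequence of gene
identifiers; sequence evolution is modeled separately, per gene. The
*k*-neighborhood `N_k(G, g)` is the set of up to `k` genes on each side of
`g`, and the synteny index of a gene shared by two genomes is
`SI = |N_k(G1, g) ∩ N_k(G2, g)| ∈ [0, 2k]`. Genes absent from either
genome score 0. The genome-level `average_si` is the mean of `SI/2k` over
the union of gene sets: 1 for identical genomes, 0 for disjoint ones (the
identity requires at least `2k + 1` genes; smaller genomes cannot fill a
neighborhood).

Parameters and choices:

* **`k` (neighborhood radius, genes; default 10).** Large enough that a
  conserved neighborhood is informative, small enough to stay local;
  SI histograms then live on 0–20, where empirically most core genes of
  strain pairs sit at 17–20 and relocated genes at 0.
* **Cutoff `C(delta_si)` (default `delta_si = 0.05`).** The largest
  *observed* SI level such that the fraction of core genes at or below it
  stays under `delta_si`; −1 when the low tail is empty. Only observed
  levels raise the cutoff, so a distribution concentrated at `2k` yields
  −1 rather than an arbitrary level just below the mass.
* **Candidate rule.** Inclusive (`SI <= C`) by default; the strict variant
  is available via `rule = "lt"` because the procedure can be read either
  way. The inclusive rule matches the practice of treating all genes at or
  below the cutoff as candidates.
* **Core vs union.** The cutoff fraction is taken over *core* (shared)
  genes — only those can be validated downstream — while `si_histogram`
  reports both tallies, since genes private to one genome pile up at 0.
* **Paralogs.** Duplicate identifiers are canonicalized to the first
  occurrence in genome order and logged; neighborhoods are identifier
  sets. The gene-order model treats a genome as a near-permutation and
  does not attempt paralog pairing.
* **Determinism.** Candidate lists sort by (SI, identifier).

Relocating a single gene farther than `2k` from its origin drives its SI
to 0 with certainty on otherwise-identical genomes (both neighborhoods
change completely), while genes farther than `k` from both sites keep
`SI = 2k` — the property the screen exploits, and one of the invariants the
test suite checks.

The screen cannot tell transfer from translocation or duplication, and it
cannot orient donor and recipient from one pair alone: a transferred gene
has low SI between the recipient and *every* genome carrying the ancestral
neighborhood. With three or more strains this becomes a feature:
`infer_recipient` returns the single organism common to all low-SI pairs
of the gene, provided the gene looks native among the remaining organisms,
and `"undetermined"` otherwise.

## Stage 2: the CRM validation

The rate ratio of two genes is approximately conserved along lineages
(the pacemaker observation, validated in bacteria). For candidate `g_h`,
witness `g_w`, strains `s1, s2` and references `r1, r2`:

* `rho = d_gh(r1, r2) / d_gw(r1, r2)` — the shared divergence time of the
  reference pair cancels, so `rho` estimates the rate ratio;
* `d'_gh = rho * d_gw(s1, s2)` — the divergence the candidate *should*
  show between the strains;
* both observed and expected distances are mapped back to mismatch
  fractions with the Jukes–Cantor forward formula
  `h = (3/4)(1 − e^(−4d/3))`, and compared via
  `chi2 = l (h_obs − h_exp)^2 / (h_exp (1 − h_exp))` with 1 degree of
  freedom over the gene's `l` comparable sites.

Numerical and design choices:

* **Distance model.** Jukes–Cantor throughout, isolated behind
  `jc_correct`/`jc_to_hamming` so another time-reversible model could be
  slotted in. Distances at `h >= 3/4` are saturated: flagged, skipped,
  logged — never silently dropped. Gap/ambiguity columns are excluded
  pairwise (per-pair deletion), which maximizes usable sites; input is
  case-insensitive and validated to `A C G T N -`.
* **Hamming scale.** The chi-square treats sites as Bernoulli trials, so
  it is evaluated on the mismatch-fraction scale after converting the JC
  distances, exactly as the worked example in the test suite does. The
  algebraically identical two-cell form `sum (O−E)^2/E` is computed
  alongside and asserted equal to 1e−9 — a guard against regressions in
  either form.
* **Witness eligibility.** Witnesses are core genes of the strain pair,
  present in both references, that are *not* themselves SI candidates for
  that pair: a transferred witness biases the expected distance and masks
  detection, so suspected genes are excluded conservatively.
* **Multiple testing.** Bonferroni per candidate gene: the raw p-value is
  multiplied by the number of tests actually performed for that gene
  (witnesses × reference pairs, skips excluded from the denominator).
  Default `delta_rho = 0.01` on the corrected value.
* **Direction.** Both tails are reported. A distance *decrease* is the
  classic signature (the copies coalesce at the transfer, not at the
  strain split); an *increase* indicates the strain acquired the gene from
  a lineage outside the analyzed set, which shows up as excess divergence.
* **Degenerate inputs.** Zero witness reference distance (`rho`
  undefined), zero or saturated expected distance, missing orthologs —
  each yields a skip record with its reason in `$skips`.

## The simulation study

`run_replicate` and the `sweep_*` functions reproduce the power study: a
Yule (pure-birth) species tree over 20 taxa, all tips extant, branch
lengths in expected substitutions per site (rate 1 — only ratios matter to
CRM, so this loses no generality); a witness gene evolved on the species
tree; a transfer grafted by re-attaching the recipient tip onto the donor
lineage at a fraction `height` of the recipient-to-LCA path (0 = at the
leaves, 1 = at the ancestor, where the gene tree coincides with the
species tree); the transferred gene evolved on the grafted tree; the four
JC distances estimated from the simulated sequences; and the CRM
chi-square applied. Grafting provably conserves every tip-pair path not
involving the recipient, keeps the tree ultrametric, and makes the
recipient–donor gene distance `2 * height * t(LCA)` — all verified
exactly in the tests.

Simulation conditions (chosen once, documented here):

* **Birth rate 5.** Expected root height `sum_{k=2..20} 1/(5k) ≈ 0.52`,
  so the deepest tip pairs diverge by about one substitution per site and
  reference-pair distances land near the mid-0.5s — the divergence scale
  of the worked example's reference organisms, and a realistic backdrop
  for strain-level work.
* **Pair choice `"deep"`.** A power study chooses its organisms; the
  simulator picks the most diverged pair as the strains and the most
  diverged remaining pair as references, maximizing signal
  ("laboratory conditions"). `"random"` pairs are available and markedly
  weaker.
* **Significance level 0.05 for the sweeps** (the single-test default
  stays 0.01): the conventional level for operating-characteristic
  curves.
* **20 replicates per grid point** by default, matching the study design
  the curves summarize; acceptance computations raise single points to
  100 replicates to shrink binomial noise.
* **Saturated replicates** (possible at 20-taxon depths with short genes)
  are redrawn by continuing the RNG stream and counted in `redraws`.

What the sweeps show, and their honest limits. Identification is certain
for transfers at the leaves with long genes, decays with event height and
grows with gene length; false-positive rates are flat in gene length
(every term in the statistic scales as `1/sqrt(l)`), which the suite
asserts. Two published-style operating points are *not* reachable in this
simulation and the corresponding checks are expected to fail: perfect
identification of an 80 bp gene transferred at height 0.7, and a perfect
plateau up to height 0.4 at 70 bp. The mismatch-fraction gap between a
grafted and an ungrafted gene at height 0.7 is at most ≈ 0.10 over all
tree depths, below the 1% rejection threshold `2.58 sqrt(h(1−h)/80)` even
if the expected value were known noiselessly — with 80 observed sites the
signal cannot clear the bar, whatever the tree scale. Similarly, the
false-positive rate does not decline monotonically with organism
distance here: the variance inflation of the statistic (driven by the
noise of the estimated expectation relative to its nominal binomial
variance) *grows* with distance below the saturation point, in both the
Yule-rescale and a controlled fixed-reference design. These gaps are
properties of estimating all four distances from the same short
sequences; the sweep functions report what the model actually does.

## Synthetic fixtures

`make_fixture` builds the end-to-end test bed: a two-clade ultrametric
tree (shallow strain clade, default height 0.02 substitutions/site —
strain-level divergence; deeper reference clade at 0.3; root at 0.6),
sixty 1 kb genes evolved per the JC model, identical ancestral gene
orders, and implanted transfers that both re-route the gene tree (default
event height 0.1 — a recent transfer) and relocate the gene in the
recipient's order to a slot more than `2k` genes away, mimicking random
insertion. The generator emulates what the method needs to see —
conserved synteny, strain-scale divergence, a known ground truth — and
deliberately not what real strain data adds: gene gain/loss, paralogy,
rearrangement hotspots, rate heterogeneity across sites and genes, or
alignment error. Recovery on fixtures therefore demonstrates correctness
of the machinery, not field performance.

## Composition scan

The comparison baseline for composition-based detection: the `4^w`-word
spectrum (w = 1–4, or the two-component G+C spectrum) of 2000 bp windows
slid at 10 bp steps, each window's Euclidean distance to the whole-genome
spectrum, and δ-atypical calls above the empirical `1 − δ` quantile
(strict inequality, so a constant-composition genome yields no atypical
windows, and at most a δ fraction ever can). Genes are called atypical if
any overlapping window is (`"majority"` rule available); genes no window
overlaps are reported uncovered. Words are counted overlapping, on the
given strand only, on the linearized sequence; words touching non-ACGT
characters are ignored. Between close relatives this scan is expected to
find little — that weakness is the reason the synteny/CRM route exists —
and the packaged scan exists to make that comparison reproducible.

## Known limitations

* SI assumes reconciled gene identifiers (e.g., a shared annotation
  namespace); no ortholog calling is performed.
* The CRM test inherits JC's assumptions (equal base frequencies, one
  rate); gross model violation shifts both observed and expected
  distances, only partially cancelling.
* The chi-square treats the expected fraction as known, so the test is
  anti-conservative when the witness and reference distances are
  themselves noisy (short genes, distant references) — visible as
  elevated false-positive rates in `sweep_fp`.
* Recipient inference needs the gene present (and ancestrally placed) in
  at least three strains; two-strain analyses report `"undetermined"`.
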