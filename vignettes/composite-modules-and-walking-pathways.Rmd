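---
title: "Composite regulatory modules, master regulators and methylation biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite regulatory modules, master regulators and methylation biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwalker)
```

# The scientific problem

Tumours rewire gene regulation partly by changing the DNA methylation of
small regulatory regions. When a CpG-dense region gains or loses
methylation, transcription-factor binding sites inside it open or close,
the downstream layer of signalling pathways shifts to new target genes,
and — when a regulator ends up activating its own gene through the
TF→DNA→gene chain — a positive feedback loop can lock the system into a
pathological state. pathwalker implements a workflow for finding such
loci and the regulators behind them, and for distilling the loci into a
small diagnostic methylation panel: differential methylation and
expression → CpG–gene correlation → regulatory sequence analysis of the
windows around correlated CpGs → master-regulator search in a signalling
network biased toward self-amplifying loops → marker decorrelation and
classifier evaluation.

Because the data that motivated this design (patient cohorts, licensed
motif and pathway databases) are not redistributable, every stage is
paired with a synthetic generator that plants a known signal; the test
suite and the acceptance script measure recovery of that planted truth.

# Site scoring and the composite-module model

## Match-style PWM scoring

A count matrix is converted to frequencies with a pseudocount
(default 0.25 per cell, which keeps sparse TRANSFAC-style matrices
non-degenerate), and each position gets an information weight
$I(i) = \sum_b f_{ib}\,\ln(4 f_{ib})$. A window scores
$\sum_i I(i)\, f_{i,b_i}$, min–max normalised to $[0,1]$ by the
attainable bounds, so a matrix's consensus word always scores exactly 1.
This is the classical matrix-similarity convention; core-score
filtering is deliberately omitted (single-pass scoring). Windows
containing N score 0 — conservative, no imputation. Both strands are
scanned by default and minus-strand hits are reported at their
forward-strand window start, so downstream centre calculations are
strand-symmetric.

## The module score

A composite module is a set of PWMs with cutoffs $q^{(k)}_{cutoff}$,
top-match counts $\kappa^{(k)}$ and a width $\sigma$. For one sequence,
matches below the cutoff are dropped, the best $\kappa^{(k)}$ per matrix
are kept (ties: smaller position, then + strand), and the score is the
maximum over every nucleotide position $x$ of
$\sum_k\sum_j q^{(k)}_j \cdot \phi(|x - c^{(k)}_j|;\,0,\sigma^2)$,
with $\phi$ the normal **density** and $c$ the match-window centre
($\theta + \lfloor L/2 \rfloor$). The density (not the CDF) is the only
reading under which nearer sites contribute more; the centre (not the
window start) keeps the score invariant under strand flips. $x$ is
scanned exhaustively at 1-nt resolution with ties to the smallest
position; the hot loop is implemented in C++ and the test suite holds it
to an independent pure-R evaluation within $10^{-9}$.

A full model is an ordered list of T modules scored additively. The
model's reporting threshold (`cm_score_cutoff`) only flags "module
matched" in reports; it never enters the additive score, because the
additive definition of the model score is unconditional.

## Fitness and the genetic algorithm

Given per-sequence trait values, the fitness is
$-\,\mathrm{complexity}^{-\mathrm{penalty}}\,\log_{10}(1 - |\rho|)$
with $\rho$ the Spearman correlation (average ranks for ties; constant
input is an error, not NaN) and complexity the number of distinct
matrices in the model; $|\rho|$ is clamped to $1-10^{-12}$ so a perfect
correlation stays finite. "log" is base 10. The penalty exponent
defaults to 0 (no complexity pressure) and is exposed to the user.

The optimiser is a mutation-only genetic algorithm: tournament selection
(size 3), elitism (2), and per-module mutations that add or drop a
matrix (p = 0.2 each), or perturb a cutoff (Gaussian step 0.05), the
width (log-normal step 0.2) or a top-match count (±1), each with
p = 0.3. Defaults are population 50 and 200 generations with T = 2
modules of up to 10 matrices, width bounds [10, 150] bp initialised at
30, and $\kappa \in [1,3]$. Every matrix is scanned once per sequence at
a global floor of 0.5 and cached sorted by score, so a candidate model
is evaluated by prefix-filtering the cache — this is what makes the
search affordable. Runs are bit-reproducible given the seed, and
elitism makes the best-fitness trajectory non-decreasing.

The tests and the acceptance script run the GA at desk scale
(population 24, 30 generations, pools of 8 matrices, 400 sequences of
300 bp) — chosen so a full ten-seed recovery study with matched
permuted-trait nulls completes in a few minutes while still recovering
the planted module in every seed at $|\rho| \approx 0.82$ against a
permuted-null mean around 0.19.

# Binding-site enrichment (Yes/No sets)

For each matrix the enrichment optimiser evaluates every candidate
cutoff — the distinct observed match scores in both sets plus 1.0, a
finite and complete search space — and among the candidates whose
criterion p-value is ≤ α it returns the one maximising the odds ratio
(Haldane-corrected) of a site, or a site-bearing sequence, being in the
Yes set; if none passes, the minimal-p candidate is returned flagged
not-significant. Two criteria exist: **site** (upper-tail binomial on
site counts against the background rate, with a continuity-corrected
rate when the background has no sites) and **sequence** (one-sided
Fisher exact on sequences with ≥1 site). BH correction is applied
across matrices, not across cutoff candidates, matching the convention
of reporting per-matrix optimised thresholds.

The two criteria differ sharply in calibration, and this drove a design
decision. Under null data (Yes and No drawn from the same background)
the plug-in binomial site test is **anti-conservative** once the cutoff
optimiser is allowed to pick the extreme candidate: the plug-in
background rate ignores its own sampling variance, overlapping windows
overdisperse the site counts, and the optimiser selects the most extreme
cutoff. The Fisher sequence criterion, by conditioning on the margins,
remains calibrated even after optimisation (its measured null
false-positive fraction in the test suite is at the nominal level or
below). The **sequence criterion is therefore the package default**;
the site criterion is provided as specified, with this caveat, for users
who need site-count-level sensitivity and interpret its p-values as
scores rather than calibrated probabilities.

# Master regulators and walking pathways

The signalling network is a directed graph with strictly positive edge
costs and ±1 signs. For a candidate node $k$, cheapest paths of at most
`radius` edges (default 10 — the radius counts steps) to each input TF
are computed by a truncated Bellman–Ford sweep (one relaxation round per
allowed step; an ordinary Dijkstra cannot respect a hop bound). The
score is $\sum_t 1/(1+\mathrm{cost}(k\to t))$ over reached inputs,
divided by the number of nodes reachable from $k$ within the radius:
many cheaply-reached inputs raise the score, promiscuous hubs are
penalised by their reach. The exact weighting of the original key-node
ranking is unpublished; this form is our interpretation and is fixed by
the hand-computable star-graph case (regulator feeding two inputs at
unit cost scores (1/2 + 1/2)/2 = 0.5), which the tests pin exactly.
Searches run backwards from each input once, rather than forward from
every candidate.

The context algorithm multiplies the cost of every edge **adjacent**
(either endpoint) to a context node — a product of an up-regulated
gene — by a discount (default 0.5). "Adjacent" is read as both incoming
and outgoing since the source text does not restrict the direction.
Feedback loops are enumerated by bounded depth-first search over simple
cycles through a candidate that traverse at least one TF→gene regulatory
edge; the sign product flags positive (self-amplifying) loops. On
synthetic networks where the regulator sits on a positive loop and an
off-loop twin has slightly cheaper wiring, the twin wins the plain
ranking while context weighting flips the order — the walking-pathways
signature, tested across ten random fixtures.

Isoforms: candidate nodes sharing a gene are ranked per node and
collapsed to their best-scoring node at the prioritisation step, where
candidates are filtered by absolute expression and methylation log fold
changes and ordered by score.

# Omics preprocessing

Beta-values follow the Infinium convention $M/(U+M+100)$, always
strictly below 1. Differential statistics are per-feature Welch t-tests
with BH correction; log fold changes are log2 ratios of group means
(offset $10^{-9}$ for expression; for betas the conventional 1.5 / 0.67
fold-change thresholds map to ±log2 1.5). A moderated-variance model
would need fewer samples to reach the same power; the simulations here
use ≥5 samples per group to compensate, and the type-I rate of the
plain test is verified at the nominal level in the suite. The critical
correlation $z_{1-\alpha/2}/\sqrt{n-1}$ is the large-sample
approximation for the Spearman coefficient — at $n = 120$ and
α = 0.05 it reproduces the familiar 0.18 threshold; the sample size is
an explicit argument rather than a hard-coded constant. CpG windows are
half-open intervals `[pos − w/2, pos + w/2)` clipped at zero, merged
when overlapping or touching; probe–gene pairs default to a ±2 kb
proximity rule.

# Panel construction

Pairwise Pearson correlations over all samples (cases and controls
pooled) feed a greedy decorrelation: pairs above the threshold
(default 0.8) are visited by descending |r| and the member with the
smaller univariate effect is dropped, ties to the lexicographically
smaller id — deterministic, and anchored by the convention that an
r = 0.876 pair loses a member while an r = 0.308 pair keeps both.
Panels are evaluated by stratified random 50/50 splits (default 100)
with a linear soft-margin SVM at unit cost (e1071); stratification
avoids degenerate splits at cohort sizes around 24. Accuracy is the
fraction correct; no ROC summarisation. Backward elimination
(`minimize_panel()`) drops, at each step, the marker whose removal
least degrades mean accuracy.

# Synthetic data: what it does and does not emulate

The generators are pure functions of their seed. Background DNA is
order-0 i.i.d. (GC configurable); planted modules write **consensus
words** at non-overlapping positions within ±σ of a common centre, so
recovery targets are unambiguous — real sites are degenerate, so
recovery rates here are upper bounds on real-data performance. Trait
values are a linear effect of module presence plus Gaussian noise.
Synthetic cohorts shift case betas upward (hypermethylation) around a
clean control baseline; real 450K data has probe-specific baselines,
bimodality and batch structure that these fixtures do not attempt.
Synthetic networks wire a planted regulator to every input TF cheaply
while zoned decoys can never reach more than two inputs; real pathway
databases are far denser and noisier. Passing the recovery tests
therefore demonstrates correctness of the algorithms and their
integration, not clinical performance.

The end-to-end bundle (400 CpG windows of 500 bp with the module planted
at the window centre of half the loci, 12 + 12 samples, anti-correlated
expression for each locus's paired gene, a 40-node network whose
regulator sits on a positive loop through its own up-regulated gene)
is sized so ten full pipeline runs complete in a few minutes; the
pipeline's GA settings in the bundle (population 20, 15 generations,
at most 200 model regions) reflect that choice and are plain config
fields.

# Numerical choices and degenerate inputs

* Position maximisation ties break to the smallest x; top-match ties to
  the smaller start, then + strand; decorrelation ties to the
  lexicographic id — every data-dependent choice is deterministic.
* Degenerate matrices (max score = min score) score 0 everywhere rather
  than dividing by zero; all-zero count rows require a positive
  pseudocount.
* Zero-variance features in both groups give p = 1 when the means agree
  (and 0 when they differ); constant vectors are a signalled error in
  correlation functions.
* $|\rho| = 1$ is clamped before the log so fitness stays finite.
* Coordinates are 0-based half-open everywhere internally (BED-native);
  1-based annotations are converted at the boundary.
* The pipeline validates every input path before stage 1, logs each
  stage with its parameters, keeps partial outputs on failure, and is
  byte-reproducible given the config and seed.

# Known limitations

Single-pass PWM scoring without dinucleotide dependencies; no
moderated-variance differential model; the key-node score is an
interpretation of an unpublished weighting, fixed only by its
qualitative contract and the star-graph case; loop enumeration is
exponential in principle and intended for the radius-bounded
neighbourhoods of top candidates; the site-criterion enrichment p-values
are anti-conservative under cutoff optimisation (see above); promoter
retrieval from gene identifiers is out of scope — sequences arrive
pre-extracted.
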