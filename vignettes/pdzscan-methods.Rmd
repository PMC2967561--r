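---
title: "Predicting PDZ domain-peptide interactions by proteome scanning"
author: "pdzscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting PDZ domain-peptide interactions by proteome scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzscan)
```

## The problem

PDZ domains are ~90-residue protein recognition modules that bind the
hydrophobic C-terminal tails of their target proteins in a groove between
strand β2 and helix α2. Their binding preferences are narrow enough to be
learnable from data, and broad enough that a reliable predictor is useful:
given a trained model for a domain, every unique C-terminal 5-mer of a
proteome can be classified to nominate candidate binding partners.
`pdzscan` implements such a predictor as a binary classifier of
(domain, peptide) pairs, with the surrounding machinery that makes it
usable in practice: filtering of training data, construction of artificial
negatives, several feature encodings, cross-validation schemes that measure
different kinds of generalization, baseline predictors, and the proteome
scan itself.

A domain is represented by the 16 alignment columns of its binding site
that contact the peptide; a peptide by its last five residues, numbered
p-4..p0 with p0 the C-terminus.

## Genomic-like filtering of positive-only data

Phage-display selections report only binders, and may report optimal
binders that do not occur in any real proteome. A peptide is called
*genomic-like* when its last four residues match the last four residues of
some real protein tail. Domains are then categorized by how many unique
genomic-like and non-genomic-like peptides they bind (threshold 10):
`genomic_like`, `non_genomic_like`, `dual`, or `non_specific`.
`enrichGenomicLike()` applies the filter in this order: categories are
assigned on the unfiltered data; non-genomic-like domains are dropped
entirely; dual domains lose their non-genomic-like interactions and are
dropped if fewer than 10 unique genomic-like peptides remain; genomic-like
and non-specific domains are kept unfiltered provided they have at least 10
unique peptides in total. The unique-peptide counts use fully unique
5-mers.

## Artificial negatives from PWMs

Training a binary classifier requires negatives. For positive-only data
`generateNegatives()` builds, for each domain, a position weight matrix
(PWM) from its binders and selects negatives from the pool of unique real
binders of *all* domains: only candidates scoring *strictly below* the
minimum PWM score of the domain's own positives are eligible (a peptide
tied with an observed binder is score-indistinguishable from it, so ties
are excluded), and candidates are accepted greedily in ascending score
order, skipping any candidate sharing more than `redundancyMaxIdentity`
(default 3 of 5) identical positions with an already-accepted negative.
Greedy lowest-score-first acceptance makes the selected set maximally
unlike the binders while keeping it non-redundant; the exact redundancy
rule is this package's own operationalization of "low redundancy", chosen
once and configurable. The default quota of 2 negatives per positive
mirrors the roughly 2:1 negative-to-positive ratio of the original
phage-display training compendium (745 artificial negatives for 363
positives). A domain whose quota cannot be met is flagged, and can be
excluded from training -- this is the operational meaning of a domain
being "difficult to generate artificial negatives for".

Three baselines are provided for comparison: `random` (i.i.d. uniform
residues), `shuffled` (permutations of each positive), and
`randomly_selected` (uniform draws from the same below-cutoff pool,
ignoring score order).

PWM scoring is the sum of log2 cell probabilities. No background model is
used: the selection cutoff and the ensemble baseline only require rank
consistency, and probabilities are the simplest faithful reading of the
PWM definition. The default pseudocount 0.01 exists to keep unseen
residues scoreable; it is configurable everywhere.

## Feature encodings

The principal encoding is the *contact map*: a fixed list of 38
(domain position, peptide position) pairs covering all 16 binding-site
positions and all 5 peptide positions, derived from a PDZ-peptide
co-crystal structure (residue pairs within 5 Å). Each pair contributes a
400-bit block, a one-hot 20 × 20 residue-pair matrix, giving binary
vectors of length 15,200 with at most one set bit per block. The package
ships a reconstruction of the pair list (the published constants are the
pair count and coverage, which the shipped file reproduces exactly; the
identity of individual pairs is not published, and no algorithmic
behaviour depends on it). The bit layout -- pair-major, then domain
residue × 20 + peptide residue, amino acids alphabetical -- is this
package's frozen convention. A gap '-' at a domain position encodes as an
all-zero block ("no information").

Two comparison encodings are included: `binary_sequence` (one-hot blocks
for the 21 residues, length 420) and `physicochemical` (a five-factor
numeric descriptor per residue, length 105, using the published five-factor
amino-acid descriptor set shipped under `inst/extdata`, min-max scaled to
[0, 1] per factor). `fitScaler()`/`applyScaler()` provide per-dimension
min-max scaling fitted on training data; test values outside the training
range are clipped to [0, 1] so kernel inputs stay bounded, and constant
dimensions scale to 0. Binary encodings pass through unchanged. Scaling is
applied after encoding.

## The weighted-cost RBF SVM

The classifier is a soft-margin SVM with the radial basis function kernel
$K(x, z) = e^{-\gamma \lVert x - z \rVert^2}$. Class imbalance is handled
with per-class box constraints $C^+ = (n^+/n^-)\, C^-$, so the smaller
class's constraint scales with the imbalance. The dual problem is solved
by libsvm (via `e1071`), called on the package's sparse feature matrices;
the decision function is evaluated by this package's own kernel expansion
over the extracted support vectors,
$f(x) = \sum_i \alpha_i y_i K(s_i, x) + b$, with the label +1 assigned
when $f(x) \ge 0$ (sgn(0) = +1). The expansion reproduces libsvm's
decision values to ~1e-14 and makes text-serialized models
self-contained. Because solver libraries orient the decision function by
factor-level internals, the sign is normalized against the training labels
at fit time. The solver tolerance defaults to 1e-3 and is configurable
(`tol`); tests that compare against a quadratic-programming oracle tighten
it.

`gridSearch()` scans log2-spaced grids (defaults $C \in 2^{-5..15}$,
$\gamma \in 2^{-15..3}$, the conventional exhaustive ranges) by seeded
stratified k-fold cross-validation, scoring by mean ROC AUC -- AUC matches
how performance is reported downstream -- with ties broken toward smaller
$C$, then smaller $\gamma$.

## Evaluation

`computeMetrics()` implements TPR/recall, FPR, precision and F1, with the
0/0 cases of precision and F1 defined as 0 (logged). `rocPrCurves()`
sweeps all score thresholds with tied scores grouped: ROC AUC by the
trapezoidal rule (equal to the Mann-Whitney U statistic, which the tests
verify exhaustively), PR AUC by the achievable-point interpolation of
Davis and Goadrich, stepping true positives one at a time and
interpolating false positives linearly between adjacent threshold points.

`runCV()` implements the cross-validation schemes that probe different
generalization questions: stratified ten-fold at the interaction level
(how well does the model interpolate?), leave-a-fraction-of-domains-out,
leave-a-fraction-of-peptides-out and both (how well does it extrapolate to
unseen entities?), and leave-one-domain/peptide-out with per-entity AUCs.
The held-out fractions default to 12% of domains and 8% of peptides (the
source literature states the two fractions inconsistently between its
methods and its figures; both are parameters here, with the figure
caption's assignment as default). A repeat whose held-out or training side
lacks both classes is redrawn up to a cap, with a message.
`similarityStratifiedAUC()` bins leave-one-out AUCs by each entity's
binding-site (or peptide) similarity to its nearest training neighbour --
similarity being the fraction of identical aligned positions, gaps
matching only gaps.

Two baselines: `nearestNeighbourPredict()` returns the label of the most
similar training interaction (domain similarity first, then peptide
similarity; score = product of the two; ties prefer the positive label,
then lexicographic order -- the published description of this baseline is
informal, so this concrete rule is the package's documented
reconstruction). `pwmEnsemblePredict()` scans tails with the PWM of the
nearest training domain and returns the top 1% by score.

`fisherOverlapTest()` is the one-sided hypergeometric upper tail used to
ask whether predicted binders overlap known binders more than chance, via
`stats::phyper`.

## Proteome scanning

`extractCTerminalTails()` collects the unique k-mer tails of a proteome
FASTA (trailing stop characters stripped, short sequences skipped), mapping
each tail to every protein sharing it; prediction operates on unique tails
and maps hits back to proteins. `scanProteome()` encodes every tail
against a domain and classifies it; tails containing non-standard residues
(X, U, B, ...) are skipped with a warning rather than imputed.
`validateScan()` reports recall over known binders, FPR only when known
non-binders are supplied (NA otherwise -- absence of negatives is not
evidence of specificity), and the Fisher overlap p-value.

## The synthetic data generator

`syntheticDataset()` emulates the statistical shape of the training
compendia -- domains with position-specific binding preferences, positive
peptide sets sampled from them, and a decoy proteome -- without any
external data. Each domain family founder gets a random 16-residue site
and a planted specificity: per peptide position, a favoured residue
carrying weight $w = s/(s+1)$ (sharpness $s$; the remaining mass is
uniform over all 20 residues, so $s \to \infty$ collapses positives onto
the consensus and $s = 0$ is uniform). Family members mutate the
founder's site at 0-8 positions and re-draw each favoured residue with
probability proportional to the site divergence, so similar sites imply
similar specificities -- the property that makes similarity-stratified
analyses meaningful on synthetic data. Positives are sampled from the
specificity (duplicates retained: multiplicity carries the frequency
signal a PWM estimates); negatives are uniform random decoy tails; labels
flip with probability `labelNoise`. The decoy tail map doubles as the
synthetic proteome and includes every positive peptide, so positives are
genomic-like by construction.

The generator's defaults are the package's chosen study conditions:
sharpness 4 (a strong but not deterministic preference, ~81% of the mass
on the favoured residue, resembling a class I/II-like motif with
variability), 2 negatives per positive (the training compendium's ratio),
zero label noise unless requested. What passing tests on this generator
show is that the pipeline recovers planted, position-independent
preferences; real data differ in ways the generator deliberately omits --
correlations between ligand positions (a PWM cannot represent them, and
the generator inherits that simplification), non-uniform proteome tail
composition, and experimental noise structure -- so synthetic performance
is an upper bound, not a forecast.

## Numerical and design choices

* Interaction tables are TSV with columns `domain_id`, `binding_site`,
  `peptide`, `label`, `source` (plus optional `organism`); duplicated
  (domain, peptide, label) rows are dropped with a warning at read time,
  and errors name the offending line. Gaps are permitted in aligned
  binding sites, never in peptides.
* PWM similarity is 100 × the mean over columns of $(r+1)/2$, $r$ the
  Pearson correlation of the 20-entry probability vectors: bounded,
  symmetric, 100 at identity; a zero-variance column contributes 50. The
  metric used for the corresponding published figure is not public, so
  this definition is the package's documented stand-in.
* Sequence-logo export writes letter heights $p \cdot IC$ with
  $IC_j = \log_2 20 + \sum_a p_{aj} \log_2 p_{aj}$ bits; rendering is left
  to plotting tools.
* Ten-fold CV AUCs are reported both as per-fold means and as pooled
  curves; the two answer slightly different questions and both are
  returned.
* All stochastic steps take explicit seeds; the pipeline derives per-stage
  seeds from one root seed, and a manifest records the configuration and
  artifact checksums.

### Problem sizes used by the checks

The package's own end-to-end checks run the pipeline at 50 domains × 50
peptides (sharpness 4, no noise, 3,000 decoy tails) for the held-out and
CV-scheme comparisons, and 24 domains × 25 peptides over 16 families
(8 of them singletons, to populate the low-similarity bins) for the
leave-one-domain-out similarity analysis. These sizes give stable AUC
estimates while keeping a full run in the minutes range on one CPU.

## Known limitations

* The contact-map pair list is a labelled reconstruction; results depend
  only on its published constants (38 pairs, 16 + 5 positions).
* The predictor shares the sequence-similarity dependence it measures:
  domains without a similar training neighbour (below ~60% binding-site
  identity) are predicted poorly, and the similarity-stratified analysis
  exists to quantify exactly that.
* PWMs (and the synthetic generator) assume independence between ligand
  positions.
* Proteins carrying several PDZ domains cannot have protein-level
  interactions attributed to a specific domain by sequence alone; scan
  validation against protein-protein interaction lists is therefore a
  rough estimate.
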