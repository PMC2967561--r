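# pdzscan

Proteome scanning for PDZ domain–peptide interactions with support vector
machines.

PDZ domains recognize the C-terminal tails of their target proteins, and
their binding preferences are specific enough to learn from experimental
interaction data. `pdzscan` trains a binary classifier of
(domain, peptide) pairs and uses it to scan whole proteomes: every unique
C-terminal 5-mer is classified against a domain model to nominate
candidate binding partners. It is aimed at researchers who have
domain–peptide interaction tables (protein microarray, phage display) and
want genome-scale candidate binder lists with honest performance
estimates.

## The method

A domain is represented by the 16 aligned binding-site positions that
contact the peptide; a peptide by its last five residues p-4..p0. The
pipeline:

1. **Genomic-like filtering** (`enrichGenomicLike`) — phage-display data
   contain binders that may not exist in any proteome; peptides whose last
   four residues match a real protein tail are kept, and domains are
   categorized (genomic-like / non-genomic-like / dual / non-specific) by
   unique-peptide counts at a threshold of 10.
2. **Artificial negatives** (`addArtificialNegatives`) — positive-only
   data need negatives for binary training. A PWM built from each domain's
   binders selects, from the pool of all domains' real binders, peptides
   scoring strictly below the domain's minimum positive score, accepted
   greedily in ascending score order under a pairwise redundancy cap
   (≤ 3 of 5 identical positions). Baselines: random, shuffled,
   randomly-selected.
3. **Contact-map encoding** (`encodePair`) — each of 38 contacting
   (domain, peptide) position pairs contributes a one-hot 20 × 20
   residue-pair block: binary vectors of length 15,200 = 38 × 400.
   Binary-sequence (420) and physicochemical (105) encodings are included
   for comparison.
4. **Weighted-cost RBF SVM** (`trainSVM`) — decision function
   f(x) = Σᵢ αᵢyᵢ K(sᵢ, x) + b with K(x, z) = exp(−γ‖x − z‖²), label +1
   iff f(x) ≥ 0 (sgn(0) = +1), and per-class costs C⁺ = (n⁺/n⁻) C⁻ to
   balance the classes. The dual is solved by libsvm (`e1071`);
   `gridSearch` tunes (C, γ) by seeded stratified CV.
5. **Evaluation** (`runCV`) — ten-fold CV plus leave-domains-out,
   leave-peptides-out and leave-one-entity-out schemes, ROC and
   precision–recall curves (Davis–Goadrich interpolation),
   similarity-stratified AUCs, a nearest-neighbour baseline and a PWM
   ensemble baseline.
6. **Proteome scan** (`scanProteome`, `validateScan`) — classify every
   unique tail of a FASTA proteome, map hits back to proteins, validate
   against known-interaction lists with recall, FPR and a one-sided
   Fisher (hypergeometric) overlap test.

A seeded synthetic generator (`syntheticDataset`) plants per-position
binding specificities on domain families so the entire pipeline is
testable without external data. See the methods vignette
(`vignettes/pdzscan-methods.Rmd`) for the model details and design
choices.

## Worked example

```r
library(pdzscan)

# simulate a small study: 12 domains with planted specificities
ds <- syntheticDataset(nDomains = 12, peptidesPerDomain = 20,
                       sharpness = 4, nDecoyTails = 1500, seed = 42)
ds$interactions
#> PdzInteractionSet: 720 interactions ( 240 positive / 480 negative ) over 12 domains

# phage-display-style route: positives only, then PWM-selected negatives
pos <- positiveOnlyView(ds$interactions)
training <- addArtificialNegatives(pos, method = "pwm_selected",
                                   ratio = 2, seed = 43)
training
#> PdzInteractionSet: 578 interactions ( 240 positive / 338 negative ) over 12 domains

# contact-map encoding and weighted-cost RBF SVM
X <- encodeInteractions(training, method = "contact_map")
model <- trainSVM(X, attr(X, "labels"), gamma = 0.05, cost = 1)
model
#> PdzSVM (RBF kernel): gamma = 0.05 , C+ = 0.71006 , C- = 1
#>   428 support vectors; trained on 240 positive / 338 negative examples; contact_map encoding

# ten-fold cross-validation
runCV(training, gamma = 0.05, scheme = "ten_fold", folds = 10, seed = 7)
#> Cross-validation (ten_fold): 10 runs
#>   mean ROC AUC: 0.9995  mean PR AUC: 0.9993
#>   pooled ROC AUC: 0.9994  pooled PR AUC: 0.9991

# scan the synthetic proteome for binders of the first domain
dm <- domainTable(training)
scan <- scanProteome(model, dm$binding_site[1], ds$tails,
                     domainId = dm$id[1])
scan
#> ScanResult for SYND001 : 1663 tails scanned, 81 predicted binders, 0 tails skipped
head(subset(scanPredictions(scan), label == 1), 3)
#>      tail      score label protein_ids
#> 10  HTFYV 0.05636755     1   SYNP00010
#> 116 KTCRI 0.05073043     1   SYNP00116
#> 220 NMFPF 0.25060231     1   SYNP00220
```

The interaction counts show the generator's 2:1 decoy-to-binder design
and, after the artificial-negative step, the PWM-selected negative set
(338 here: the redundancy cap and score cutoff leave slightly fewer than
the 2-per-positive quota for some domains). `C+ = 0.71` is 240/338 — the
weighted-cost rule keeping the two classes balanced. The near-perfect
ten-fold AUCs reflect clean planted specificities at sharpness 4; the
scan's 81 positive predictions out of 1,663 tails include the planted
binders of the scanned domain.

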