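---
title: "Substrate-motif decomposition and phosphosite scoring: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate-motif decomposition and phosphosite scoring: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mddphos)
```

## The problem

Protein kinases phosphorylate serine, threonine and tyrosine residues in
sequence contexts — substrate motifs — that are conserved around the
modified site. Given a set of experimentally verified phosphosites, the
goal is twofold: expose the distinct motif subgroups hidden in the pooled
site collection, and build a predictor that calls new sites in query
proteins. A single profile over all sites blurs the motifs together; a
model per kinase is impossible when, as in most plant phosphoproteome
data, the responsible kinase is unannotated. `mddphos` takes the middle
road: cluster first, then model each cluster.

## Data model

All computation operates on 21-mer peptide windows centered on an S, T or
Y residue (flank coordinates −10..+10 with the site at 0). Windows
overhanging a protein terminus are padded with `X`; pads never enter any
count. Every residue of the class is a data point: annotated residues are
positives, unannotated ones negatives. The three residue classes are
processed independently throughout.

Two preprocessing steps precede modeling:

* **Redundancy removal.** Duplicate windows are collapsed within each
  label set; a window appearing in both sets is kept only as a positive
  (an annotated site outranks an unannotated occurrence of the same
  context elsewhere).
* **Balancing.** The negative pool is typically 20–300× larger than the
  positive set. Rather than a uniform random draw, negatives are
  clustered into K groups (K = the positive count) on Hamming distance
  between window strings and each cluster's medoid — the member with
  minimal total distance to the rest — is selected. The result is a
  representative, size-matched negative set insensitive to a lucky or
  unlucky draw. The implementation is a k-medoids-style Lloyd iteration:
  k-means++-style seeded initialization, assignment to the nearest
  medoid, medoid update, at most 100 rounds; medoid ties break by input
  order and an emptied cluster is reseeded with the worst-fit point.
  `X` participates in the distance like any other character, so pads
  mismatch every residue and match each other.

## Maximal dependence decomposition

The clustering engine recursively partitions the positive windows on the
position pair with the strongest statistical dependence. To make the test
reflect biochemistry rather than raw residue identity, the 20 amino acids
are collapsed to five property groups:

| group | residues |
|---|---|
| acid | D, E |
| basic | K, R, H |
| aromatic | F, W, Y |
| imino | P |
| neutral | G, A, V, L, I, M, C, S, T, N, Q |

For a pair of flank positions $(A_i, A_j)$ the 5×5 contingency table of
group co-occurrence is tested with Pearson's statistic

$$\chi^2(A_i, A_j) = \sum_{m=1}^{5}\sum_{n=1}^{5}
  \frac{(X_{mn} - E_{mn})^2}{E_{mn}}, \qquad
  E_{mn} = \frac{X_{mR}\,X_{Cn}}{X},$$

where $X_{mn}$ counts windows with group $m$ at $A_i$ and group $n$ at
$A_j$, and $X_{mR}$, $X_{Cn}$, $X$ are the margins and total. A
dependence is called strong when $\chi^2 > 34.3$, the upper 0.005
quantile at $(5-1)^2 = 16$ degrees of freedom
(`chi_square_cutoff()` recomputes it rather than hard-coding). Cells with
a zero expected count are skipped, keeping the statistic defined on
sparse tables instead of collapsing categories.

At each node the split position maximizes
$S_i = \sum_{j \ne i} \chi^2(A_i, A_j)\,[\chi^2 > 34.3]$ — only
significant pairs count, following the significant-dependency convention
of the decomposition's original use on splice sites. The node divides by
presence/absence of the modal property group at that position. Recursion
stops when a node is smaller than `min_cluster_size`, no pair is
significant, or a split would leave a child empty. Reference defaults
for `min_cluster_size` are 200 (S), 100 (T) and 30 (Y), reflecting the
relative abundance of the three site classes in plant data.

### Numerical behavior worth knowing

With 19 usable flank positions there are 190 position pairs per node, so
at the nominal 0.005 level a node with no true structure still has
roughly a 50–60% chance of showing at least one significant pair (the
asymptotic test is also mildly anti-conservative on sparse tables, which
is why the generator's null calibration is asserted at 0.02, not 0.005).
Consequently nodes above `min_cluster_size` tend to keep splitting, and
deep trees over-fragment: the guard parameter, not the cutoff, is what
terminates recursion in practice. Choose it no smaller than the smallest
subgroup you would act on. The optional `merge_similar()` step
(single-linkage agglomeration on the mean per-position Jensen–Shannon
divergence between group-frequency profiles) can re-fuse fragments of one
motif; it is off by default (`threshold = 0`) so the raw tree remains the
canonical output: in practice such subgroups are merged by expert
inspection of their entropy plots, and any automated divergence
threshold is a convenience, not a substitute for that judgment.

Leaves are labeled S1, S2, ... by decreasing size. `motif_summary()`
reports, per position, residue frequencies (pads excluded) and
information content $\log_2 20 - H$ in bits — the numeric content of a
sequence-logo/entropy plot; an all-pad position is flagged and reported
as 0 bits.

## Profile models and bit scores

Each cluster trains one ungapped positional emission model from its
positive windows only:

$$e_p(a) = \frac{c_p(a) + \alpha}{n_p + 20\alpha},$$

with $c_p(a)$ the count of residue $a$ at flank position $p$, $n_p$ the
mapped (non-pad) count there, and pseudocount $\alpha = 1$ by default
(Laplace smoothing keeps every emission positive and is scale-free).
Position 0 carries no emission — the center residue is fixed by the
class. A query window scores

$$\mathrm{bits}(x) = \sum_{p \ne 0} \log_2
  \frac{e_p(x_p)}{b(x_p)},$$

pads contributing 0. A full profile HMM (HMMER-style) trained on the
same data would add nothing here: on gap-free fixed-length windows its
alignment machinery is inert and its score reduces to exactly this
positional log-odds sum, so the familiar integer bit-score threshold
semantics carry over while E-value calibration is unnecessary. The background $b$ defaults to
residue frequencies pooled over the training fragments (positives plus
balanced negatives) of the class; a uniform 1/20 background is available
and is the default for a bare `train_profile()` call.

## Threshold calibration and evaluation

Performance uses the standard confusion metrics: precision TP/(TP+FP),
sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
(TP+TN)/(TP+FP+TN+FN); a zero denominator yields an undefined (NA)
metric excluded from means, never a zero.

Each model's decision threshold is an integer bit score from −20..0.
`select_threshold()` classifies `score > t` positive and picks the `t`
maximizing accuracy, breaking ties by the most balanced Sn/Sp and then
by the larger `t` (raising the threshold favors true negatives). As `t`
rises, sensitivity is non-increasing and specificity non-decreasing — a
property asserted in the test suite.

Five-fold cross-validation splits each cluster into five near-equal
seeded folds. Per fold, the profile is trained on the other four folds
and a threshold is chosen on training data only (training positives
versus an equal-size seeded draw of the balanced negatives); held-out
positives plus a matched negative draw are then classified at that
threshold. The protocol never states which negatives belong to which
cluster, so per-fold random draws from the shared balanced negative set
are used — a declared choice, since positives cluster but negatives do
not. Per-fold metrics therefore carry no selection leakage, while the
cluster's final reported threshold is the grid value with the best mean
validation accuracy across all five folds, which is what a deployed
model uses.

The independent test evaluates calibrated models on held-out sites: per
repeat (default 10), the negative pool is re-balanced by medoid
selection under a fresh derived seed, and every test window is classified
by the ensemble rule — a site is called a phosphosite when **at least
one** model scores above its threshold, and the best-scoring model above
threshold names the matched motif. The repeat spread quantifies how much
the estimate depends on the negative draw. The ∃-rule is monotone:
adding a model can only add calls, so ensembles of many clusters trade
specificity for sensitivity by construction — visible in any run with a
weak, background-like cluster whose calibrated threshold sits low.

## The synthetic-data generator

`generate_dataset()` emulates labeled 21-mer fragment sets with planted
positional structure: positives are drawn from a mixture of motif
specifications over a background (uniform by default; a plant-like
composition can be supplied), negatives are pure background. A motif
plants a residue or property group at chosen flank positions with stated
probabilities; a coupled position pair shares a single Bernoulli draw,
so its symbols co-occur — this joint occurrence is precisely what the
chi-square dependence test detects, mirroring how proline-directed
(+1 imino) and acidophilic (+3 acid) contexts co-occur in real substrate
subgroups. Which mixture component generated each positive, and whether
all its draws fired, are returned in a separate truth table that no
training or evaluation path reads.

What the generator does *not* emulate: positional composition gradients
around real sites, homology between fragments, protein-level features
(disorder, accessibility), and unannotated true sites contaminating the
negative pool. Passing tests on synthetic data therefore demonstrate the
machinery — dependence detection, clustering, calibration, the ensemble
rule — not field performance on any organism's phosphoproteome.

## Problem sizes and default study conditions

The bundled checks run, deliberately at modest scale: planted-coupling
recovery on 1000 fragments × 100 seeds (joint probability 0.5), null
calibration on 20 replicates of 500 fragments (3800 position pairs), and
an end-to-end pipeline on a three-motif S-like mixture of 600 positives /
600 negatives (three planted positions per motif at probability 0.9,
`min_cluster_size = 200`), followed by a 10-repeat independent test on
150 fresh positives against a pool of 400. On such data the macro-average
CV accuracy sits above 0.9; clustering purity against generator truth is
≈0.97–0.98 (weighted majority-label purity over leaves — robust to the
benign over-splitting discussed above, unlike a per-motif same-leaf
criterion, which the spurious-split rate makes unattainable at these
node sizes).

## Degenerate inputs and tie-breaking, collected

* Empty contingency table → statistic 0 with a warning.
* `S_i` ties → smallest flank coordinate in magnitude, negative first;
  modal-group ties → fixed group order (neutral, acid, basic, aromatic,
  imino).
* Both-children-nonempty guard: a node whose members all share the split
  group becomes a leaf rather than producing an empty sibling.
* Medoid ties → input order; k-medoids empty cluster → reseed with the
  globally worst-fit point.
* Non-standard letters (B, Z, U, X) in inputs are accepted in sequences,
  excluded — like pads — from all counts and scores.
* Duplicate site annotations collapse with a warning; annotations
  referencing unknown proteins are dropped with a message; a
  residue/annotation mismatch is an error, since it signals inconsistent
  inputs rather than noise.

## Limitations

Subgroup counts depend strongly on `min_cluster_size`, and the
automated JS-divergence merge is a stand-in for expert entropy-plot
review. Thresholds are integers on a fixed −20..0 grid by design;
sub-bit calibration is not attempted. The balancing clusters on sequence
identity only — no substitution-matrix similarity — and the predictor
uses sequence context alone.
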