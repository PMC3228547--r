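# mddphos

Kinase substrate-motif discovery and phosphorylation-site prediction from
protein sequence alone.

Experimentally mapped phosphosites (pSer/pThr/pTyr) pool the substrates of
many kinases, each recognizing its own sequence context around the modified
residue. `mddphos` separates that pool into motif subgroups by **maximal
dependence decomposition (MDD)** and trains one positional profile model per
subgroup, giving both an interpretable catalog of substrate motifs and a
predictor for unannotated proteins.

The pipeline, per residue class (S, T, Y):

1. **Windows.** Every class residue yields a 21-mer window (flanks −10..+10,
   `X`-padded at termini); annotated residues are positives, the rest
   negatives. Duplicate windows are removed, with positives outranking
   negatives.
2. **Balancing.** Negatives are reduced to the positive count by k-medoids
   clustering on Hamming distance — representative sequences, not a random
   draw.
3. **MDD clustering.** Residues collapse to five property groups (acid DE,
   basic KRH, aromatic FWY, imino P, neutral rest). For flank positions
   $A_i, A_j$ the 5×5 group table is tested with Pearson's
   $\chi^2 = \sum_{mn} (X_{mn}-E_{mn})^2/E_{mn}$,
   $E_{mn} = X_{mR}X_{Cn}/X$; dependence is strong when
   $\chi^2 > 34.3$ (P = 0.005, 16 df). Positives are split recursively on
   the position with the largest sum of significant $\chi^2$ values, by
   presence of its modal group, until subgroups fall below a minimum
   cluster size (defaults 200/100/30 for S/T/Y).
4. **Profiles.** Each subgroup trains per-position emission probabilities
   with Laplace pseudocounts; a query window scores
   $\sum_p \log_2 (e_p(x_p)/b(x_p))$ bits against a background $b$.
5. **Calibration.** Each model's integer bit-score threshold (grid −20..0)
   is chosen by five-fold cross-validation for maximal, balanced accuracy.
6. **Prediction.** A residue is called a phosphosite when **at least one**
   model scores above its threshold; the best-scoring model names the
   matched motif. A repeated, re-balanced independent test quantifies
   generalization.

A synthetic-data generator with planted (optionally coupled) positional
motifs makes every stage testable with known ground truth.

## Worked example

Simulate an S-centered dataset whose positives mix three motif subgroups
(e.g. proline-directed `+1 P / +3 D / +5 E`), cluster, calibrate and scan:

```r
library(mddphos)

mk <- function(coords, syms) {
  motif_spec(setNames(lapply(syms, \(s) list(symbol = s, prob = 0.9)), coords),
             coupling = as.integer(coords[1:2]), weight = 1/3)
}
spec <- dataset_spec(600, 600, motifs = list(
  mk(c("1", "3", "5"),   c("P", "D", "E")),
  mk(c("-3", "-5", "-1"), c("K", "R", "K")),
  mk(c("2", "-2", "4"),  c("F", "W", "P"))), seed = 42)
ds <- generate_dataset(spec)

root <- mdd_cluster(ds$positives, min_cluster_size = 200)
cls  <- motif_clusters(root, "S")          # S1(192) S2(171) S3(127) S4(110)

bg <- background_frequencies(rbind(ds$positives, ds$negatives))
cv <- cross_validate(cls, ds$negatives, k = 5, seed = 42, background = bg)
```

Per-subgroup cross-validation (mean over folds) prints as:

```
S1 n=192 thr=-1 Pre=0.964 Sn=0.953 Sp=0.964 Acc=0.958
S2 n=171 thr=0  Pre=0.944 Sn=0.883 Sp=0.947 Acc=0.915
S3 n=127 thr=-1 Pre=0.952 Sn=0.897 Sp=0.953 Acc=0.925
S4 n=110 thr=-1 Pre=0.968 Sn=0.791 Sp=0.973 Acc=0.882
macro  Pre=0.957 Sn=0.881 Sp=0.959 Acc=0.920
```

`thr` is each model's calibrated bit-score cutoff; the macro row averages
the subgroup means — on this planted mixture the ensemble recovers the
subgroups at 92% accuracy. `motif_summary(cls[[1]])` gives the per-position
information content behind an entropy plot; S1's most informative flank
position (+1) carries 4.32 bits, a residue point mass. Scanning a query
protein:

```r
models <- train_final_models(cls, cv, background = bg)
scan_protein(models, list(id = "QP1",
                          sequence = "MAAKRLKSPADEAAGGWFSPGAAAAA"),
             all_sites = TRUE)
#>   protein_id position residue                window best_cluster best_score    decision
#> 1        QP1        8       S XXXMAAKRLKSPADEAAGGWF           S1       5.38 phosphosite
#> 2        QP1       19       S PADEAAGGWFSPGAAAAAXXX         <NA>      -1.45    non-site
```

The serine at position 8 sits in an S-P-A-D-E context and is called by the
proline-directed model S1 at 5.38 bits; the serine at 19 scores below every
threshold.

Real data enter through `load_inputs(fasta, sites_tsv)` →
`extract_fragments()` → `deduplicate_fragments()` →
`select_representatives()`, then the same clustering/calibration calls; a
thin command-line wrapper (`inst/cli/mddphos`, subcommands `simulate`,
`train`, `predict`) drives the same functions from a shell and exchanges
models as JSON bundles.

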