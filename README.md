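# tfbinder

Multi-label prediction and explanation of transcription-factor (TF)
**family** binding from DNA sequence.

Plant genomes are regulated by hundreds of TFs from a few dozen families
with heavily overlapping sequence preferences (many bZIP, bHLH, BES1 and
BZR factors all recognise the palindromic G-box `CACGTG`). Instead of one
binary classifier per TF, `tfbinder` trains a single convolutional neural
network that maps a 250 bp window of DNA to a vector of per-family binding
probabilities — the multi-label formulation used for family-level DAP-seq
compendia — and then explains and applies it:

* **Data handling** — FASTA genomes, BED/narrowPeak peak sets, GFF3 genes;
  250 bp window tiling, the 70% peak-coverage labelling rule,
  chromosome-held-out cross-validation, exact mono-/dinucleotide shuffle
  baselines (Euler-path construction).
* **Classifier** — four conv blocks (conv → batch-norm → ReLU → max-pool),
  two dense blocks, sigmoid outputs; Adam (lr 0.002), early stopping
  (patience 5), optional inverse-frequency class weights and
  offset-augmented (75/125 bp step) training for the long-tailed family
  imbalance. The network engine (C++ kernels + BLAS) lives in the package;
  its gradients are verified against finite differences in the tests.
* **Evaluation** — per-family and support-weighted auPR/auROC, MCC/F1/
  balanced accuracy, the multi-label confusion matrix with a no-label
  row/column (maskable diagonal), binned bootstrap MCC,
  abundance-performance correlation.
* **Motif discovery** — gradient×input (or sampled Shapley) attribution,
  seqlet extraction, interaction predictive motifs (IPMs), strand-aware
  motif similarity and trees, log-odds genome scanning at 85% of the
  maximum score, recovery rates, MEME-format I/O.
* **Regulatory syntax** — offset independence (24-window sliding ceiling),
  weighted co-occurrence, IPM context importance (IPMciv) and
  predictability (`1/civ - 1`), co-enrichment Z-score networks,
  model-vs-motif-occurrence FDR comparison, flank-perturbation scans.
* **Applications** — gene regulatory-profile clustering (promoter +
  terminator, 1.5 kb each) with enrichment and co-expression permutation
  tests; SNP gain/loss prediction with a 30-control in-silico mutation
  null and the |Δp| > 0.2 shift filter; footprint-peak annotation and
  condition-response classification with permutation importance.
* **Synthetic test bed** — a fully specified generator (multi-chromosome
  genome, planted family motifs with a shared G-box-like core, long-tailed
  abundances, co-occurrence rules, gene models, SNPs, condition peaks)
  with a complete ground-truth registry, so the whole pipeline is testable
  end to end without downloads.

## Worked example

Generate the default synthetic bundle, train one chromosome-held-out fold
of the reference model, and look at what it learned:

```r
library(tfbinder)

bundle <- synthetic_bundle(seed = 7)          # 5 x 200 kb, 8 families
fold <- prepare_fold(bundle$genome, bundle$peak_sets, val_chrom = "chr1",
                     train_step = 75)         # offset training windows
model <- train_fold(fold, model_config(n_outputs = 8, max_epochs = 15,
                                       seed = 101))

pred <- predict_probabilities(model, fold$val$seqs)
compute_pr_roc(pred$probabilities, fold$val$labels$values)
#> metrics_report [genome]: macro auPR 0.659, weighted auPR 0.878, macro auROC 0.849

per_class_scores(pred$calls, fold$val$labels$values)[, c("family", "support", "mcc")]
#>     family support   mcc
#>      GboxA     244 0.917
#>      GboxB     154 0.873
#>      GboxC      76 0.729
#>   WRKYlike      55 0.576
#>    AP2like      59 0.868
#>    MYBlike      19 0.000
#>    HSFlike       8 0.000
#>    TCPlike      59 0.721
```

The abundant families are learned well; the two rarest (under ~100
planted sites) are not — per-family performance tracks abundance, which
is the imbalance phenomenon the family-level formulation is built to
study, and which class-weighted training (`use_class_weights = TRUE`)
rescues at a small overall cost. Recover the planted G-box motif from
the trained model:

```r
ipms <- discover_ipms(model, fold$train$seqs[1:4000],
                      fold$train$labels$values[1:4000, ],
                      "GboxA", max_windows = 300)
ipms[[1]]
#> ipm [GboxA]: width 15, support 370, consensus ACGTGTTCAATGTCC
motif_similarity(ipms[[1]]$pwm, bundle$truth$library$GboxA$pwm)
#> [1] 0.999
```

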