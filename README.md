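# mendelscan

Predicting which CRISPR double-strand breaks heal into a *single,
predictable allele*.

## The problem

Most nuclease-induced double-strand breaks (DSBs) are repaired by
non-homologous end joining, which scatters the outcome over many different
indels — a serious obstacle when you need a reproducible genotype (F0
screens, knockout panels, somatic gene therapy). Microhomology-mediated end
joining (MMEJ) is different: when two short exact repeats (microhomologies,
μH) flank the break, repair can collapse them into one copy, deleting the
intervening sequence and producing the *same* allele again and again. A cut
site whose most frequent repair outcome is such an MMEJ deletion at ≥ 50%
of the read pool is a **PreMA** (predominant MMEJ allele) reagent.

`mendelscan` is a toolkit for finding and evaluating PreMA reagents:

* **Microhomology engine** — enumerate every cut-spanning arm pair
  (λ ≥ 3 nt), score each candidate deletion with the Bae-style pattern
  score

  π = 100 · round(exp(−Δ/20), 3) · (λ + GC),

  where Δ = λ + ∂ is the deletion length, ∂ the gap between the arms, and
  GC the number of G/C arm bases (weighted 2 vs 1). Site-level competition
  is summarised by the **MENTHU score** π_max / π_max−1; a site is called
  PreMA when the score is ≥ 1.50 *and* the top pattern's ∂ is ≤ 5 bp
  (both inclusive; ∂ presets 3/4/5/6 are exposed).
* **Nuclease scanning** — SpCas9 (NGG, blunt cut 3 bp 5′ of the PAM) and
  Cas12a (TTTV, nominal cut 18 nt 3′ of the PAM) on both strands, with
  fixed-width context windows (52 or 60 nt) centred on the cut.
* **Ground-truth labelling** — consolidate repair-read pools, align the top
  read to WT (match +1 / mismatch −50; only single simple indels are
  included), classify it (MMEJ vs non-MMEJ deletion by ≥ 3 nt junction
  microhomology; 1 bp vs longer insertion) and call single-majority
  outcomes at the inclusive 50% threshold.
* **MENdel** — combine the deletion-based PreMA call with a pluggable 1 bp
  insertion predictor (adapter contract; deterministic mock included) into
  a single-majority *frameshift* call.
* **Evaluation** — confusion metrics, threshold-sweep ROC curves (including
  the truncated sweep that arises when the ∂ filter is held fixed), AND/OR
  predictor combination, stratified splits, and the two-feature baselines
  *Moon Rover* (logistic regression) and *Moon Walker* (gradient boosting
  with 10-fold CV grid search).
* **Gene screening** — scan the first 30% of a CDS (≥ 182 bp) for early
  frameshift-inducing single-majority sites.
* **Synthetic data** — seeded generators of planted-μH windows and
  simulated read pools with analytically known labels, so the whole
  pipeline is testable without any downloads.

All coordinates are 0-based and half-open; a cut index is the number of
bases 5′ of the break.

## Worked example

```r
library(mendelscan)

menthu("AAGCATTTGCATCC", cut_index = 7)
#> MENTHU site summary (cut at 7, 0-based)
#>   candidate MMEJ patterns: 1
#>   top pattern: arm GCAT  lam=4  dist=2  del_len=6  pi=444.6
#>   MENTHU score: Inf  (thresholds: score >= 1.50, dist <= 5)
#>   PreMA: TRUE   top frameshift: FALSE
```

The `GCAT` arms (λ = 4) flanking the break collapse into one copy, deleting
Δ = 6 nt (`AAGCATTTGCATCC → AAGCATCC`). No competing arm pair spans this
cut, so the score ratio is infinite and the site is a PreMA; the 6-nt
deletion is in frame, so it is not a frameshift reagent.

Evaluating the classifier on a simulated corpus with known truth:

```r
co    <- simulate_eval_corpus(200, prema_prevalence = 0.104, seed = 42)
preds <- vapply(co$events, function(e)
  menthu(extract_context(e$wt, 30, 52), 26)$is_prema, logical(1))
confusion_metrics(co$truth$is_prema, unname(preds))
#> Confusion metrics
#>   TP 7  FP 9  TN 169  FN 15
#>   sensitivity: 31.8%   specificity: 94.9%   PPV: 43.8%
```

A thin CLI wraps the same functions:

```sh
inst/exec/mendelscan score --seq AAGCATTTGCATCC --cut 7
inst/exec/mendelscan sites --fasta genes.fa --nuclease spcas9
inst/exec/mendelscan classify --events events.tsv
inst/exec/mendelscan simulate --n 500 --seed 3 --out corpus/
inst/exec/mendelscan screen --fasta cds.fa --nucleases spcas9,cas12a
```

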