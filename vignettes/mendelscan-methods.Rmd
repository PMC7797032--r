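---
title: "Predicting predominant MMEJ alleles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting predominant MMEJ alleles: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelscan)
```

## The model

After a nuclease-induced double-strand break (DSB), microhomology-mediated
end joining (MMEJ) can anneal a pair of short exact repeats — microhomology
arms — that flank the break, one arm ending at or 5′ of the cut and the
other starting at or 3′ of it. Repair collapses the two copies into one,
deleting one arm plus everything between them. For an arm pair with arm
length $\lambda$ and $\partial$ intervening bases, the deletion length is
$\Delta = \lambda + \partial$ and the deletion product is fully determined
by the arm positions. Because the same product can arise from nested or
slid arm pairs, `enumerate_mh_patterns()` deduplicates by product and keeps
the maximal-$\lambda$ representative.

Each candidate deletion is weighted by the Bae-style pattern score

$$\pi = 100 \cdot \mathrm{round}(e^{-\Delta/20}, 3) \cdot (\lambda + GC),$$

where $GC$ counts G/C arm bases — i.e. A/T bases weigh 1 and G/C bases 2 —
and the exponential term (decay constant 20 nt) penalises long deletions.
The 3-decimal rounding of the length factor *before* multiplication is
retained deliberately: it reproduces the arithmetic of the original
published scoring code, and scores like 444.6 for a GC-balanced 4-mer arm
with $\Delta = 6$ are exact under it.

The site-level statistic is the **MENTHU score**, the ratio of the two
largest pattern scores $\pi_{max}/\pi_{max-1}$. It measures *competition*:
when one arm pair is much stronger than every alternative, repair outcomes
concentrate on a single allele. A site is classified as a **PreMA**
(predominant MMEJ allele) reagent when

* MENTHU score $\ge$ 1.50, and
* the top pattern's $\partial \le$ 5 bp,

both comparisons inclusive. The distance threshold is exposed as presets
3/4/5/6 ("@3" … "@6"); tightening it trades sensitivity for precision
monotonically, which the test suite asserts as an invariant.

### Conventions and edge cases

* Coordinates are 0-based, half-open; `cut_index` is the number of bases 5′
  of the break.
* Arms may abut the break but must lie entirely on opposite sides of it
  (left arm end $\le$ cut $\le$ right arm start). This is the
  biologically motivated form of "the deletion spans the break" and is
  placement-invariant.
* A site with a *single* candidate pattern has no competitor; its score is
  defined as $+\infty$ (no competition = maximal confidence) and the PreMA
  call then rests on $\partial$ alone. For model fitting, infinite scores
  are capped at a large finite constant (default `1e6`).
* Ties in $\pi$ are broken by smaller $\partial$, then smaller
  `left_start`, making the ranking fully deterministic.
* Enumeration searches the entire supplied window; no cap on $\partial$ or
  $\Delta$ is imposed beyond the window itself.
* A note on one derived constant: the three-pattern example ratio
  444.6/258.3 equals 1.72125…, i.e. 1.7213 at 4 decimals; tests compare
  against the exact ratio.

## Nuclease scanning

SpCas9 recognises NGG and cuts bluntly 3 bp 5′ of the PAM:
`cut = pam_start − 3` on the plus strand, and a minus-strand PAM (CCN on
the plus strand at $q$) maps to `cut = q + 6`. Cas12a recognises TTTV
(V ∈ {A, C, G}); its cut is staggered 18/23 nt 3′ of the PAM, which we
collapse to a single nominal blunt break 18 nt past the 4-nt PAM
(`cas12a_offset`, configurable). Minus-strand scanning is implemented by
scanning the reverse complement and reflecting coordinates, so the
plus/minus symmetry invariant holds by construction. Context windows are
even-width and centred on the cut (52 nt for deletion scoring, 60 nt for
insertion predictors); sites whose window would cross a sequence end are
skipped, not truncated.

## Ground-truth labelling of repair pools

Observed repair reads for one event are pooled, consolidated by sequence
and ranked by count (lexicographic tie-break). The most frequent read is
aligned globally to the WT sequence with match +1, mismatch −50 and gap
opening/extension 10/4 — the mismatch penalty effectively forbids
substitutions, and the gap penalties are the alignment function's defaults
since only the substitution scheme is prescribed. An event is *included*
only when the optimal alignment is exactly one contiguous gap in one
sequence with zero mismatches (a single simple indel). One subtlety:
terminal gaps are not reported in the aligner's indel ranges, so the
single-gap certificate is completed by an exact prefix/suffix criterion
that is mathematically equivalent for interior and terminal indels alike.

Indel placement is canonicalised leftmost. Deletions are classified MMEJ
when the junction carries $\ge$ 3 nt of exact microhomology — the largest
$k$ such that, over all equivalent placements, the deleted segment shares a
$k$-prefix with the retained downstream flank or a $k$-suffix with the
retained upstream flank; this quantity is placement-invariant, so the MMEJ
call does not depend on the leftmost convention. Single-majority calls
(PreMA for MMEJ deletions, single-majority insertion for 1 bp insertions)
require the top read to hold at least 50% of the pool, inclusively. The
frequency denominator is the full consolidated pool of the event;
processed profiles normally contain no WT-identical reads, and when one is
present it simply competes in the denominator (documented behaviour, see
Limitations). A `genomic` curation flag lets callers exclude events
targeting artificial constructs; it is input curation, not sequence
computation.

## MENdel: adding insertion-based frameshifts

MENTHU ranks deletions; it does not predict insertions. External
per-outcome predictors are consumed through an adapter contract — a
function from a 60-nt window (break after position 30) to an
`outcome_distribution` (probabilities summing to 1 within $10^{-6}$,
renormalised). Two distribution-based rules mirror the threshold
classifier: a *PreMA* when the top outcome has probability $\ge$ 0.50 and
is a deletion with junction microhomology $\ge$ 3; a *single-majority
insertion* when the top outcome is a 1 bp insertion with probability
$\ge$ 0.50. Any 1 bp insertion is out of frame, so the inserted base is
irrelevant to the frameshift call. `mendel_predict()` combines the two
routes:

$$\text{frameshift} = (\text{PreMA} \wedge \Delta \bmod 3 \ne 0) \vee
  \text{single-majority 1 bp insertion}.$$

With a null adapter (insertion probability always 0), MENdel reduces
exactly to MENTHU frameshift-PreMA calls — asserted as a test invariant,
alongside monotonicity of the call in the adapter probability. A trained
insertion predictor is external to this package and plugs in through the
same contract (file-based adapters are supported via TSV/JSON); tests use
the deterministic mock. The empirical distribution of an observed pool
(`empirical_outcome_distribution()`) doubles as a perfect-information
adapter on simulated data.

## Evaluation machinery

`confusion_metrics()` reports integer counts and sensitivity TP/(TP+FN),
specificity TN/(TN+FP) and PPV TP/(TP+FP), with 0/0 reported as undefined
(`NA`) rather than 0. `roc_sweep()` sweeps the classification threshold
over every distinct score plus the limit thresholds. In the MENTHU mode the
arm-distance filter stays fixed while the score threshold runs from
$\infty$ to 0; positives whose top $\partial$ exceeds the filter can never
be recovered, so the curve is *truncated* at a maximum attainable
sensitivity below 1. The reported AUC is the trapezoid over the attainable
points only, anchored at (0,0) and **not** extrapolated to (1,1): for a
heavily truncated curve this area is necessarily small and is not
comparable to a full-curve AUC — it is reported together with
`max_sensitivity` and a `truncated` flag for that reason. On random
60-nt windows only ~20% of sites have a top-pattern $\partial \le 5$, so
truncation is severe by construction.

Stratified splitting rounds per-class sizes to the training fraction
(default 0.7, which maps 614/5271 labelled events onto a 4120/1765 split)
and is deterministic given a seed. The two baselines use exactly the two
features of the rule-based classifier: *Moon Rover* is a plain logistic
regression; *Moon Walker* is a gradient-boosted tree model whose
hyperparameters — number of trees, maximum depth, minimum observations per
node, shrinkage — are selected by 10-fold cross-validated AUC over a grid
(ties broken in grid order, trees varying fastest). The default grid
{50,150,300,450,600} × {2,4,6} × {5,10,20} × {0.01,0.1} spans the region
where such models typically land, including 450/6/10/0.01. The boosting
backend is xgboost; its `min_child_weight` plays the minimum-observations
role (for logistic loss the per-observation Hessian is at most 1/4, so the
correspondence is approximate but monotone).

## Gene screening

For a CDS of length $L$, cut positions within the first
$\max(\mathrm{round}(0.30\,L),\ 182)$ bp are screened (182 = 150 bp of
gene plus 32 bp of upstream prediction context guarantees every gene
contributes at least 150 bp). Guide sites come from both strands; each
site is scored on its centred window (52 nt, or 60 when an insertion
adapter makes it a full MENdel call), and sites within 30 nt of the 3′ end
or lacking a full window are skipped and counted. Frameshift status uses
the top-ranked pattern only, consistent with single-majority logic. CDS
shorter than 212 nt are reported unscreenable rather than raising errors.
Adding Cas12a to the nuclease set can only add sites — a superset property
asserted in the tests.

## Synthetic data: what it emulates, and what it does not

Two generators provide labelled data at desk scale; their defaults are the
package's study conditions and all sampling is seed-deterministic.

**Planted corpus** (`plant_mh_sequence()`, `simulate_corpus()`,
`write_corpus()`). Each 60-nt WT window (cut at 30) carries *exactly one*
cut-spanning microhomology family with requested $\lambda$, $\partial$ and
arm GC. Uniqueness cannot be achieved by naive rejection — a uniform
random 60-mer contains about a dozen chance cut-spanning 3-mer repeat
pairs in expectation — so backgrounds are built base by base under a
forbidden-3-mer constraint (no 3-mer occurs on both sides of the cut
except within the planted arms; single-base arm extensions are blocked so
$\lambda$ is exact), with bounded restarts. Read pools are multinomial
draws (1000 reads) over the planted MMEJ product, non-MMEJ deletions with
junction homology < 3 enforced by resampling, and 1 bp (rarely longer)
insertions. The top-read category mix is 54% non-MMEJ deletion / 31% MMEJ
deletion / 14% 1 bp insertion / 0.2% longer insertion, with a PreMA
prevalence of 0.104 carved out of the MMEJ share; majority tops draw their
frequency from U(0.55, 0.85) and sub-majority tops from U(0.30, 0.48);
planted $\lambda \in 3..8$ (decaying) and $\partial \in 0..10$, with PreMA
events favouring short distances. Truth labels are computed from the
*realised* counts plus the generator's knowledge of each read's category,
so pipeline recovery can be checked read-for-read — the agreement test is
about the labelling code, not sampling noise.

**Evaluation corpus** (`simulate_eval_corpus()`). The uniqueness constraint
above deletes the very signal a competition classifier uses: with one
pattern per window, every score ratio is infinite, and score-based
evaluation degenerates. The evaluation corpus therefore uses plain random
windows (full natural competition) and emulates the competition hypothesis
mechanistically: for MMEJ-top events the top-read frequency follows a
logistic-type link, increasing in $\log(\min(\text{score}, 20))$ and
decreasing in $\partial$ (slope 0.3, noise SD 0.7), with the intercept set
by a quantile so the majority share matches the requested prevalence.
Classifier metrics measured on this corpus reflect that *planted*
association — they demonstrate the pipeline end to end, not repair
biology, and their numerical values are properties of these study
conditions.

Neither generator models sequencing error, chimeric reads, replicate
structure, substitution-containing reads, or WT contamination; passing
tests therefore say nothing about robustness to those features of real
amplicon data.

## Problem sizes and numerical choices

The shipped checks use: 200 random 50–80-nt sequences for the brute-force
enumeration oracle; a 1000-event planted corpus for label recovery; a
1000-event evaluation corpus for classifier metrics; 2000 windows for the
rule-truth baseline corpus with a 70/30 split and a reduced walker grid
({150,450} × {2,6} × {10} × {0.01,0.1}, which brackets the default grid's
selected region); and 20 synthetic 900-nt genes for the screen. These
sizes give stable estimates on a single CPU. Probability normalisation
tolerance is $10^{-6}$; profile fractions must sum to 1 within $10^{-9}$;
AUC is exact trapezoid arithmetic (cross-checked against an independent
ROC implementation in the tests).

## Known limitations

* The figshare-style profile importer assumes a plausible column layout
  (`target_id`/`sequence`/`reads` plus `target_id`/`wt_sequence`/`cut_site`);
  public archives of processed profiles ship no formal schema, so it is
  best-effort and isolated from the core pipeline.
* Whether single-majority frequency should be computed over mutant reads
  only when WT reads are present is left to the caller's curation; the
  package uses the full consolidated pool.
* MENTHU-style ranking does not output per-outcome probabilities; only the
  adapter route provides them.
* The Cas12a cut offset is a convention (midpoint of the stagger), not a
  measured quantity; it is configurable.
* Splice-site targeting and combined-allele frameshift estimation across
  the whole outcome distribution are out of scope.
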