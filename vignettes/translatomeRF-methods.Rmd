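---
title: "Models and methods behind translatomeRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind translatomeRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Polysome profiling separates a cell's mRNA pool into fractions by ribosome
load: `total` RNA, mRNAs carrying a single 80S ribosome (`monosome`) and
mRNAs carrying several (`polysome`). Comparing the polysome:monosome ratio
between a control and a stress condition asks, per gene, whether stress
moved the transcript between the actively translated and the poorly
translated pool — a *translational* response, distinct from a change in
transcript abundance. translatomeRF implements the downstream computational
analysis for such an experiment in budding yeast under oxidative stress:
it calls per-gene translation states, asks which mRNA *sequence* features
predict the translational response using a random forest, and tests whether
known RNA-binding-protein (RBP) target sets — Puf3p above all — co-associate
with the responding classes.

# Translation-state model

For gene $g$ and condition $c$, the translation state is

$$\mathrm{ts}_{g,c} = \overline{\log_2 P_{g,c}} - \overline{\log_2 M_{g,c}},$$

the difference of replicate means of log2 polysome and monosome
intensities (equivalently, the log2 ratio of geometric means). The change
in translation state is $\Delta_g = \mathrm{ts}_{g,\mathrm{stress}} -
\mathrm{ts}_{g,\mathrm{control}}$, the log2 of the ratio of the two
ratios. We deliberately implement the *difference* of the two log-ratios:
a literal quotient of two log-ratios would not correspond to a fold change
of absolute ratios and behaves pathologically near zero. $|\Delta| > 1$
then means a 2-fold change of the absolute polysome:monosome ratio.

Significance comes from a per-gene two-factor linear model
`log2 intensity ~ condition * fraction` over the monosome and polysome
arrays; the condition-by-fraction interaction coefficient *is* $\Delta$,
and its F-test asks whether the fraction contrast shifts under stress.
Because designs in this field have very few replicates, the residual
variance can optionally be moderated: each gene's $s^2_g$ is shrunk toward
the across-gene mean $s^2_0$ with `prior_df` ($d_0$, default 4)
pseudo-observations,

$$\tilde s^2_g = \frac{d_0 s^2_0 + d\, s^2_g}{d_0 + d},$$

and the moderated statistic is referred to $F(1, d + d_0)$. This is a
deliberately closed-form, testable variant of empirical-Bayes moderation:
the prior degrees of freedom are fixed rather than estimated, which keeps
the null distribution exact in tests while preserving the qualitative
benefit (small-replicate variances stop exploding). With `moderation =
FALSE` the test is the textbook two-way ANOVA interaction F-test, and the
test suite verifies both its exactness against `lm()`/`anova()` and its
type-I calibration on 10 000 simulated null genes.

A transcript is called `up` when $\Delta > \tau$ (strict) and the
Benjamini–Hochberg adjusted interaction p-value is $\le \alpha$, `down`
symmetrically, otherwise `unchanged`; defaults $\tau = 1.0$, $\alpha =
0.01$. The adjustment method for the interaction p-values is
Benjamini–Hochberg, chosen to match the multiple-testing treatment used in
the enrichment stage. "Unchanged" is defined as the complement of
up ∪ down; no buffer zone around the threshold is carved out.

# The 77-feature vector

Each transcript is split into 5′UTR, ORF and 3′UTR from a region-length
table (transcripts without a measured 5′ or 3′ UTR are excluded by
default, mirroring the upstream exclusion practice). The default schema
has exactly 77 features:

| block | count |
|---|---|
| region lengths (nt) | 3 |
| base composition %A/%C/%G/%U per region | 12 |
| GC fraction in 30 nt before / after the start codon | 2 |
| folding-energy proxy per region | 3 |
| CAI, fop, tAI, AUG-CAI(r) | 4 |
| amino-acid composition of the translated ORF | 20 |
| upstream AUG count, uORF presence, 5′UTR stop presence | 3 |
| transcript level (control), transcript level (stress) | 2 |
| RBP motif sites (panel-defined) | 28 |

The 28 motif features are defined entirely by the bundled motif panel
(`inst/extdata/motif_panel_default.tsv`), one feature per (motif, region)
entry; replacing the panel file changes the schema accordingly. The panel
is a *reconstruction* of a yeast RBP binding-site collection — plausible
consensus elements for PUF-family proteins and other well-known yeast
RBPs — with one deliberate anchor: `Puf3_3utr` carries the canonical Puf3p
element `CYUGUAAAUA`. Motif scanning is IUPAC-consensus window matching on
the forward strand, counting overlapping matches.

Choices inside the blocks:

* **CAI** uses relative synonymous codon usage of a reference ORF set
  (weight = usage / max usage within the family, 0.5 pseudocount), with the
  geometric mean taken over codons excluding stops and the single-codon
  families AUG and UGG. The default reference set is the top decile of
  input transcripts by control transcript level — a self-contained stand-in
  for "highly expressed genes" that requires no external annotation.
* **fop** counts weight-1 codons among codons with a synonymous choice.
* **tAI** weights each codon by discounted tRNA availability: the
  Watson–Crick anticodon plus the wobble anticodon, discounted by the
  standard pairing penalties (G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68);
  weights are scaled to max 1 and unreadable codons imputed with the
  geometric mean of the rest. The bundled yeast tRNA gene copy numbers are
  an approximate reconstruction (the file says so in its name); analyses
  that depend on exact tAI values should supply measured copy numbers.
  All tests of tAI use toy tables with hand-computed expectations, so no
  result asserted anywhere depends on the reconstruction.
* **AUG-CAI(r)** scores the −6..+3 start context as the geometric mean of
  positional frequency ratios $f(b_i, i) / f_{\max}(i)$ under a positional
  table built from the same reference decile.
* **Folding energy** is a deterministic proxy, not a thermodynamic
  prediction: a maximum base-pairing dynamic program (Watson–Crick + GU,
  minimum hairpin loop 3) scored with +1 per pair and +1 per stacked pair,
  reported negated. It is computed on the leading 100 nt of each region —
  local structure near region boundaries is what the start-proximal
  features care about, and the cap keeps cost linear in transcript count.
  Bit-exact reproducibility in tests is the reason the proxy, rather than
  an external folding engine, is the default; `foldEnergy()` accepts whole
  sequences (`window = Inf`) when fidelity matters more.

Missing values (e.g. transcripts absent from the expression table) are
imputed with the per-feature median and recorded in the `imputed` slot; no
missingness indicator columns are added, so the feature count stays fixed
at 77.

# Random-forest protocol

Classification is one-vs-rest per response class: `down` vs everything
else, and `up` vs everything else. The forest learner is the standard
`randomForest` implementation; this package owns the protocol around it:

* **Tuning**: grid search over `ntree` ∈ {250, 500, 1000} and `mtry` ∈
  {⌊√p/2⌋, ⌊√p⌋, ⌊2√p⌋}, selecting the lowest out-of-bag (OOB) error;
  ties break toward smaller `ntree`, then smaller `mtry`.
* **Class weighting**: "balanced" = inverse class frequency. A weighting
  equal to class prevalence would be a no-op, so the inverse reading is
  the only one that can matter; it protects the small up/down classes
  against the unchanged majority.
* **Evaluation**: the OOB confusion matrix (TP/FP/TN/FN) from the tuned
  forest, and a ROC curve from 10-fold class-stratified cross-validation
  with out-of-fold vote fractions pooled over folds. AUC is the trapezoid
  area, which the tests pin to brute-force concordant-pair counting.
* **Importance**: mean Gini decrease and permutation importance from the
  fitted forest, plus an effect sign per feature — the sign of the
  rank-biserial correlation (2·AUC−1) between the feature and the positive
  class. Rank-biserial rather than Pearson because motif counts and
  similar features are heavy-tailed.
* **Determinism**: every stochastic step (bootstraps, folds, permutations)
  derives from the single seed in `forestConfig()`; reruns are
  byte-identical.

# Enrichment statistics

Set co-association uses the hypergeometric distribution over a declared
universe. The universe defaults to the transcripts that entered
classification (post-exclusion) — a conservative choice; using the whole
genome would only inflate significance. Over-representation is the upper
tail $P(X \ge k)$; under-representation is reported with its own lower
tail, not as $1 - p$. BH correction is applied across all cells of a
co-association matrix, and across terms within a term-enrichment query.
Enrichment heatmap ordering uses UPGMA (average-linkage) clustering on
Euclidean distances of $-\log_{10} q$ matrices.

# The synthetic benchmark

The generator plants a fully known signal so every stage can be scored:

* 3000 transcripts; UTR lengths log-normal (medians ≈70 nt for 5′UTRs,
  ≈120 nt for 3′UTRs, yeast-like); ORF lengths log-normal with median
  ≈350 codons. UTRs are i.i.d. uniform over ACGU — a known simplification
  (no compositional or Markov structure), so composition features carry
  no class signal, which is the point: the planted motif and expression
  effects must do the work.
* ORFs choose each amino acid's optimal codon with a per-gene tier
  probability (0.25/0.5/0.85), spreading CAI, fop and tAI realistically.
* A regulon of 400 genes receives the Puf3 element in its 3′UTR at rate
  0.9 (background 0.05); chance background matches are recorded in the
  ground truth rather than removed, so specificity tests stay honest.
* Expression: per-gene baseline N(8, 1), fraction and condition offsets, a
  per-gene transcriptional stress shift in the total fraction (SD 0.5, to
  exercise the transcript-level features), and the planted interaction
  `delta = −2` confined to the stress × polysome cell — exactly the
  contrast the ANOVA tests. Noise SD 0.25, 3 replicates per cell.
* Gene sets: a Puf3-like target set sharing 70% of its members with the
  regulon, 8 uniform decoy RBP sets, and a flat term annotation whose
  first term is regulon-enriched.

What passing these tests does and does not show: recovery of a planted
regulon under i.i.d. backgrounds with Gaussian noise demonstrates the
pipeline's statistical machinery, determinism and wiring; it does not
certify performance on real arrays, where probe effects, correlated noise
and compositional structure are present. The benchmark sizes (3000 genes,
10 seeded replicates for the importance-stability check, 10 000 null genes
for calibration) were chosen as the smallest runs at which the binomial
noise of the checked proportions is comfortably below the tested margins.

For the 10-seed importance-stability check the forest is fit at fixed
`ntree = 500`, `mtry = ⌊√77⌋ = 8` rather than re-tuning the full grid in
every replicate: tuning selects among configurations whose importance
rankings agree, and a fixed configuration makes the replicates
commensurable.

# Numerical and degenerate-input conventions

* Hypergeometric tails are evaluated in log space via `phyper(log.p =
  TRUE)`; q-values are floored at 1e-300 before `-log10` for clustering.
* Composition denominators exclude N bases; empty regions yield zero
  fractions and zero lengths and are flagged.
* Sequences shorter than a motif score 0 (count mode) or the documented
  floor −1e6 (log-odds mode); regions under 8 nt get folding energy 0.
* Region tables are transcript-local lengths (0-based half-open joins),
  never genomic coordinates, eliminating strand ambiguity.
* Ties in UPGMA merges and in forest tuning break deterministically by
  input order / smaller parameter.
* The ORF grammar (starts AUG, ends with one stop, no internal stop,
  length divisible by 3) is enforced at assembly; violators are dropped
  with a warning (or raise an error, per policy).

# Known limitations

* The folding proxy ranks structured vs unstructured sequences but its
  pseudo-energies are not kcal/mol; plug an external folder into
  `foldEnergy()`-style scores for thermodynamic work.
* The bundled tRNA copy numbers and motif panel are labelled
  reconstructions; swap in measured tables for production analyses.
* The moderation uses a fixed prior df rather than estimating it from the
  data; with many genes the difference is small, and `moderation = FALSE`
  recovers the exact classical test.
* One UTR isoform per transcript: when an atlas offers several, the caller
  chooses the row to supply.
* The expression model is additive Gaussian on the log2 scale with
  i.i.d. noise; dye biases, probe effects and mRNA-decay dynamics are out
  of scope.
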