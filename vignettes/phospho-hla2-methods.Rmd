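---
title: "Methods: discovering and predicting phosphorylated HLA-II ligands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and predicting phosphorylated HLA-II ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoHLA2)
```

## The problem

Class II human leukocyte antigen (HLA-II) molecules present peptides of
roughly 12–25 residues to CD4+ T cells. Each ligand binds through a 9-mer
core (positions P1–P9, with primary anchors at P1/P9 and secondary anchors
at P4/P6) while its flanking regions (PFRs) extend out of the groove.
Mass-spectrometry immunopeptidomics recovers these ligands in bulk, and a
fraction of them carry phosphorylated serine, threonine or tyrosine
(pS/pT/pY). phosphoHLA2 implements the full computational path from a raw
MS identification table to a phospho-aware binding predictor:

1. **PSM curation** — parse MaxQuant-style `msms.txt` tables and keep
   peptide-spectrum matches with identification score ≥ 40, delta score
   ≥ 10, every phosphosite localization probability > 0.75, and length
   12–25.
2. **Allele assignment** — score each phosphopeptide against the allele
   models of its sample and keep alleles with percent rank ≤ 10;
   unassignable peptides are treated as co-eluted contaminants or wrong
   identifications, and the Kolmogorov–Smirnov separation of their score
   distributions is the QC readout.
3. **Motifs and positional statistics** — phospho binding motifs per
   allele, their Euclidean distance to unmodified motifs (intra- versus
   inter-allele, one-sided rank-sum test), core-versus-PFR and per-core-
   position phosphosite distributions, and kinase-motif enrichment with a
   source-gene bias control.
4. **Benchmark** — leave-one-sample-out cross-validation of the
   phospho-aware predictor against phosphosite-pool negatives, with AUC,
   MCC and F1 metrics and paired signed-rank comparisons between
   predictor arms.

## The model

The predictor is a single position weight matrix (PWM) per allele over a
**23-letter alphabet** — the 20 amino acids plus pS, pT and pY — with
max-over-offsets log-odds scoring. For a peptide with symbol sequence
$a_1 \ldots a_L$ the raw score is

$$S = \max_{o}\ \sum_{p=1}^{9} \log_2
  \frac{W_{p}(a_{o+p-1})}{B(a_{o+p-1})},$$

where $W_p$ is the PWM column at core position $p$ and $B$ the background
frequency vector. The maximizing offset defines the binding core; ties go
to the smallest offset. This is deliberately the *minimal* scorer
consistent with every analysis in the package (core prediction, motif
construction, percent-rank thresholds). Offset priors, flanking-region
terms and multiple binding specificities per allele are natural extension
points but are not modelled.

**Training.** Column frequencies use background-proportional pseudocounts,
$W_p(a) = (n_p(a) + \lambda B(a)) / (n + \lambda)$ with $\lambda = 5$ by
default — enough to keep the rare phospho symbols strictly positive
without drowning the counts. Display motifs (`build_motif()`) use
$\lambda = 0$ so that logos reflect observed residues only.

**Background.** Canonical frequencies are counted from the supplied
proteome. Background frequencies of phosphorylated residues cannot be
estimated from sequence alone; each phospho symbol therefore receives its
parent residue's frequency times an explicit, configurable phospho prior
(default 0.01), after which the 23-vector is renormalized. This choice is
deliberately exposed as a parameter because motif estimates are sensitive
to it.

**Percent rank.** Raw scores are calibrated per peptide length (12–25)
against `n_per_length` random proteome subsequences (default 10,000,
which stabilizes percent ranks to about 0.1; tests and the acceptance
script use 500–2,000 for speed at correspondingly coarser resolution).
The percent rank of a score $s$ for length $L$ is
$100\,(1 + \#\{\text{calibration scores} \ge s\}) / (N + 1)$ — strictly
decreasing in $s$, bounded away from 0 and 100, and lower-is-better. Two
thresholds matter downstream: **10%** for assigning a peptide to an
allele during discovery, **5%** for calling binders when computing MCC
and F1 in the benchmark.

**Two scoring modes.** Discovery historically predates phospho-aware
models, so assignment defaults to `substitute_E` mode: phosphosites are
replaced by glutamate (mimicking the phosphate's negative charge) and the
20-letter sequence is scored against models trained on unmodified
ligands. The benchmark defaults to `native23` mode, where cores keep
their phospho symbols in both training and scoring. The leave-one-sample-
out harness runs both arms so the value of phospho-aware training is
measured on the same folds.

## Conventions and numerical choices

* **Coordinates are 1-based and closed everywhere**, following base-R
  convention; binding-core positions are reported with the field's P1–P9
  labels. (A 0-based internal convention buys nothing in R and invites
  off-by-one errors at every `substr()`.)
* A peptide's identity is its sequence *plus* its phosphosite set
  (`peptide_key()`); the same sequence with different localizations is a
  different ligand, because localization is the object of study.
* Non-phospho variable modifications (Met oxidation, N-terminal
  acetylation) are parsed and ignored downstream.
* The percent-rank assignment cutoff is **inclusive** (≤ 10); declared
  and tested.
* Peptides mapping to several proteins take the lexicographically
  smallest protein identifier for context extension (deterministic);
  out-of-protein context positions are padded with a sentinel `-` that
  matches no motif position and no PWM row, so protein termini can never
  produce spurious kinase-motif hits.
* Equal-scoring cores break ties toward the smallest offset; scores are
  log base 2 (bits).
* Multiply phosphorylated peptides contribute each in-core phosphosite
  independently to the core-position distribution — the only convention
  under which the per-position denominator is well defined. Both
  site-level and peptide-level countings are reported for the terminal
  (N-/C-) statistics because the published split is ambiguous between
  them.
* Kinase motifs follow the bracket grammar (`[pS/pT]P`, `RXX[pS/pT]`);
  exactly one position (the anchor) holds phospho symbols. Denominators
  count sites whose residue type matches the anchor set — pS+pT sites for
  `[pS/pT]P` in the phospho stratum, unmodified S+T sites in the
  unmodified stratum. "Non-redundant" motif selection drops any motif
  whose phospho-stratum match set is a subset of a shorter retained
  motif's (off by default, testable).
* The inter-allele motif distance renormalizes only the phospho-side PWM
  onto the 20-letter alphabet (the unmodified side has no phospho mass by
  construction in zero-pseudocount display motifs).
* Fisher tests are one-sided toward enrichment in the phospho stratum;
  the source-gene overlap odds ratio applies the Haldane +0.5 correction
  only when a cell is zero, and flags it.
* The paired comparison of predictor arms uses a two-sided signed-rank
  test with zero differences dropped; for n ≤ 14 the null is enumerated
  exactly over all sign patterns (the classical exact distribution does
  not apply under tied magnitudes), otherwise `stats::wilcox.test` is
  used.
* AUC uses midranks, so ties between positive and negative scores count
  one half; MCC is reported as 0 with a flag when a confusion-matrix
  margin is zero.
* Degenerate inputs are flagged rather than silently handled: empty
  restricted motifs, positions with all mass on phospho symbols,
  all-identical distance sets (p = NA), all-zero metric differences
  (p = 1).

## The synthetic-data generator

`generate_world()` emits every input the pipeline consumes — proteome
FASTA, phosphosite catalogue, sample manifest, MaxQuant-dialect PSM
table — plus a ground-truth ledger of every peptide's allele, core offset
and phosphosites. Its defaults are the package's study conditions and are
set once:

* **Planted motifs**: each allele prefers one symbol at P1/P4/P6/P9 with
  frequency 0.9, background elsewhere. Real HLA-II pockets concentrate
  roughly this much mass on a small residue class; with a single
  preferred symbol per anchor, 0.9 is also what makes the generator
  self-consistent — ligands drawn from a planted motif must themselves
  score inside the top decile of the allele's percent-rank scale, which
  diffuse 0.7-anchors do not achieve.
* **Lengths** 12–25 peaked at 15 (discretized normal, sd 2), the shape of
  curated HLA-II peptidomes.
* **Phosphosites**: 85.4/13.3/1.3% mono/di/tri mixture; 60% of sites in
  the core with placement weights peaking at P5 and depleted at P1; PFR
  sites favor the C-terminal side 63/37; residue mixture S/T/Y =
  75/20/5%.
* **Scores**: true PSMs draw identification scores from N(120, 25) and
  delta scores from N(40, 15); contaminants (random proteome slices,
  25% of phospho PSMs by default) from N(70, 25) and N(12, 8), with
  poorly localized phosphosites (Beta(4, 2) versus Beta(40, 2)). This
  reproduces the qualitative assigned-versus-unassigned score separation
  without claiming any published distribution.
* **Proteome**: 500 proteins, geometric lengths with mean 450; every
  emitted peptide is embedded as an exact substring (placements never
  overlap, and contaminants are sliced only after all embeddings).
* `noiseless = TRUE` is the closure condition: no contaminants and
  score/localization distributions entirely above the curation
  thresholds, so end-to-end recovery of planted interactions measures
  the predictor, not the noise model.

What the generator does **not** emulate: real spectral noise and search-
engine score distributions, shared peptides between proteins, multiple
binding specificities per allele, length-dependent binding preferences,
protein-level abundance biases, and realistic kinase-motif structure
around phosphosites (motif enrichment worlds are built per test).
Passing tests therefore demonstrate correctness of the algorithms and
recoverability of planted structure at realistic scale — not performance
on real immunopeptidomes.

## Problem sizes

Module tests run on a 3-allele, 4-sample world (30 phospho + 60
unmodified ligands per sample, 200 proteins); the recovery checks use a
6-sample noiseless world (60 + 120 per sample, 400 proteins), 500-core
PWM recovery, 100-run enrichment simulations, and leave-one-sample-out
folds with 1,000–2,000 calibration peptides per length. These sizes give
stable statistics at desk scale; all of them are ordinary function
arguments if larger runs are wanted.

## Known limitations

* A single PWM per allele cannot represent alleles with several binding
  registers or strong flanking preferences.
* Percent-rank calibration draws unmodified proteome peptides; a query
  with many phospho symbols is ranked against a null that contains none.
  The effect is conservative (phospho log-odds are regularized toward the
  phospho prior) but real.
* `substitute_E` treats every phosphosite as a fixed negative charge;
  it cannot capture allele-specific accommodation of the phosphate
  group.
* The phosphosite catalogue is trusted as-is; no attempt is made to
  model catalogue incompleteness or cross-tissue variation in site
  usage.
* Under this minimal scorer the fold-level advantage of the `native23`
  arm over `substitute_E` is small even when phosphosites are planted at
  core anchors. The rare-background pS symbol earns a large log-odds
  bonus for true ligands, but a decoy phosphopeptide can usually slide
  its own phosphosite into the same anchor column at no cost (decoys
  carry no competing anchors), and percent-rank calibration on
  unmodified peptides shifts both classes alike — so rank-based metrics
  move little. Both arms are reported side by side so this can be
  inspected per fold; a scorer with offset priors or phospho-aware
  calibration nulls is the natural upgrade path.
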