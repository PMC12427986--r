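---
title: "Sequence-based CpG methylation classification: models, data and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based CpG methylation classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylUNet)
```

## The problem

Bisulfite experiments report, for each CpG site, a methylation percentage
β ∈ [0, 100]. methylUNet treats the binarized status (methylated when
β ≥ 50%, the threshold being inclusive at 50) as a label to be predicted
from the surrounding DNA sequence alone — no read-level data, no chromatin
marks. The interest is twofold: a practical imputation/screening tool, and
a probe of how much methylation state is encoded in local sequence.

## Data model and conventions

Genomes are read from FASTA into `DNAStringSet`s; residues are uppercased
and anything outside {A,C,G,T,N} becomes N (counted and reported).
Methylation tables are TSVs with columns `chrom`, `pos`, `beta_percent` in
either 0-based (`bed0`, the BED/RRBS track convention) or 1-based (`tsv1`)
coordinates; internally sites live in 1-based `GRanges`, so `bed0`
positions gain 1 on read and lose it on write.

For a site whose C sits at 1-based position *p*, the width-*W* window is
[*p* − *W*/2, *p* + *W*/2 − 1]: the C occupies 0-based offset *W*/2 and the
CG never straddles the edge. Published descriptions of "centered" windows
rarely pin down the basis or whether the anchor is the C, the G or the
midpoint; this convention was chosen once for determinism and is asserted
by the validity checks. Three choices deserve a note:

- **Boundary sites** are skipped with a logged reason rather than padded:
  padding would feed the encoders synthetic residues indistinguishable
  from data.
- **Strand**: all sites are taken as forward-strand Cs. An optional flag
  reverse-complements windows of minus-strand sites; note that after
  reverse complementation the G of the CpG, not the C, falls at the
  centering offset.
- **Subsampling** preserves the methylated:unmethylated ratio to within
  one site (stratified sampling under a fixed seed); how the original
  studies thinned their site lists is typically unstated, and a
  label-stratified draw is the simplest rule that keeps the label
  distribution of the subset representative.

The 70:20:10 train/test/validation split is a seeded shuffle followed by
contiguous slicing with floor sizes and the remainder going to validation,
which gives exactly 3500/1000/500 at n = 5000.

## Encodings

The monomer encoding maps each base to a 4-channel one-hot row in the
fixed order A, C, G, T. The dimer encoding maps each *overlapping*
dinucleotide to the concatenation of its two constituent one-hot vectors:
L − 1 rows of 8 channels, every unambiguous row summing to 2. The 8-channel
concatenation is canonical here because it is the reading that reproduces
both the published worked example (the 30-bp table checked bit-for-bit in
the test suite) and the n×299×8 tensor shape for 300-bp windows; the
alternative 16-way one-hot over dinucleotide identities is kept as the
optional `dimer16` scheme. Ambiguous content is represented by all-zero
rows (any dimer containing N is fully zeroed), so tensor shapes depend
only on the window; windows above a configurable N fraction (default 10%)
are dropped upstream instead.

## Architectures

All three classifiers are implemented natively (forward, backward, Adam)
— the convolution layers reduce to BLAS matrix products via im2col, which
is fast enough at these problem sizes that no compiled code or external
runtime is needed. The convolution primitive itself is the sliding dot
product F_i = Σ_m I_{i+m} K_m (cross-correlation orientation, no kernel
flip), exposed as `conv1d()` and tested against a brute-force double loop.

**UNet (1-D).** Encoder conv(16) → pool(÷4) → conv(32) → pool(÷4) →
conv(64); decoder tconv(×4, 64) + skip, tconv(×4, 32) + skip, conv(16);
head GAP → dense → softmax(2). Kernel size is 3 with length-preserving
padding, so only pooling and upsampling change the sequence length; each
convolution is followed by batch normalization and ReLU. The pooling
factor 4 is forced by the documented length ladders (⌊299/4⌋ = 74,
⌊74/4⌋ = 18, 18×4 = 72, 72×4 = 288). Because floor division loses
remainders, encoder maps are 1–11 positions longer than the upsampled
decoder maps (74 vs 72, 299 vs 288); they are center-cropped before
concatenation, which avoids padding artifacts at window edges at the cost
of ignoring a few edge positions in the skip path.

**CNN.** Three conv-BN-ReLU blocks (16, 32, 64 filters), each followed by
pool(÷4) where the remaining length permits, then the same GAP/softmax
head. It has roughly a fifth of the UNet's parameters.

**MobileNet-1D.** A 16-filter stem, then three inverted-residual blocks
(pointwise expansion ×4 → depthwise kernel-3 convolution → squeeze-and-
excitation gate with reduction 4 → linear pointwise bottleneck), strides
2, 2, 1, with the identity residual present exactly where stride is 1 and
channel counts match. The depth (three blocks) keeps the baseline
desk-scale; every structural constant is in the `ModelSpec`.

**Training.** Softmax cross-entropy, Adam with step size 1e-3, batch 32,
a fixed number of epochs (default 50) with no early stopping; the seed
fixes initialization and batch order, making runs bit-reproducible on one
platform. Class order is (unmethylated, methylated) and prediction ties go
to class 0 (unmethylated) — an arbitrary but documented tie-break.
Training curves are computed on the validation split; the test split is
touched only for final metrics.

## Evaluation conventions

Positive class is methylated throughout. SN, SP, ACC, MCC, precision and
F-1 follow their standard confusion-matrix definitions; any metric with a
zero denominator is reported as `NA` rather than 0 so degenerate
classifiers remain visible. ROC and PR curves sweep the distinct score
values (ties grouped into one point); areas use the trapezoid, with the PR
curve's recall-0 endpoint extending the first precision value — under
which a constant-score classifier's AUPRC equals the positive prevalence.
AUROC is verified in the tests against the Mann–Whitney U normalization
and an independent reference implementation. Areas are always reported on
the 0–1 scale, with 0–100 convenience columns in the flat report, since
published tables mix both conventions.

`solveConfusionMatrix()` exhaustively searches the positive count P and
reconstructs every integer (TP, FP, TN, FN) whose recomputed ACC/SN/SP
round (half-up, two decimals — the precision of printed tables) back to a
given tuple, reporting uniqueness; the test suite uses it to confirm that
published metric tuples correspond to unique integer matrices.

## The synthetic methylome generator

The generator exists so the full pipeline — readers, windowing, encoders,
training, evaluation — can be exercised end to end with no downloads, with
an honest, known performance ceiling.

`generateGenome()` draws i.i.d. residues at a target GC content (default
0.5). `plantMethylome()` selects CpG sites spaced at least a window width
apart (so windows never interact), injects a sequence element into the
window of half the sites, and draws β from a Beta distribution with mean
80% when the element is present in the window (whether injected or by
chance) and mean 20% otherwise. With concentration parameter 6, each
class's probability of crossing the 50% threshold "correctly" is 0.951, so
the Bayes accuracy of the planted rule is ≈ 0.95; the object reports the
exact value, computed from the Beta tail probabilities and the observed
element frequency. In the noiseless limit the ceiling is 1; with equal
high/low means the rule is uninformative and the ceiling collapses to the
majority base rate — both limits are tested.

The planted element is a cluster of three occurrences of the periodic
TATA-like hexamer `TATATA`. Both properties are deliberate. Real
methylation-associated determinants are regional (CpG islands, AT-rich
promoter elements) rather than single hexamer hits, so a clustered element
is the more faithful miniature; and a periodic motif is detectable from
its constituent 3-mers without phase information, matching what a
kernel-3/pool-4 encoder can express. During development, a single
occurrence of a non-periodic hexamer proved to sit at the edge of this
architecture's sample efficiency at n = 2000 (the network memorizes the
training windows before it generalizes the rule); that regime is a real
limitation of the fixed architecture worth knowing about, and it is why
the default fixture plants a clustered, periodic element. The labeled rule
is still plain motif presence, and the Bayes ceiling is independent of the
cluster size.

What the generator does *not* emulate: bisulfite conversion error,
read-depth-dependent β noise, strand asymmetries, CpG-island-scale spatial
autocorrelation of methylation, and genome composition beyond i.i.d.
residues. A model that passes the synthetic tests has demonstrated that
the pipeline is wired correctly and can learn a planted sequence rule near
its Bayes ceiling — not that it attains any particular accuracy on real
methylomes.

## Problem sizes used by the tests

The test suite trains the UNet on the default fixture (2000 sites, 100-bp
windows, dimer encoding, 20 epochs, seed fixed) and checks test accuracy
≥ 0.85 and AUROC ≥ 0.90 against the 0.951 ceiling, plus chance-level
accuracy ([0.40, 0.60]) after label permutation; a second fixture keyed on
a dinucleotide repeat (`CGCGCG`) checks that dimer encoding is not
inferior to monomer there. Architecture ladders are asserted for inputs
299×8, 300×4 and 99×8 by reading the shapes off instantiated networks, and
all gradients are checked against finite differences. These sizes were
chosen as the smallest at which the statistical properties are stable.

## Known limitations

- Training is single-threaded R; desk-scale by design. Tens of thousands
  of 300-bp windows train in minutes-to-hours, not seconds.
- No regularization (dropout, weight decay) is applied, matching the
  reference training recipe; on small noisy datasets the final-epoch model
  can be a few points below its own early-epoch peak.
- The promoter-style evaluation mode scores user-supplied site lists with
  an already-trained model; it does not fetch or curate promoter
  annotations.
- Minus-strand handling is a convenience flag, not a full strand-aware
  pipeline; merged/destranded CpG calls should be resolved upstream.
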