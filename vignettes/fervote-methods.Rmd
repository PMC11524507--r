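---
title: "Methods: models, statistics and design choices in fervote"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and design choices in fervote}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fervote)
```

# The measurement problem

A panel of raters assigns one of seven emotion labels (anger, disgust,
fear, happiness, sadness, surprise, neutral) to each face in a stimulus
set. Different panels — raters with different cultural backgrounds, or the
same raters viewing masked versus unmasked faces — produce systematically
different label distributions. `fervote` treats the per-face vote vector as
the primary observable and provides the statistics needed to compare
panels: agreement indices on confusion matrices, signed vote-rate
difference maps, correlation comparisons, and a landmark-based eye-opening
covariate that helps explain fear/surprise confusions.

# Vote model and encodings

A face rated by a panel of $n$ raters yields a count vector
$c \in \mathbb{N}^7$ with $\sum_j c_j \le n$ (crowd-vote files may contain
votes for extra labels — contempt, unknown, not-a-face — which are dropped
at the vote level; the face is kept). Three encodings are supported:

* **Vote count** — $c$ itself.
* **Majority (one-hot)** — $\arg\max_j c_j$, ties broken by the canonical
  label order (anger first, neutral last). The tie rule makes the encoding
  a deterministic function of $c$; ties are flagged. An all-zero $c$ is an
  error naming the face, not a silent default.
* **Vote rate** — $r = c / n$ with the panel size as the default
  denominator, so dropped votes leave $\sum_j r_j < 1$. A
  `retained_votes` denominator that renormalises to 1 is available; the
  panel-size rule is the default because it keeps rates comparable across
  faces with different numbers of dropped votes.

Whole-face exclusion (rather than vote-level dropping) is not a separate
mode: filter the vote table's rows before encoding if a design calls
for it.

# Agreement statistics

Confusion matrices fix the column axis to a reference majority labeling
and distribute responses (a second majority labeling, or every individual
vote) over the rows; each column is normalised by its raw total. Two
summary indices are reported:

* Precision $P = \operatorname{tr}(C)/n_{\text{total}}$, the diagonal
  share of all judgements.
* Cohen's kappa. The matrix-level default is the multiclass form
  $(p_o - p_e)/(1 - p_e)$ with $p_e$ from the row/column marginals; the
  binary one-vs-rest closed form
  $2(TP\,TN - FN\,FP)/\{(TP{+}FP)(FP{+}TN) + (TP{+}FN)(FN{+}TN)\}$ is
  exposed separately (`kappa_eq2`) and is algebraically identical to the
  standard binary $(p_o-p_e)/(1-p_e)$ — the test suite verifies this by
  exhaustive enumeration of 2×2 tables. A matrix-level scalar is only
  meaningful as the multiclass statistic, which is why that is the
  default. Degenerate margins return `NA` (an undefined-kappa signal)
  rather than a number.

Cell-wise enrichment is tested with Fisher's exact test on the 2×2 table
{this cell vs rest of its column} × {this column vs all other columns},
two-sided, FDR-corrected (Benjamini–Hochberg) across the 42 off-diagonal
cells. This particular 2×2 construction conditions on the reference
category's margin; other marginalisations are defensible, and absolute
p-values from this test should not be compared against implementations
that marginalise differently.

Between two rater panels, the package reports the **mean pairwise kappa**:
the multiclass kappa of every cross-group rater pair, averaged over all
$|A|\times|B|$ pairs. Averaging over rater pairs (rather than over
categories or images) is the interpretation consistent with kappa being a
two-rater statistic; pairs with undefined kappa are excluded from the
mean.

# Rate difference and shift maps

Because both panels rate the *same* faces, the per-image signed difference
$r^B_{ij} - r^A_{ij}$ cancels biases common to a group. Faces are ordered
by the reference group's majority category (canonical order, then face id)
so each category forms a contiguous block; averaging the difference map
within blocks gives the 7×7 **category shift map** (reference category ×
perceived label).

Each cell's per-image differences are tested against zero with a
one-sample t test — the paired form is the natural choice since the
differences are per-image — and corrected across all testable cells of the
map with Benjamini–Hochberg FDR (default family: all 49 cells; cells from
categories with fewer than two images, or with zero variance, are flagged
untestable and excluded from the family while their means are still
reported).

Per-emotion **correlations** between panels are Pearson correlations of
the two groups' per-image rates for one label, pooled across all faces
(one $r$ per emotion over the full face set); zero-variance series return
an undefined flag. Two correlations are compared with Fisher's r-to-z
transform, $z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2) /
\sqrt{1/(n_1-3) + 1/(n_2-3)}$. Pairwise mean-rate comparisons across
labels or conditions use the Tukey–Kramer studentised-range procedure
(via `stats::TukeyHSD`, which honours unequal group sizes); in the fully
degenerate case of zero residual variance the p-value is defined as 1 for
equal means and 0 otherwise, so constant data yield "no differences"
rather than `NaN`.

The 2-D **embedding** of 7-d rate vectors is a contract-level wrapper: it
guarantees one output point per input vector, determinism under a fixed
seed, and proximity of duplicate inputs. It delegates to classical
multidimensional scaling (`stats::cmdscale`) on Euclidean distances — a
deterministic metric embedding that satisfies the contract exactly; the
`perplexity` argument is retained from the usual stochastic-embedding
interface as an input-size guard (`n ≥ 3 × perplexity`).

# Landmarks, masks and the eye-opening rate

Faces are described by the standard 68-point annotation (jaw 0–16, brows
17–26, nose 27–35, eyes 36–41 / 42–47, mouth 48–67; pixels, origin top
left, y downward). The **mask region** is the polygon through jaw
landmarks 2–14 closed through the mid-nose-bridge landmark 29. That vertex
recipe is the package default because it provably satisfies the functional
requirements of wide-medium lower-face coverage — it contains every mouth
landmark and no eye landmark (asserted by point-in-polygon tests on the
template and on jittered faces) — while remaining configurable
(`mask_polygon(lm, recipe = ...)`) for other coverage recipes.
Self-intersecting recipes are rejected with the offending segment pair.

Rasterisation fills pixels whose *centres* lie inside the polygon, using
an even-odd crossing test with a half-open edge convention, so the fill is
deterministic for boundary pixels. The fill colour is pure white or black,
a seeded fair coin per face by default (mask colour is not believed to
carry systematic recognition effects, so it is randomised rather than
modelled).

The **eye-opening rate** uses the six points of each eye:
$R_{\text{raw}} = (\lVert p_5-p_1\rVert + \lVert p_4-p_2\rVert) /
(2\lVert p_3-p_0\rVert)$, an aspect-ratio-like quantity invariant to
translation, rotation and uniform scale, then
$R_{\text{rate}} = (R_{\text{raw}} - 0.15)\times 3$ clamped to $[0,1]$.
Clamping is the package's reading of "adjusted to the range 0–1"; the
unclamped value and a clamp flag are retained. The per-face value is the
mean of the two eyes (configurable to a single eye); if one eye is
degenerate the other is used with a warning, and only two degenerate eyes
raise an undefined-metric error.

# The synthetic generator

The generator exists so every stage is testable without external data. It
emulates a two-group study: 98 faces (14 per category), an experimental
panel of 17 raters labelling both masked and non-masked conditions, and a
10-rater reference panel labelling non-masked faces only (1,666 and 980
votes per condition respectively).

* **Votes.** Each group × condition has a row-stochastic 7×7 *confusion
  kernel*; every rater's label for a face of category $i$ is an
  independent draw from kernel row $i$. Raters are i.i.d. within a panel —
  the simplest structure consistent with group-level analysis; per-rater
  reliability is deliberately not modelled.
* **Default kernels** (`study_kernels()`). The reference ("Western-like")
  kernel has diagonals 0.62–0.88 with the characteristic confusions of
  forced-choice emotion labelling: fear→surprise 0.17, sadness→neutral
  0.21, disgust→anger 0.12. The experimental ("East-Asian-like")
  non-masked kernel strengthens fear→surprise to 0.26 and trades most of
  the sadness→neutral drift for sadness→disgust. The masked kernel blends
  the non-masked kernel 3:1 with uniform guessing and adds further
  fear→surprise, happiness→neutral and disgust→neutral drift, modelling
  the loss of lower-face cues. These values were fixed once, from the
  descriptive structure the package is designed to detect, and are
  configuration, not estimates.
* **Shift planting.** `inject_shift(kernel, from, to, magnitude)` moves
  diagonal mass off-row, enabling recovery experiments: plant a 0.3
  fear→surprise shift in one group and check the shift map finds it.
* **Landmarks.** A parametric template face in a 48×48 frame (the face-crop
  geometry of common FER datasets); the lid separation is constructed so
  the raw eye opening equals a value drawn uniformly from a requested
  range (exact at zero jitter), and isotropic Gaussian jitter
  (default 0.25 px) roughens the geometry. The study-shaped fixture gives
  fear/surprise faces raw openings in [0.30, 0.40] and the others
  [0.15, 0.25], encoding the premise that those two categories come with
  wide-open eyes.

**What the generator does not emulate.** Real faces within a category are
heterogeneous: each image has its own idiosyncratic response distribution,
*shared* between any two panels that rate it. Under the kernel model all
images of a category are exchangeable, which has two visible consequences.
First, majority-vs-majority agreement between groups is nearly perfect in
synthetic runs (majorities average away rater noise, and the kernels share
their argmax almost everywhere), whereas with real data per-image
ambiguity keeps such agreement well below 1. Second, per-emotion
cross-group correlations are driven only by between-category structure
plus binomial noise; with real data, shared per-image variation pulls the
correlations of unshifted labels towards 1 and makes a genuinely shifted
label (fear) stand out as clearly lowest. In synthetic recovery runs the
planted fear→surprise shift depresses the fear *and* surprise correlations
about equally, so "fear is strictly lowest" holds only in about half of
replicates even though the planted shift cell itself is recovered as the
top significant cell in ≥95%. Passing tests on synthetic data therefore
demonstrate the statistics and their error control, not the full
image-level texture of real datasets.

# Seeds, sizes and numerical conventions

Every stochastic function takes an explicit integer seed; the pipeline
fans a single global seed out to per-stage seeds by fixed offsets
(`seed × 1000 + stage`). Test and acceptance runs use the study-shaped
sizes (98 faces, panels of 17 and 10) with 100-replicate recovery
experiments, 200-replicate null calibrations, and a 1,000-replicate
Tukey–Kramer null; these sizes give Monte-Carlo error comfortably below
the asserted margins while keeping a full run in tens of seconds.

Other conventions: kernel rows must sum to 1 within $10^{-9}$; confusion
columns with zero totals stay zero instead of dividing by zero; undefined
statistics (kappa with degenerate margins, correlation of constant series,
eye metrics of zero-width eyes) signal their undefinedness (`NA` or a
classed condition) rather than returning an arbitrary number; CSV I/O of
the crowd-vote dialect preserves the file's column order bit-exactly on
write, and landmark JSON is written at full double precision so round
trips are identity.

# Known limitations

* No per-image or per-rater random effects in the generator (see above);
  both are natural extensions of the kernel model.
* The cell-wise Fisher construction and the shift-map FDR family are
  reasonable defaults, not canonical; absolute p-values depend on them.
* Weighted kappa, Krippendorff's alpha and bootstrap intervals are out of
  scope, as are landmark detection and photorealistic mask rendering.
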