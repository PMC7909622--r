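---
title: "Peak-word embeddings for MS/MS spectral similarity: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peak-word embeddings for MS/MS spectral similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models implemented in `specembed`, the
parameters that matter and why their defaults are what they are, what the
synthetic benchmark does and does not emulate, and the numerical choices
made where the design was genuinely open.

## 1. From spectrum to document

An MS/MS spectrum is a list of fragment (m/z, intensity) pairs plus
metadata (precursor m/z, parent mass, ionisation mode, structure
identifier). Two observations motivate a text analogy: fragment peaks have
no meaningful order the way words in a sentence do, and recurring fragment
or neutral-loss positions across a corpus behave like a vocabulary whose
co-occurrence statistics encode chemistry (shared substructures fragment
alike).

Tokenisation is positional binning: a fragment at m/z $x$ becomes the word
`peak@x` with $x$ rendered at `n_decimals` (default 2) decimals. Neutral
losses — precursor m/z minus fragment m/z, a signature of the lost
substructure — are added as `loss@x` words when they fall in the closed
window 5.0–200.0 Da: below 5 Da losses are chemically uninformative, above
200 Da they mostly duplicate low-mass peak information. Spectra without a
precursor m/z contribute peak words only.

Numerical choices:

* **Rounding is decimal, not binary, with ties away from zero.** Plain
  `round()` operates on the binary double: 200.445 is stored as
  200.44499…, so binary rounding yields 200.44. `format_mz()` first
  renders nine guard digits (which recovers the intended decimal literal)
  and then rounds at the target precision with ties away from zero,
  giving 200.45. This makes word identity reproducible across platforms
  and matches how practitioners read peak lists.
* **Duplicate words are kept.** Two distinct peaks binning to the same
  word remain two tokens; deduplication would silently discard intensity
  mass and distort the training statistics.
* **Loss words are ordered by ascending loss value.** Word order inside a
  document is irrelevant to training (the context window spans the whole
  document), so this is purely a reproducibility convention.
* **Weights.** Document weights are intensities normalised to a maximum
  of 1 within the spectrum; a loss inherits the weight of its generating
  peak, since losses are derived observations, not independent ones.

## 2. The two filtering tracks

All spectra first pass a closed m/z window filter ([0, 1000] Da) and a
minimum-peak rule (≥ 10 peaks; sparser spectra carry too little signal
for any similarity score). Beyond that, the classical and embedding
scores get different treatment, because their noise sensitivities differ:

* **Cosine track** — intensities normalised, then peaks below 1% relative
  intensity dropped (kept at exactly 1%). Low-intensity noise peaks both
  distort greedy matching and inflate its cost.
* **Embedding track** — the number of peaks is capped at
  `floor(0.5 · parent_mass)`, keeping the most intense ones. Larger
  molecules legitimately produce more informative fragments, so the cap
  scales with mass; its purpose is to keep document lengths comparable
  across the corpus. The floor is taken because a fractional peak count
  is meaningless and flooring is the conservative direction. When no
  parent mass is available the cap is skipped with a warning rather than
  guessing.

Parent mass falls back to `precursor_mz − 1.007276` (proton mass, i.e.
assuming a singly protonated positive-mode ion). This is an explicit,
logged assumption: adduct inference beyond the single proton is out of
scope, and spectra with known different adducts should carry a corrected
`parent_mass`.

## 3. The embedding model

`spec_embedding()` trains word vectors by CBOW (default) or skip-gram
with negative sampling — the word2vec scheme — in compiled code with an
internal deterministic RNG. Key parameters:

| parameter | default | why |
|---|---|---|
| `window` | 500 | fragment order is meaningless, so the whole document must act as context; 500 exceeds any realistic document length. A corpus with longer documents triggers a truncation warning. |
| `mode` | `"cbow"` | observed to work better than skip-gram for spectrum corpora; skip-gram remains available. |
| `negative` | 5 | negative samples per target word, drawn from the unigram distribution raised to 0.75. |
| `epochs` | 15 | appropriate for corpora of roughly $10^3$–$10^5$ documents; see "training volume" below. |
| `dim` | 300 | standard for released models of this family; a configuration key, not a constant. |
| `min_count` | 1 | every observed word gets a vector, so missing words arise only from train/apply vocabulary mismatch. |
| `alpha`, `min_alpha` | 0.025, $10^{-4}$ | initial learning rate with linear decay over the run. |
| `intensity_power` | 1 | exponent on the weights in the spectrum-vector sum; 1 is the plain weighted sum, the exponent is exposed because implementations of this method family sometimes weight by a power of intensity. |

**Determinism.** Training is single-threaded by design; the same corpus,
parameters and seed reproduce the vector matrix bit for bit (the RNG is
an internal xorshift generator, not R's). This is the only reproducible
mode; a parallel trainer would trade that away.

**Training volume, not epochs.** What governs embedding quality is the
total number of training updates — documents × epochs — relative to the
vocabulary size, not the epoch count alone. In early training all word
vectors share a large common component (output vectors start at zero and
the first gradients all point the same way), which inflates every cosine
towards 1; enough updates disperse it. Fifteen epochs suffice for a
~700-document corpus; very small corpora (tens to a few hundred
documents) need proportionally more epochs, which is why the package's
own small-corpus examples train for 50–200 epochs — the same reasoning
that leads to training longer on smaller reference libraries in
practice. Conversely, very long training with negative sampling can
degrade scores again (overfitting), so epochs should scale inversely
with corpus size rather than grow without bound.

**Spectrum vectors and missing words.** A spectrum vector is
$v_S = \sum_i w_i v_i$ over the in-vocabulary words of its document. The
intensity-weighted missing fraction
$1 - \sum_{i \in \text{vocab}} w_i / \sum_i w_i$ quantifies how much of
the spectrum the model has never seen: a few weak unknown peaks barely
move it, one strong unknown peak dominates it. Similarities are computed
regardless but flagged unreliable above `allowed_missing` (default 0.05)
— a policy choice: callers decide whether to drop flagged scores, since
a flagged score can still be informative context.

## 4. Classical scores

The greedy cosine collects candidate peak pairs within an inclusive m/z
tolerance (default 0.005 Da), sorts them by intensity product (ties:
smaller m/z residual, then lower peak index — the tie-break makes
results platform-deterministic), and accepts pairs whose peaks are both
unused. The modified cosine additionally admits pairs aligning after a
shift by the precursor m/z difference; each peak may be matched as-is or
shifted, never both. Normalisation uses the intensity norms of *all*
peaks, not only matched ones — the standard dot-product cosine — so the
score of a spectrum with itself is exactly 1. Scores with fewer than
`min_match` matched pairs (defaults: 6 for cosine, 10 for modified
cosine) are forced to 0, suppressing matches built on a handful of
coincidental peaks.

Greedy assignment is a 1/2-approximation to the maximum-weight matching;
`optimal_assignment()` provides the exact brute-force reference for
validation (it is exponential and test-only). On random instances with
up to 8 candidates the greedy total equals the optimum in roughly 85–90%
of cases and never exceeds it — the package's test suite checks both.

## 5. Evaluation workflows

* **Top-percentile curves.** For each fraction $f$, the mean structural
  similarity over the $\lceil f \cdot n\rceil$ unique pairs with the
  highest spectral scores, alongside the theoretical maximum (the mean
  of the $f$ highest structural similarities themselves).
* **Library matching.** Candidates are pre-selected by an inclusive
  1 ppm precursor window; the highest-scoring candidate is accepted iff
  its score is *strictly* above the threshold ("larger than" read as
  strict; ties broken by smaller precursor difference, then id). A true
  positive shares the query's planar InChIKey (first 14 characters,
  hashing the 2D skeleton). Retrieval is the fraction of queries
  yielding any match; accuracy is TP/(TP+FP), 0 when nothing matched.
  These definitions are documented assumptions: the axes semantics of
  accuracy/retrieval plots rarely print their formulas. The default
  threshold sweep is 0.95 down to 0 in steps of 0.05.
* **Top-k analog search.** The whole library ranked by embedding cosine,
  no precursor filtering — the use case where fixed-length vectors shine
  computationally and structurally related molecules of different mass
  can surface.
* **Networking.** Each node contributes edges to its up-to-10
  highest-scoring neighbours strictly above the threshold; the graph is
  the undirected union, so degrees may exceed 10 via incoming edges.
  Connected components larger than `size_cutoff` (default 30) are split
  by weighted Louvain modularity communities (`igraph::cluster_louvain`,
  seeded for determinism; resolution left at 1 — the Louvain
  configuration is an explicit knob, not a tuned constant). Cluster
  quality: per cluster with at least one internal edge, the mean
  structural similarity over its internal edges; nodes in clusters at or
  above the 0.5 cutoff count as well-clustered, below as
  poorly-clustered, and nodes whose cluster has no internal edges
  (isolates and, after splitting, edgeless singletons) as unclustered.
  The three counts partition the nodes, so the fractions sum to 1
  exactly on the integer counts.

## 6. The synthetic benchmark

Real spectral libraries with structure annotations are large downloads;
the package instead ships a generator whose ground truth is exact by
construction, so every workflow is testable offline.

**Block model.** A universe of `n_blocks` (default 40) substructure
blocks; each block owns a disjoint set of fingerprint bits (24 of 2048)
and a disjoint set of characteristic fragments (8, with base intensities).
A molecule is the union of `blocks_per_molecule` (4) blocks, so the
Tanimoto similarity between two molecules is *exactly*
shared blocks / union blocks — the score-versus-structure analyses need
no chemistry dependency and have a closed-form oracle.

**Families.** Molecules are organised into families of `family_size` (4):
members share a core block set, and each non-first member swaps one core
block for an outside block with probability `swap_prob` (0.5). This
emulates analog series — molecular families — whose within-family
Tanimoto is high (1, 0.6 or 0.33 for 0, 1 or 2 swapped blocks between
two members of a 4-block family). Without families, independently drawn
block sets almost never produce pairs above 0.5 Tanimoto and the
networking and analog-search phenomena would be unobservable.

**Spectra.** A spectrum subsamples the molecule's fragments (dropout
0.1), jitters m/z (Gaussian, sd 0.002 Da — below the two-decimal bin
width, so most words survive binning intact) and intensities (log-normal,
sd 0.1), and adds 5 spurious uniform peaks. The precursor is
`parent_mass + 1.007276` (singly protonated positive mode); the parent
mass sits 21–180 Da above the heaviest fragment so that a realistic
subset of losses falls inside the 5–200 Da window. A floor of 10 total
peaks is guaranteed by restoring the most intense dropped fragments;
parameter sets that cannot reach the floor at all are rejected. Default
scale: 200 molecules × 4 spectra. All randomness flows through one
seeded generator; identical configuration and seed reproduce the output
files byte for byte.

**Experiment designs.** *Library-split*: 100 query molecules contribute
one spectrum each to the query set and keep their remaining spectra in
the library — every query has a same-molecule hit available, the library
matching scenario. *Unknown*: all spectra of 20 molecules are removed
from both library and training corpus — the analog-search scenario with
zero molecular overlap between queries and training data.

**What the benchmark does not emulate** — and hence what passing tests do
not show about real data: fragmentation chemistry (fragments are not
constrained by a molecular formula; there are no isotope patterns or
multiply charged ions), realistic fingerprint bit correlations (real
path fingerprints have correlated, unevenly weighted bits; here Tanimoto
is exactly block overlap), instrument-dependent mass accuracy and
intensity response, adducts other than [M+H]⁺, and metadata errors. The
benchmark validates the *pipelines* — that the scores, matching,
ranking, networking and bookkeeping behave as specified when structure
and spectra are linked in a known way — not chemical performance claims
on real libraries. Parent masses are also continuous random values, so
the 1 ppm precursor window almost never returns wrong-molecule
candidates; synthetic matching accuracies are accordingly optimistic and
serve as pipeline checks, not benchmarks against real-world accuracy
figures.

## 7. Problem sizes used in tests and the acceptance script

The test suite trains small models (40 molecules, 64 dimensions, 60
epochs) for fixture-based checks and one benchmark-scale model (200
molecules, default dimension, 15 epochs, seed 0) for the end-to-end
recovery test. The acceptance script runs the 200-molecule benchmark:
training at 15 epochs for matching and percentile analyses, and a
200-epoch model on the 200-document one-spectrum-per-molecule corpus for
networking (the training-volume equivalent of many more epochs being
appropriate on a much smaller corpus, as discussed in section 3). These
sizes were chosen as the smallest at which the studied effects are
stable across seeds.

## 8. Known limitations

* The trainer is single-threaded; corpora of $10^5$ documents train in
  tens of minutes, not seconds. A multi-worker mode would be
  non-deterministic and is deliberately absent.
* `optimal_assignment()` is exponential and guarded; it exists to
  validate the greedy matcher, not to score real spectra.
* The fingerprint adapter produces OpenBabel FP2 path fingerprints
  (1024 bits). These are daylight-like but not identical to other
  toolkit fingerprints; mixing adapter output with precomputed
  fingerprints from another source in one comparison set is rejected by
  the length check, and is scientifically inadvisable anyway.
* Negative ionisation mode is stored but not treated specially; the
  proton-mass parent fallback assumes positive mode.
* Word-level geometry in tiny, deterministic corpora can be
  counter-intuitive: a word that never appears in its *own* context and
  always with the same companion can end up with an input vector opposed
  to its companion's in the overfit regime. Document-level similarities
  — the package's product — are unaffected at realistic corpus sizes;
  the test suite therefore checks word-level claims in the probabilistic
  co-occurrence regime the method is designed for.
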