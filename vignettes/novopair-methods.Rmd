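---
title: "Library-assisted de novo sequencing of HCD/ETD spectrum pairs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Library-assisted de novo sequencing of HCD/ETD spectrum pairs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(novopair)
```

## The problem and the model

De novo peptide sequencing reads a peptide's sequence directly from its
tandem mass spectrum, without a protein database. A single spectrum rarely
carries a complete fragment ladder, so one productive strategy fragments the
same precursor twice with complementary chemistries — HCD, which yields
mostly b/y ions, and ETD, which yields mostly c/z ions — and sequences the
pair jointly. `novopair` implements such a pipeline, with one extra
ingredient: annotated spectral libraries are used as *training data* to
quantify how trustworthy each peak-selection rule is, and that trust is
carried as a per-peak significance score through every downstream stage.

The pipeline is:

1. **Charge expansion.** Fragment ions of a charge-`n` precursor can carry
   charges 1..n−1. Each spectrum is re-expressed under every charge
   hypothesis `i`: a peak observed at `mz` becomes `i·mz − (i−1)·m_H` at
   charge 1 (`expand_charges()`).
2. **Peak selection** (`select_aa_difference()`,
   `select_complementarity()`). Two criteria identify peaks likely to be
   true fragment ions:
   - *Amino-acid mass difference*: a peak `v` is selected when flanking
     peaks `u < v < t` exist in the same charge hypothesis with
     `v − u = a_i − σ` and `t − v = a_j + σ` for residues `a_i, a_j` and a
     single neutral-loss offset `σ ∈ {0, m(H2O), m(NH3)}`. The shared `σ`
     is the loss carried by `v` itself: a fragment that lost water sits
     `18 Da` low relative to its left neighbour and `18 Da` "high" seen
     from its right neighbour. Only the middle ion is selected, and its
     loss state is recorded.
   - *Ion complementarity*: two charge-1 peaks flanking the same backbone
     cleavage satisfy `u + v = m_p + 2·m_H` (b/y, HCD) or
     `u + v = m_p + 3·m_H` (c/z, ETD), where `m_p` is the neutral parent
     mass. Pairs may span charge hypotheses, which is how a doubly charged
     fragment is recognised: its hypothesis-2 re-expression is the member
     that satisfies the relation, and the source peak's charge is recorded.
3. **Scoring and merging** (`merge_pair()`). Each selected peak receives
   the library-trained significance score of the criterion that selected
   it; a peak selected by several distinct criteria sums their scores, and
   repeated witnesses of the *same* criterion count once. Selected peaks
   from both spectra are pooled on the charge-1 axis and coalesced within
   `θ` into the merged spectrum, a scored peak list.
4. **Tags** (`generate_tags()`, `extend_tags()`, `score_tags()`,
   `select_tags()`). Length-3 sequence tags are read from every 4-peak
   chain whose consecutive differences are residue masses; tags with a
   two-residue sequence overlap and matching support peaks merge into
   longer tags until a fixed point. Tags are scored by a weighted mean of
   their supporting peaks' significance scores and the best `Sel` per
   source class are kept.
5. **Graph search** (`build_graph()`, `enumerate_segment_paths()`,
   `assemble_and_rank()`). The merged peaks are mapped into prefix-mass
   space under their mode's ion-series interpretations, coalesced into
   vertices, and connected by residue edges and 2–3-residue gap edges.
   Each selected tag anchors the search; the regions between the tag and
   the termini are filled with the `K` best partial paths each, and
   assembled candidates are ranked by the sum of significance scores along
   their path. The top `C` distinct sequences are reported.

## Significance scores and training

The significance score of a criterion is its empirical precision on an
annotated library: on each library spectrum the selector runs exactly as in
production, every selected peak is checked against the theoretical fragment
ladder of the annotated peptide (series per mode, charges 1..n−1, losses
none/H2O/NH3, tolerance `θ`), and the per-spectrum fraction of selected
peaks that are real is averaged over all spectra that selected anything
(`train_score_model()`).

For HCD the complementarity score is split by pair position: the charge-1
axis `[0, m_p + 2·m_H]` is divided into four equal parts, and a pair whose
members both fall in the middle two quarters is scored `S_compM`, otherwise
`S_compE`. Anchoring the quarters to the maximal possible charge-1 fragment
value (rather than the highest observed peak) keeps the classification
independent of which peaks happen to be detected in a given spectrum; for
library-quality HCD spectra, whose top peaks approach the precursor, the
two definitions nearly coincide. For ETD a single complementarity score is
used, and a single pooled amino-acid-difference score is used rather than
400 residue-pair-specific ones — positional and per-residue variation is
real but small relative to the noise of estimating hundreds of scores.

Why one `σ` per aa-difference selection rather than an independent loss on
each side? The two readings disagree on observable output: with independent
per-side offsets, a peak flanked by two loss-bearing ions would also be
selected, and on the didactic integer-mass example (see
`tests/testthat/test-acceptance.R`) that would admit a second middle ion
(277) and a second complementary pair (130, 346), while the consistent-loss
reading selects exactly the peaks the method intends — those explainable by
a single physical loss state of the middle ion. The same reasoning applies
to complementarity: the default (`sigma_mode = "inferred"`) corrects each
peak by the loss already inferred for it in the aa step and then tests the
relation exactly; the literal free-offset reading remains available as
`sigma_mode = "free"` for sensitivity analyses.

## Tag scoring: the printed weights and the symmetric option

The tag score is

\[
s_t = \frac{1}{l_t + 1} \sum_{l=1}^{l_t+1} ss_l\,\bigl(1 + 0.1\,\min\{l,\; l_t - l\}\bigr),
\]

with `ss_l` the significance score of the l-th supporting peak. As printed,
the weights are asymmetric: for `l_t = 3` they are (1.1, 1.1, 1.0, 0.9), so
a uniform-unit-score tag evaluates to 1.025. The motivating idea — end
peaks are less reliable than interior peaks — suggests the symmetric form
`1 + 0.1·min{l−1, l_t+1−l}`, i.e. (1.0, 1.1, 1.1, 1.0) and 1.05 on the same
tag. The printed form is the default; `score_tags(symmetric = TRUE)`
switches to the symmetric reading. Peaks without a score contribute 0, so
tags unsupported by the library-trained selection rank low.

## Graph reconstruction choices

The spectrum-graph layer is a reconstruction around the published search
parameters (per-segment stop threshold `K`, output count `C`):

- **Vertex convention.** All peaks map into N-terminal prefix-mass space:
  HCD peaks under b (`prefix = mz − m_H`) and y
  (`prefix = m_p + m_H − mz`) interpretations, ETD peaks under c
  (`b − NH3` shifted) and z analogously. True interpretations of
  complementary ions land on the same prefix and coalesce (within `θ`)
  into one vertex whose score is the sum over distinct contributing peaks,
  concentrating evidence exactly where cleavages are.
- **Edge types.** Residue edges (one amino acid within `θ`) and gap edges
  labelled with the closest 2–3-residue mass combination; candidate
  assembly spells a gap's residues in alphabetical order, and ties in
  candidate ranking prefer paths with fewer gaps.
- **Search.** `enumerate_segment_paths()` is an exact top-K dynamic
  program over the prefix-ordered DAG under a deterministic total order
  (score, then gap count, then sequence, then vertex ids). Truncating each
  vertex's partial-path list to its K best is lossless for the global top
  K, so the returned paths provably match exhaustive enumeration — the
  property the correctness tests assert — and raising `K` never removes a
  previously returned path. No randomness exists anywhere in the pipeline;
  all ties break by documented rules.
- **Tag anchoring.** A tag is located under each ion-series interpretation
  compatible with its source class (C-terminal series reverse the
  string); all of its support-peak prefixes must match graph vertices
  within `θ`. Assembled candidates must match the parent mass within
  `θ·(length+1)` before ranking by score sum.
- **z-ion convention.** The z series is the z-dot radical ion defined as
  `y + m_H − NH3`, which makes singly charged c/z partners sum to exactly
  `m_p + 3·m_H` — the same constant the ETD complementarity relation uses,
  so the chemistry and the selection rules are mutually consistent.

## Parameters

| Parameter | Meaning | Default |
|---|---|---|
| `θ` | peak-selection / coalescing / edge tolerance (Da) | 0.01 |
| `Sel` | tag budget per source-spectrum class | 10 |
| `K` | stop threshold: paths kept per segment | 10 |
| `C` | candidates output per spectrum pair | 3 |
| pairing tolerance | max parent-mass difference within a pair (Da) | 0.02 |

The first four defaults are the method's published operating point; the
pairing tolerance is this package's choice (the datasets the method was
developed on are annotated, so pairs are primarily matched by title, with
parent mass as fallback). An integer "toy" mass table (S = 87, E = 129,
water = 18, m_H = 1, exact matching) exists solely to make the worked
example reproducible by hand; real data always uses monoisotopic masses.

## The synthetic-data generator

`simulate_pair()` / `simulate_library()` emulate the data the algorithm
assumes: complete b/y and c/z ladders at fragment charges 1..n−1 for
tryptic-like peptides (7–12 residues, C-terminal K/R, alphabet without I so
exact-sequence recovery is well defined), with four corruption knobs —
neutral-loss satellites (default probability 0.2 per fragment), fragment
dropout (0.1), uniform noise peaks (fraction 0.3 of the peak list) and
Gaussian m/z jitter (3 mDa). The defaults are plausible for deconvoluted
Orbitrap-class data; noise-free settings (`loss_prob = dropout =
noise_fraction = jitter_sd = 0`) generate exact ladders.

Two design points matter for testing:

- Noise peaks are drawn uniformly but rejected within `3θ` of any
  theoretical fragment, so per-peak ground-truth labels are unambiguous —
  a "noise" peak can never be accidentally correct.
- The signal and noise parts of each spectrum come from independently
  seeded RNG streams derived from the base seed. Libraries generated at
  different noise fractions from the same seed therefore share their real
  spectra exactly, and their noise sets are nested. Comparisons of trained
  scores across noise levels are then coupled comparisons: they isolate
  the effect of added noise instead of confounding it with fresh sampling
  of peptides and ladders.

What passing tests on this generator do **not** show: behaviour under
correlated chemical noise, isotope envelopes, intensity-dependent peak
quality, modified residues, or the peculiarities of any particular
instrument. The published accuracies on real SCX datasets depend on
libraries and raw data without stated accessions and are not reproduced
here; the property-based checks (exact training scores on clean data,
monotone degradation with noise, ≥ 90% top-3 recovery on clean pairs) are
the package's stand-ins.

## Problem sizes used in the test-suite

The bundled checks run at sizes chosen to exercise the statistics without
waste: training sanity uses libraries of 50 spectra per mode and noise
fractions {0.1, 0.3, 0.5}; search correctness uses 200 random DAGs of up
to 15 vertices against an exhaustive oracle; the end-to-end property uses
100 noise-free pairs (length 7–12, charge 2–3) with models trained on 20
clean spectra per mode. On clean data all trained scores equal 1.0 exactly,
so the end-to-end run effectively counts criterion hits per peak — with
noisy training data the same pipeline runs unchanged, with scores between
0 and 1.

## Known limitations

- Post-translational modifications are out of scope; the residue table can
  be overridden from YAML/JSON (`read_residue_table()`) as a hook for
  fixed modifications, but variable modifications are not searched.
- Intensities are read and preserved but unused: the selection criteria
  are m/z-only, as is the candidate score.
- I/L are indistinguishable by mass and reported canonically as L;
  K/Q differ by 0.036 Da and are distinguishable at the default `θ`, but
  not in the integer toy mode.
- The aa-difference criterion models at most one neutral loss on the
  middle ion; doubly lost fragments (e.g. −2·H2O) are not selected.
- Cross-mode complementarity (an HCD peak with an ETD peak) is not tested;
  the relations are defined per spectrum.
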