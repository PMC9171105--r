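---
title: "Models and methods behind audiomemory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind audiomemory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audiomemory)
```

# The task and its representation

The task is a sound-pairing adaptation of the card game "Memory" played on
a 5×5 grid of haptic blocks. Coordinates are 0-based `(row, col)`,
row-major, row 0 at the top; the center block `(2, 2)` carries the
feedback speaker and is never selectable. A difficulty condition exposes
`2 × n_pairs` apertures: 8 in the 4-pair condition, all 24 non-center
blocks in the 12-pair condition. Each hidden animal-call label occupies
exactly two apertures; an attempt is an ordered touch of two distinct
apertures, and a match covers both sites for the rest of the session.
Sessions are self-paced and end when every pair is matched; the simulator
adds a configurable safety cap (default 10,000 attempts) purely as a guard
against non-terminating agent parameterizations.

Two representational choices deserve a note:

* **The 4-pair aperture geometry is configurable.** The published grid
  drawing is not recoverable as coordinates from text, so the default is
  the first 8 non-center positions in row-major order, and any geometry
  can be supplied via `new_board(..., apertures = )` or the pipeline
  config. The 24-aperture grid is forced by geometry (25 blocks minus the
  center). No result in this package depends on which 8 positions are
  open, because the indices are functions of touch identity, not distance.
* **Feedback audio is out of scope.** The "correct/incorrect" feedback is
  represented by the `matched` flag; sound rendering, calibration and the
  tactile sensor sub-grid are hardware concerns that do not affect the
  indices.

Re-touching an unmatched aperture across attempts is legal (the game
requires it); touching the same aperture twice *within* one attempt is
modeled as illegal, as is touching a covered site.

# The three indices

**Score** starts at 0. A matching attempt adds +10 flat — never combined
with penalties, which is the only reading consistent with the published
worked example (0 − 1 − 2 + 10 = 7). A non-matching attempt adds 0 if both
blocks are first-time touches, −1 if exactly one was touched in a strictly
earlier attempt, −2 if both were. "Previously touched" is evaluated
against attempts strictly before the current one: the first touch of an
attempt does not make its own second touch "old".

**Number of Attempts** measures maintenance: for each pair `P`, let
`d(P)` be the attempt at whose end both sites of `P` have been revealed
and `m(P)` the attempt that matches it; the pair contributes
`m(P) − d(P)` and the session value is the mean over pairs. The exclusive
difference makes a pair matched on the attempt completing its discovery
count 0 and single-step perfect recall count 1, which matches the index's
meaning as a memory-maintenance measure. Whether the original counting was
inclusive is not decidable from the text, so
`compute_number_of_attempts(counting = "inclusive")` provides the
`m − d + 1` variant. Incomplete sessions raise an error unless
`partial = TRUE`, which skips never-matched pairs with a warning — pairs
never touched at all are only detectable when the session-level pair count
is attached to the log (simulated logs carry it; files do not).

**Audio-Anchor** adds 1 for every attempt (from the second on) whose first
touch equals the previous attempt's first touch. Second touches never
participate. If the previous attempt matched and covered its first block,
the next attempt cannot legally start there, so no special rule is needed
across matches.

# The behavioral agent

The generator needs a mechanism that can express a memory deficit and an
anchoring strategy with parameters that map one-to-one onto the three
indices; anything richer would be unidentifiable from the indices alone.
The agent holds a position-addressed, all-or-none memory (the original
aperture sizes were chosen to exceed auditory localization error, so
spatial blur is deliberately absent):

1. if memory holds both sites of an unmatched pair, play that pair;
2. otherwise choose the first touch: with probability `anchor_propensity`
   re-touch the previous attempt's first block if still in play, else per
   policy — `systematic_scan` (lowest row-major untouched aperture) or
   `uniform_random` (uniform over unmatched);
3. choose the second touch: the remembered partner of the first-revealed
   sound if stored, else per policy excluding the first touch.

After each attempt every newly heard `(position, sound)` is stored with
probability `p_encode`, every stored entry is dropped with probability
`p_forget`, and matched sounds are purged.

One deliberate deviation from a literal "scan" reading: once every
aperture has been touched, the scan fallback draws uniformly from the
unmatched apertures instead of deterministically taking the lowest one. A
deterministic fallback would lock a memoryless scanner onto the same two
apertures forever; the uniform fallback is the smallest change that makes
*both* policies satisfy the coverage/termination property (every unmatched
pair is eventually attempted with positive probability).

`p_encode = 1, p_forget = 0` defines the perfect-memory agent; under the
scan policy it completes a 4-pair board in at most `2 · n_pairs − 1 = 7`
attempts, a bound the tests verify over 100 seeds.

# Cohort calibration — a stated world, not an estimate

`cohort_spec()` emulates the study design: 12 subjects per group, ages
uniform on 12–54 years, both conditions within subject, all randomness
derived from one `master_seed` (per-subject parameters, ages, board and
session seeds are drawn up-front from a single seeded stream, so a spec
reproduces its cohort byte for byte).

The group parameter means are **calibration constants**, not estimates of
human parameters — no raw human data are available to fit. The defaults
are:

| group        | p_encode | p_forget | anchor_propensity |
|--------------|----------|----------|-------------------|
| sighted_like | 0.90     | 0.02     | 0.10              |
| blind_like   | 0.60     | 0.10     | 0.40              |

with a common per-subject spread of 0.05 (normal draws truncated to
[0, 1]) and the `uniform_random` policy. Encoding and anchoring means
follow the documented calibration targets; the forgetting rates are this
package's own choice: the attempts-to-pair index explicitly measures
*maintenance* of discovered locations, and the reported group deficit on
that index implies a maintenance (forgetting) difference, not only an
encoding one. A single shared forgetting rate would make the 4-pair Score
contrast rest almost entirely on sampling noise, which no behavioral
scientist would call a realistic operationalization of a group difference
reported as significant on all three indices.

What the generator does **not** emulate: learning or fatigue within a
session, spatial biases (edge effects, handedness), age effects
(age is drawn independently of behavior — which is also why the age gate
in the analysis cascade should come out negative), reaction times, and any
arm-movement constraints. A green qualitative-replication test therefore
establishes that the pipeline detects the calibrated effect pattern — not
that the agent is a model of blind or sighted humans.

On difficulty: with +10 per matched pair, the 12-pair board has a 120
point ceiling against 40, so for competent agents the mean Score is
*higher* in the 12-pair condition while attempts-per-pair and anchoring
are also higher. The direction of the Score–difficulty contrast is
parameter-dependent (a sufficiently amnesic agent pays more than 80 points
of penalties on 24 apertures); the package asserts the direction at the
calibrated parameters and treats any statement that Score must fall with
difficulty for *all* parameters as an overgeneralization.

# The inference cascade

The statistics layer is implemented from scratch; `vegan::adonis2` and
`stats::aov` appear only as oracles in the test suite.

**Permutation Welch t.** The statistic is Welch's unequal-variance t; the
reference distribution relabels the pooled sample into the original group
sizes. When `choose(nx + ny, nx)` does not exceed the enumeration
threshold (default 20,000) all splits are enumerated and the exact
proportion with `|t*| ≥ |t_obs|` is reported; otherwise Monte-Carlo
sampling uses the add-one estimate `p = (b + 1)/(n_perm + 1)`, which can
never report p = 0. Cohen's d (pooled SD) is attached. Degenerate inputs:
two zero-variance samples with equal means give t = 0; with unequal means
the statistic is ±Inf with a warning (comparisons against ±Inf remain
well-defined in the permutation loop); zero pooled variance makes d an
error rather than a silent 0.

**Mixed-design permutation ANOVA.** The statistics are the classical
repeated-measures F ratios — Group against the subject-within-group
stratum, Difficulty and Group×Difficulty against the
difficulty-by-subject residual — and the permutation layer replaces only
the reference distribution. Two schemes: `raw` (default) permutes
responses freely, which is exact under the full null and mirrors
permutation-of-raw-data ANOVA tools; `residual` is Freedman–Lane — for
each term, residuals of the reduced cell-means model are permuted and the
reduced fit added back — which protects each term against the others.
Partial η² uses each term's own error stratum,
`SS_term / (SS_term + SS_error(term))`.

**Distance-based multivariate test.** The three indices are z-standardized
(they live on incommensurate scales), Euclidean distances are
Gower-centered (`G = J(−D²/2)J`), and sequential (Type-I) projectors for
the term order Group, Difficulty, Age, then interactions partition
`tr(G)`; pseudo-F per term is `(SS_term/df_term)/(SS_res/df_res)`. With a
univariate response and Euclidean distance this reduces to the classical
one-way F, which the tests verify to 1e−9. Permutation is free row
permutation by default — matching the common usage this design replicates,
which ignores the repeated-measures dependency — with
`strata = subject_id` available as the statistically safer restricted
alternative. Multivariate partial η² is `SS_term/(SS_term + SS_res)`.
Exhaustive row enumeration is available below a factorial threshold and
then reports the exact proportion including the identity permutation.

**Cascade gates.** The pipeline mirrors the published logic: run the
multivariate test with Age; if no age term reaches α = 0.05, drop Age and
run follow-up ANOVAs per index, provided some non-age term was
significant; finish with per-index post hoc permutation t-tests (group
within each condition, condition within each group) under a
Bonferroni family of 4.

A published detail deliberately *not* imitated: the varying "iterations"
counts per term suggest a sequential stopping rule inside the original
permutation sampler; its definition is not recoverable, so this package
uses a fixed `n_perm` everywhere and records it in every result.

# Numerical and reproducibility choices

* All seeded code paths save and restore the caller's RNG state, so a
  function with a `seed` argument never perturbs the surrounding stream.
* Permutation comparisons use `|stat*| ≥ |stat_obs| − 1e−12` to keep ties
  stable under floating-point noise; ties count toward the p-value.
* F ratios with a zero error mean square return 0 when the effect sum of
  squares is also (numerically) zero, `Inf` otherwise, and a constant
  response yields F = 0 and η² = 0 throughout.
* Sequential model ranks come from pivoted QR, so collinear terms
  contribute `df = 0` and are reported as an error ("singular term")
  rather than silently absorbed.
* Monte-Carlo p-values are add-one corrected; exhaustive enumerations
  (permutation t below the split threshold, row enumeration below the
  factorial threshold) report exact proportions and are flagged
  `exhaustive = TRUE`.
* Logs serialize either as a flat TSV table or as line-delimited JSON
  records, auto-detected by extension; both round-trip exactly, and a
  malformed row fails with its line number.

# Known limitations

* The agent is a minimal mechanism for index recovery, not a cognitive
  model; its parameters should not be interpreted as human encoding or
  forgetting rates.
* The free-permutation multivariate default inherits the anticonservatism
  of ignoring within-subject dependency; use `strata` when correctness
  matters more than fidelity to the replicated design.
* Published F, p and d values cannot be reproduced without the raw human
  data; the package targets the qualitative effect pattern only.
* The inclusive/exclusive ambiguity in the attempts-to-pair index is
  resolved by a default, not by evidence; both variants are exported.
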