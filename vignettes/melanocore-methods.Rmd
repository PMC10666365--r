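---
title: "Methods: motif ranking, Boolean calibration and perturbation screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif ranking, Boolean calibration and perturbation screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melanocore)
```

## Scope and model

`melanocore` implements a network-to-target workflow for regulatory maps
of EMT-driving transcription programs, melanoma being the motivating
system. The pipeline has four stages: (1) enumerate three-node feedback
loops in a signed directed interaction map; (2) rank them with a weighted
multi-objective score and merge the top-ranked motifs, receptors and EMT
markers into a core network; (3) translate the core into a Boolean model
calibrated against fold-change signs; (4) screen sustained clamps for
interventions that change the ordinal EMT level.

Everything downstream of the input files is deterministic; the only
randomness in the package lives in the synthetic-data generator, which is
a pure function of its seed.

## Signed networks and motif enumeration

Edges carry signs +1 (activation), −1 (inhibition) or 0 (an interaction
whose direction of effect is unidentified). Feedback motifs are simple
directed 3-cycles; self-loops and 2-cycles are excluded by definition,
and the two orientations of a triangle are distinct motifs. Motifs are
canonicalized by rotating the cycle to start at the lexicographically
smallest node id, which makes enumeration output, tie-breaking and set
operations reproducible. Neutral (sign 0) edges participate in
enumeration by default — curated maps keep them, and dropping them would
silently delete loops — but such loops have `loop_sign = "undetermined"`.
`exclude_neutral = TRUE` restores the stricter behavior.

Degree counts all distinct incident edges (in + out), ignoring signs.
Betweenness is directed shortest-path betweenness normalized by
$(n-1)(n-2)/2$, the convention of the widely used network-analysis
tooling for curated maps, under which the sole intermediary of a directed
path scores exactly 1. The choice of normalization constant is
immaterial to the ranking because the score normalizes every property to
its batch maximum.

## The ranking score

Motif $i$ under weighting scenario $j$ scores

$$ s_{ij} = \frac{w_{1j}}{2}\left(\frac{ND_i}{\max ND} +
\frac{BC_i}{\max BC}\right) + w_{2j}\frac{DP_i}{\max DP} +
w_{3j}\frac{GP_i}{\max GP} + w_{4j}\frac{|FC|_i}{\max |FC|} $$

with all maxima over the motif batch and any zero-maximum term
contributing zero. Per-motif values of ND, BC and GP are arithmetic means
over the three member nodes (a sum option exists; means were chosen
because the fold-change property is explicitly an average and mixing
aggregation styles across terms would skew the weighting). DP is the
count (0–3) of member nodes inside the disease pathway, normalized to the
batch maximum rather than the constant 3, so the term keeps its full
dynamic range in batches where no motif has all three nodes in the
pathway. $|FC|_i$ is the mean of $|\log_2 FC|$ over member nodes with a
non-missing fold change; a zero fold change carries no sign information
and is treated as missing throughout the package. Motifs with no
fold-change data at all score 0 on that term (flagged) rather than being
dropped.

Thirteen default weighting scenarios ship with the package: one uniform,
four emphasizing a single property (weight 2 vs 1), four using one
property alone, and four emphasizing pairs. They are a documented,
reproducible grid standing in for the user-defined iterative weighting
the method anticipates; users override them with a YAML/JSON config. Ties
in top-$k$ selection break by score descending, then canonical motif id
ascending.

## Core assembly

The unique motifs selected across scenarios are merged (union of nodes
and edges, signs preserved). Receptors — supplied as an explicit list,
since receptor curation is a judgment call, not a structural property —
are added when they are first neighbors (either direction) of a core
node, along with their connecting edges; unconnected receptors are
skipped with a warning. The four EMT markers are then added with every
direct edge between a marker and a core node, marker–marker edges
included (epithelial/mesenchymal markers repress each other in real
maps, and dropping those edges would break the readout). Layers are
assigned: receptors → input, markers → output, everything else →
regulatory. Assembly is idempotent and the result is always an exact
subgraph of the full map.

## Boolean calibration

States are three-valued: 0, 1 or unknown, combined with Kleene semantics
(AND: any 0 gives 0, all 1 gives 1, otherwise unknown; OR dual; NOT
flips and preserves unknown). Fold-change signs map to states (positive
→ 1, negative → 0, zero/missing → unknown). Gates are restricted to the
two candidate forms — pure OR and pure AND over signed literals — because
those are the two interpretable hypotheses ("independent regulation" vs
"collective regulation") the calibration data can distinguish; richer
mixed forms are underdetermined by a single sign pattern and are out of
scope. For each multi-regulator node both candidates are evaluated on
the regulators' fold-change states and the one matching the target's
sign is kept. A tie keeps OR, the independent-regulation default, and is
recorded in the calibration report so users can override per node. When
neither candidate matches, or when the comparison is impossible (target
or all regulator signs unknown), OR is kept and the node is flagged
(`unresolved` / `uncalibrated`) instead of guessing.

Input nodes are clamped to their fold-change sign and override their
gates at every step; inputs without a sign stay free.

## Steady states

The logical steady state (LSS) starts from the clamps with everything
else unknown and re-evaluates all gates until the state stops changing.
Because information only accumulates (Kleene gates are monotone in the
information order), the result is the unique maximal partial fixed point
and is independent of update order. Kleene propagation is sound but not
complete: a node fed by reconvergent complementary paths (e.g.
$A \lor \lnot A$ through two branches) is constant over all completions
yet stays unknown. The tests assert exactly the sound direction, plus
full agreement with truth-table evaluation on acyclic models whose
inputs are all clamped.

Pure LSS leaves feedback cycles unknown. The screening convention is
therefore: compute the LSS; if cycle nodes remain unknown, seed them
with their fold-change signs and iterate the synchronous map to its
attractor; nodes constant across the attractor take that value,
oscillating nodes stay unknown. For the bundled fixture the LSS alone is
already complete (its receptor inputs force every OR gate), so the
seeding path only engages for cyclic user models. Synchronous
simulation detects the attractor by first state repetition, with a
default budget of 4 × (node count) steps — regulatory cores have short
transients; the budget is a parameter for adversarial inputs.

## EMT readout and screening

The readout is `EMT = ZEB1 + NOT(CDH1) + VIM + SNAI1`, an ordinal level
0–4. Unknown markers widen the level to a tight interval obtained by
minimizing/maximizing over their completions; interval endpoints travel
through all result tables (`emt_lo`, `emt_hi`) and deltas use interval
arithmetic.

An intervention is a sustained clamp (the node's gate is ignored at
every step). Single and double screens are exhaustive over the
regulatory layer (markers are never clamped; inputs can be included
explicitly), deterministic, and sorted by EMT level then intervention
label. The double screen caps itself at 10,000 evaluations and asks the
user to restrict candidates beyond that. Minimal-intervention search
returns every set of size ≤ 2 achieving the optimal reachable level,
dropping supersets of already-optimal smaller sets.

Robustness analysis flips each regulatory node to the opposite of its
baseline steady-state value and asks whether the EMT level changes
(interval midpoints are compared when unknowns persist). Failures model
mutation-type events on protein-coding genes, so miRNA-species nodes are
excluded by default — a miRNA can be a perfectly good *drug target* (the
screen includes them) while not being a typical spontaneous *failure
mode*; `include_mirna = TRUE` lifts the exclusion. This is also why the
bundled fixture reports fragile nodes {AKT1, MDM2} while its screen
still finds MIR25 inhibition effective.

## The bundled fixture

`melanoma_fixture()` is a hand-built 19-node minimal sufficient model:
ten receptors, five regulatory nodes (E2F1, AKT1, MDM2, MIR25, CTNNB1)
and the four markers, 22 signed edges including a positive feedback loop
E2F1 → MIR25 → MDM2 → E2F1 and the mechanistic axes MDM2 ⊣ CDH1,
CDH1 ⊣ CTNNB1 → SNAI1, AKT1 → VIM and AKT1 → MDM2. Its fold-change
profile was chosen so that gate calibration is self-consistent
(`validate_calibration()` reports no mismatches) and the screen
reproduces the reference behavior: baseline EMT 3; MDM2 or MIR25
inhibition → EMT 1; AKT1 activation → EMT 4; fragile set {AKT1, MDM2}.
It is deliberately *not* a reconstruction of the full published
48-node melanoma core — that edge list lives in supplementary data and
can be supplied as a SIF file — so conclusions about the real map should
be drawn by running the pipeline on the real map.

```{r fixture}
fx <- melanoma_fixture()
model <- infer_gates(fx$core, fx$fc)
glance(model)
find_minimal_interventions(model, max_size = 1)
```

## Synthetic data: what it emulates, and what it does not

The generator emulates the statistical shape of the real inputs: a
sparse signed digraph with planted, verifiable 3-cycles; in-degree-0
receptors wired into the planted loops; four marker nodes fed by the
regulatory layer; a ground-truth Boolean model (random AND/OR gates,
random input clamps); and fold changes whose signs equal the model's
steady state, log-normal magnitudes, and a controllable flipped-sign
fraction `fc_noise`. Defaults — 30 regulatory nodes, 5 planted loops,
density 0.05, sign mix 60/30/10 activation/inhibition/neutral, 10
receptors, noise 0 — are a realistic small curated-map regime; the
noise-degradation checks use 60-node networks over 8–10 seeds and the
recovery checks 40-node networks over 20 seeds, sizes at which every
property under test is already well exercised while the full suite runs
in well under a minute.

What passing these tests shows: the enumeration, scoring, calibration
and screening machinery is correct against independent brute-force
oracles, and planted structure is recovered perfectly at zero noise with
monotone degradation as sign noise grows. What it does not show: that
any particular biological map satisfies the modeling assumptions —
correlated measurement noise, batch structure, feedback-dominated
dynamics with long transients, and curation errors in edge signs are all
absent from the generator.

## Numerical and degenerate-input choices

* Zero fold change = missing sign, never state 0.
* Duplicate edges with conflicting signs are always an error; exact
  duplicates are an error by default (`keep_first` opts out).
* Zero-maximum score terms contribute 0, never NaN.
* Calibration on a *reduced* core can mismatch fold-change signs even at
  zero noise, because motif selection truncates regulator sets; the
  calibration report exists precisely to surface this.
* All exhaustive screens sort deterministically; reruns are
  byte-identical.

## Known limitations

Only 3-node loops are enumerated; gates are pure AND/OR over literals;
update is synchronous (no asynchronous or stochastic schemes); only the
EMT output is multi-valued; intervention sets are capped at size 2. The
13 default weighting scenarios are a stand-in grid — analyses of real
maps should state their own weighting choices.
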