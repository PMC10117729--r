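---
title: "Logical dynamics of Fe-S cluster biogenesis regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logical dynamics of Fe-S cluster biogenesis regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fesnet)
```

## The model and its assumptions

`fesnet` analyzes a multivalued logical (Thomas-formalism) model of the
regulatory network that coordinates the two *E. coli* Fe-S cluster assembly
machineries, Isc and Suf, with iron homeostasis and the peroxide stress
response. The network has 14 nodes. Two are environmental inputs, both
ternary: `Fe_ext` (0 = starvation, below 1 µM external iron; 1 = 1–5 µM;
2 = above 5–10 µM) and `O2` (0 = anaerobiosis, 1 = aerobiosis,
2 = oxidative stress, i.e. external H2O2 above 2 µM). The twelve internal
nodes split into three strongly connected process modules — oxidative
stress (`H2O2`, `OxyR`, `Hpx`), iron homeostasis (`Fe_free`, `Fur`,
`RyhB`) and the IscRSUA module (`IscR-A`, `IscR-H`, `Isc`) — plus the
readouts `Suf`, `ErpA` and `NfuA`. IscR is deliberately split into its apo
(`IscR-A`, Suf-activating) and holo (`IscR-H`, Isc-repressing) forms, so
that both expression and Isc-dependent maturation of the regulator are
represented.

Each node carries a discrete level in `0..max`. Non-input nodes have
ordered rules, one Boolean expression per nonzero target level, written in
a small grammar (`Name`, `Name=k`, `Name<k`, `Name>=k`, `!`, `&`, `|`).
Three semantic conventions matter:

* **Rule priority.** Rules are scanned from the highest target level
  downwards; the first expression that holds sets the target, and 0 is the
  default when none does. Under this scan order the two printed variants of
  the Suf level-1 rule (with and without the explicit
  `!(OxyR & IscR-A)` exclusion term) coincide; we encode the explicitly
  exclusive form. For the shipped network the rule rows of every node are
  in fact mutually exclusive at every one of the 279,936 global states —
  the test suite asserts this rather than assuming it.
* **Unitary asynchronous updating.** One node updates per transition, and
  a multivalued node moves one level toward its target rather than jumping
  to it. The source material never states the stepping convention
  explicitly; unitary stepping is the convention of the GINsim/logical
  modeling framework the model was built in, and we adopt it as a design
  decision. All reported behaviors were computed under it.
* **Inputs are clamps.** `Fe_ext` and `O2` are rule-less nodes fixed per
  simulation; they define the nine-condition grid and are never treated as
  free variables, and they cannot be "mutated" — genotypes are clamps over
  internal nodes only.

## Attractor detection

For a given input condition (plus any mutant clamp) the engine enumerates
the full clamped subspace — 3^5 × 2^7 = 31,104 states for a wild-type
condition — in a fixed mixed-radix order (nodes in model order, levels
ascending), evaluates every rule vectorially across all states, and builds
the complete state transition graph. Attractors are the terminal strongly
connected components, computed with `igraph`'s iterative strong-components
routine (no recursion, so subspaces of a few hundred thousand states are
safe). Working over the full subspace rather than from a seed state
matches how the model's one-attractor-per-condition results are reported:
no initial condition is privileged.

Every attractor is summarized per node by the minimum, maximum and
unweighted arithmetic mean of its level over the attractor's states; a
node oscillates iff min < max. The unweighted mean is used deliberately —
it is the quantity shown in the published heatmaps — rather than a mean
weighted by any stationary distribution, which the nondeterministic
asynchronous semantics does not define.

Two independent cross-checks guard the engine. `stable_states_direct()`
finds fixpoints by direct subspace scan, which must equal the size-1
terminal SCCs. And `brute_force_attractors()` recomputes attractors by a
deliberately different route — its own scalar rule evaluator, per-state
breadth-first reachability, and the characterization "s belongs to an
attractor iff every state reachable from s can reach s back" — with no
shared SCC machinery, so a bug in either path surfaces as a disagreement.

## What the random-network generator emulates

`random_model()` produces arbitrary well-formed multivalued networks
(configurable node count, ternary fraction, input count, rule density,
seed) with rules in disjunctive normal form so that the text grammar
round-trips them exactly. Its purpose is engine validation: the oracle
equivalence sweep runs engine and brute-force oracle over dozens of random
models and all their input clamps. These networks are *not* biologically
realistic — no scale-free topology, no signed-regulation consistency, no
module structure — so passing the sweep certifies the dynamics engine, not
any biological claim. Conversely, the biological conclusions rest entirely
on the hand-curated Fe-S network, which is printed in full and shipped
both as a constructor and as a plain-text model file (`fes_model_file()`),
the two being verified identical.

Defaults (6 nodes, 40–50% ternary, one input, density 2) keep oracle
subspaces in the hundreds of states: large enough to contain stable
states, small cycles and large cyclic attractors, small enough that the
quadratic-ish brute-force oracle stays fast. The validation sweeps in the
test suite use 50 models of up to 8 nodes, matching that envelope.

## Behavior classes and screens

A condition's **signature** records, for each of the three process
modules, whether any member node oscillates in the attractor. Class
identity is the three-module signature alone; `Suf`, `ErpA` and `NfuA`
behaviors are reported but do not enter class identity, because the five
qualitative classes are defined purely at the process-module scale, and
the three-module signature yields exactly five distinct patterns on the
wild-type grid. Signatures matching a canonical wild-type pattern get its
Roman numeral (I: none oscillate; II: iron only; III: all but oxidative
stress; IV: all but IscRSUA; V: all three); other models' novel signatures
get subsequent numerals in first-appearance order, deterministically.

The growth-defect screen flags a (mutant, condition) pair when `Isc = 0`
**and** `Suf = 0` in *every* attractor state. The strict all-states
criterion is deliberate: a machinery that is transiently present during an
oscillation still supplies some biogenesis, so only the full-off cases
constitute a predicted defect. Single mutants are enumerated as each
internal node clamped at each of its levels (29 variants for this network:
7 Boolean × 2 + 5 ternary × 3); knock-out-only screens use the 12 clamps
to zero, and the double screen all 66 knock-out pairs. On this network the
single-KO screen flags exactly the apo-IscR and Suf knock-outs, both under
iron starvation, and every defect-bearing double knock-out contains one of
those two.

```{r screen, eval = FALSE}
report <- growth_defect_screen(fes_model())
defective_perturbations(report)
#> [1] "IscR-A KO" "Suf KO"
```

## Numerical and design choices

* **Determinism.** State enumeration order, attractor ordering (by
  smallest member state) and mutant enumeration order are all fixed, so
  CSV exports and test results are bit-reproducible. The generator
  restores the caller's RNG state and derives everything from its own
  seed.
* **Safety limits.** Subspace construction refuses more than 2×10^6 states
  by default (configurable); the brute-force oracle is capped at 10^4.
* **Degenerate inputs.** Models with several attractors per condition are
  supported: `condition_attractor()` returns all of them and flags
  multiplicity, and the atlas refuses to summarize such conditions
  silently.
* **Edge counting.** The network's node count (14) is asserted
  structurally, but the printed interaction count (28) is not: rule-derived
  (regulator, target) pairs total 29 — `Fe_free` has six textual
  regulators — and drawn-arc conventions can legitimately differ from
  rule-text conventions, so the dependency graph is exposed
  (`dependency_graph()`) without enforcing a total.
* **One known looseness.** The narrative description of `Suf` at the
  mid-level condition ("oscillating between 0 and 1") conflicts with that
  condition being a stable state; under the encoded rules the (1,1)
  attractor is a fixpoint with `Suf = 1`, and the stable-state account is
  taken as governing.

## Problem sizes and limitations

All wild-type and mutant atlases run over full 31,104-state (or smaller,
once mutant clamps shrink the subspace) condition subspaces; the complete
double-knock-out screen builds roughly 600 transition graphs and finishes
in well under a minute, and the oracle sweeps use models of at most 8
nodes. The package does not implement synchronous or priority-class
updating, rate-weighted stochastic semantics, basin-of-attraction or
reachability-from-state analyses, or hierarchical transition graph
compaction — terminal-SCC detection over the full subspace suffices for
every quantity reported here. Being a qualitative formalism, the model
speaks to presence, absence and oscillation of activities, not to
concentrations or time scales; oscillation amplitudes and periods in the
attractors should be read as homeostatic regulation, not as predictions of
measurable periodic expression.
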