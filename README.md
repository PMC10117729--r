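# fesnet

Qualitative logical modeling of the regulatory network that controls
iron–sulfur (Fe-S) cluster biogenesis in *Escherichia coli*.

Fe-S clusters are essential cofactors whose assembly is handled by two
machineries — Isc (housekeeping) and Suf (stress) — under the joint control
of the IscR transcription factor (apo and holo forms), iron homeostasis
(free iron, Fur, the small RNA RyhB) and the peroxide stress response
(H2O2, OxyR, the Hpx catalases/peroxidases). `fesnet` encodes this network
as a 14-node multivalued logical (Thomas) model with two ternary
environmental inputs, external iron `Fe_ext` and oxygen `O2`, and analyzes
its asynchronous dynamics. It is aimed at systems biologists who want to
reproduce, probe or extend the model, and at anyone who needs a small,
dependency-light engine for multivalued logical networks in R.

## The formalism

Each node *v* carries a discrete level in `0..max(v)` (Boolean or ternary).
Its ordered rules map target levels to Boolean expressions over regulator
levels; scanning the rules from the highest target level down, the first
expression that holds gives the node's **target level**, with 0 as the
default. Dynamics are **unitary asynchronous**: from a state *x*, each node
whose target differs from its current level yields one successor in which
that node has moved a single level toward the target. The resulting state
transition graph (STG) over a clamped subspace (inputs fixed, mutants
clamped) has as its **attractors** the terminal strongly connected
components: size-1 attractors are stable states, larger ones are
homeostatic oscillations. Per node, an attractor is summarized by the
min/max/mean of its level over the attractor states.

## Worked example

```r
library(fesnet)

atlas <- wildtype_atlas()
atlas
#> Condition atlas (FeS_biogenesis), 9 conditions
#>   Fe_ext=0,O2=0    cyclic       size 12
#>   Fe_ext=0,O2=1    cyclic       size 12
#>   Fe_ext=0,O2=2    cyclic       size 168
#>   Fe_ext=1,O2=0    cyclic       size 512
#>   Fe_ext=1,O2=1    stable_state size 1
#>   Fe_ext=1,O2=2    cyclic       size 9792
#>   Fe_ext=2,O2=0    cyclic       size 512
#>   Fe_ext=2,O2=1    cyclic       size 512
#>   Fe_ext=2,O2=2    cyclic       size 9792
```

Eight of the nine environmental conditions settle into cyclic attractors
(homeostatic oscillations); only the unstressed mid-level condition
(`Fe_ext=1, O2=1`) is a stable state. Classifying each condition by which
of the three process modules oscillates recovers five behavior classes:

```r
classify_grid(atlas)
#>       condition Fe_ext O2 oxidative_stress  iron iscrsua class
#> 1 Fe_ext=0,O2=0      0  0            FALSE  TRUE   FALSE    II
#> 2 Fe_ext=0,O2=1      0  1            FALSE  TRUE   FALSE    II
#> 3 Fe_ext=0,O2=2      0  2             TRUE  TRUE   FALSE    IV
#> 4 Fe_ext=1,O2=0      1  0            FALSE  TRUE    TRUE   III
#> 5 Fe_ext=1,O2=1      1  1            FALSE FALSE   FALSE     I
#> 6 Fe_ext=1,O2=2      1  2             TRUE  TRUE    TRUE     V
#> 7 Fe_ext=2,O2=0      2  0            FALSE  TRUE    TRUE   III
#> 8 Fe_ext=2,O2=1      2  1            FALSE  TRUE    TRUE   III
#> 9 Fe_ext=2,O2=2      2  2             TRUE  TRUE    TRUE     V
```

Mutants are clamps over internal nodes. The knock-out screen flags a
predicted growth defect when both machineries are fully off (`Isc = 0` and
`Suf = 0` in every attractor state):

```r
growth_defect_screen(fes_model())
#> Growth-defect screen: 12 perturbations x 9 conditions
#>   defect-flagged: IscR-A KO, Suf KO
#>     IscR-A KO at Fe_ext=0, O2=0
#>     IscR-A KO at Fe_ext=0, O2=1
#>     IscR-A KO at Fe_ext=1, O2=1
#>     Suf KO at Fe_ext=0, O2=0
#>     Suf KO at Fe_ext=0, O2=1
#>     Suf KO at Fe_ext=0, O2=2
#>     Suf KO at Fe_ext=1, O2=1
```

Only the apo-IscR and Suf knock-outs lose both Fe-S assembly routes, and
they do so under iron starvation — the model's testable growth-defect
prediction. `heatmap_table(atlas)` exports the per-node mean/oscillation
grid behind the heatmaps, `plot(atlas)` draws it, and
`mutant_atlas(fes_model(), perturbation(c(Fur = 0L, OxyR = 0L)))` gives
any mutant the same nine-condition treatment.

The engine is generic: `read_model()`/`write_model()` handle plain-text
model definitions (the Fe-S network ships as `fes_model_file()`),
`random_model()` generates reproducible random multivalued networks, and
`brute_force_attractors()` is an independent oracle used to validate the
terminal-SCC engine.

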