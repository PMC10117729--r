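# Shared fixtures: tiny hand-built models plus cached Fe-S computations
# (the wild-type atlas and mutant atlases are reused across test files).

# one Boolean node repressing itself: the minimal oscillator
self_inhibitor <- function() {
  logical_model(list(node_spec("x", 1, rules = list("1" = "!x"))),
                name = "self_inhibitor")
}

# one Boolean node activating itself: two stable states
self_activator <- function() {
  logical_model(list(node_spec("x", 1, rules = list("1" = "x"))),
                name = "self_activator")
}

# ternary node pulled towards 2 whenever the Boolean input is off
ternary_ramp <- function() {
  logical_model(list(
    node_spec("u", 1, input = TRUE),
    node_spec("y", 2, rules = list("2" = "!u"))
  ), name = "ternary_ramp")
}

.cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.cache[[key]])) .cache[[key]] <- fn()
  .cache[[key]]
}

fes <- function() cached("fes", fes_model)
wt_atlas <- function() cached("wt_atlas", wildtype_atlas)
oxyr_atlas <- function() cached("oxyr_atlas", function() {
  mutant_atlas(fes(), perturbation(c(OxyR = 0L), fes()))
})
fur_atlas <- function() cached("fur_atlas", function() {
  mutant_atlas(fes(), perturbation(c(Fur = 0L), fes()))
})
double_atlas <- function() cached("double_atlas", function() {
  mutant_atlas(fes(), perturbation(c(Fur = 0L, OxyR = 0L), fes()))
})
ko_screen <- function() cached("ko_screen", function() {
  growth_defect_screen(fes())
})
double_screen <- function() cached("double_screen", function() {
  growth_defect_screen(fes(), enumerate_double_kos(fes()))
})

# normalized attractor representation for set-of-sets comparisons
attractor_keys <- function(atts) {
  sort(vapply(atts, function(a) {
    paste(apply(a$states, 1, paste, collapse = ","), collapse = ";")
  }, character(1)))
}

# all-input clamps of a model at a common level (helper for oracle sweeps)
input_clamps <- function(model) {
  iv <- input_nodes_of(model)
  if (!length(iv)) return(list(stats::setNames(integer(0), character(0))))
  ml <- vapply(model$nodes[iv], function(n) n$max_level, integer(1))
  grid <- expand.grid(lapply(ml, function(k) 0:k))
  lapply(seq_len(nrow(grid)), function(i) {
    stats::setNames(as.integer(grid[i, ]), iv)
  })
}

input_nodes_of <- function(model) {
  nms <- names(model$nodes)
  nms[vapply(model$nodes, function(n) n$input, logical(1))]
}
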