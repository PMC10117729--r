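test_that("toy transition graphs have the forced structure", {
  # self-inhibitor: two states chasing each other -> one cyclic attractor
  stg <- build_stg(self_inhibitor(), integer(0))
  expect_equal(nrow(stg$states), 2)
  expect_equal(nrow(stg$edges), 2)
  atts <- terminal_sccs(stg)
  expect_length(atts, 1)
  expect_equal(atts[[1]]$kind, "cyclic")
  expect_equal(atts[[1]]$size, 2)

  # self-activator: both states are fixpoints
  atts2 <- terminal_sccs(build_stg(self_activator(), integer(0)))
  expect_length(atts2, 2)
  expect_true(all(vapply(atts2, function(a) a$kind, character(1)) ==
                    "stable_state"))

  # unitary ramp: 0 -> 1 -> 2 when the input is off; sink has out-degree 0
  stg3 <- build_stg(ternary_ramp(), c(u = 0L))
  expect_equal(nrow(stg3$states), 3)
  expect_equal(nrow(stg3$edges), 2)
  sink <- terminal_sccs(stg3)
  expect_length(sink, 1)
  expect_equal(sink[[1]]$states[, "y"], 2L, ignore_attr = TRUE)
  expect_false(sink[[1]]$first_index %in% stg3$edges[, "from"])
})

test_that("attractors are disjoint, terminal, and terminality matters", {
  stg <- build_stg(fes(), c(Fe_ext = 2L, O2 = 0L))
  atts <- terminal_sccs(stg)
  all_rows <- unlist(lapply(atts, function(a) {
    fesnet:::state_index(a$states, stg$model, stg$clamp)$index
  }))
  expect_equal(anyDuplicated(all_rows), 0)
  # no edge leaves an attractor
  inside <- stg$edges[, "from"] %in% all_rows
  expect_true(all(stg$edges[inside, "to"] %in% all_rows))
  # negative control: non-terminal SCCs exist (dropping terminality would
  # strictly enlarge the component list) on the self-activator with a
  # transient: here, the full Fe-S STG has far more SCCs than attractors
  g <- igraph::make_empty_graph(nrow(stg$states), directed = TRUE)
  g <- igraph::add_edges(g, t(stg$edges))
  n_scc <- igraph::components(g, mode = "strong")$no
  expect_gt(n_scc, length(atts))
})

test_that("the wild type has one attractor per condition, stable only at (1,1)", {
  atlas <- wt_atlas()
  expect_length(atlas$entries, 9)
  expect_false(any(vapply(atlas$entries, function(e) e$multiple, logical(1))))
  kinds <- vapply(atlas$entries, function(e) e$attractor$kind, character(1))
  expect_identical(unname(kinds[["Fe_ext=1,O2=1"]]), "stable_state")
  expect_equal(sum(kinds == "cyclic"), 8)

  # the (1,1) fixpoint, solved independently from the rules by direct scan
  fix <- stable_states_direct(fes(), c(Fe_ext = 1L, O2 = 1L))
  expect_equal(nrow(fix), 1)
  expect_equal(fix[1, ], c(Fe_ext = 1L, O2 = 1L, Fe_free = 1L, H2O2 = 0L,
                           OxyR = 0L, Hpx = 1L, Fur = 1L, RyhB = 1L,
                           "IscR-A" = 1L, "IscR-H" = 0L, Isc = 0L,
                           Suf = 1L, ErpA = 1L, NfuA = 1L))
  expect_equal(atlas$entries[["Fe_ext=1,O2=1"]]$attractor$states[1, ],
               fix[1, ])
})

test_that("direct stable-state scan agrees with size-1 terminal SCCs", {
  # on the Fe-S grid
  for (cond in fes_conditions()) {
    direct <- stable_states_direct(fes(), cond)
    atts <- terminal_sccs(build_stg(fes(), cond))
    stable <- Filter(function(a) a$size == 1L, atts)
    expect_equal(nrow(direct), length(stable))
    if (length(stable)) {
      got <- do.call(rbind, lapply(stable, function(a) a$states))
      expect_equal(got[order(got[, 1]), , drop = FALSE],
                   direct[order(direct[, 1]), , drop = FALSE],
                   ignore_attr = TRUE)
    }
  }
  # (0,0) has no stable state at all; the self-activator has two
  expect_equal(nrow(stable_states_direct(fes(), c(Fe_ext = 0L, O2 = 0L))), 0)
  expect_equal(nrow(stable_states_direct(self_activator())), 2)
})

test_that("asymptotic summaries respect min <= mean <= max and oscillation", {
  atlas <- wt_atlas()
  for (e in atlas$entries) {
    s <- e$summary
    expect_true(all(s$min <= s$mean & s$mean <= s$max))
    expect_identical(s$oscillating, s$min < s$max)
    ml <- vapply(fes()$nodes[s$node], function(n) n$max_level, integer(1))
    expect_true(all(s$mean >= 0 & s$mean <= ml))
  }
  # a two-state oscillation averages midway
  a <- terminal_sccs(build_stg(self_inhibitor(), integer(0)))[[1]]
  s <- summary(a)
  expect_equal(s$mean, 0.5)
  expect_true(s$oscillating)
})

test_that("free-iron asymptotics track the external iron regime", {
  atlas <- wt_atlas()
  for (cn in names(atlas$entries)) {
    e <- atlas$entries[[cn]]
    s <- e$summary
    fe <- s[s$node == "Fe_free", ]
    if (e$inputs[["Fe_ext"]] == 0) {
      expect_lte(fe$max, 1)  # rises between 0 and 1 in starvation
    } else if (e$inputs[["Fe_ext"]] == 2) {
      expect_gte(fe$min, 1)  # falls between 2 and 1 otherwise
    }
    # peroxide is absent below oxidative stress
    if (e$inputs[["O2"]] <= 1) {
      expect_equal(s$max[s$node == "H2O2"], 0)
    }
  }
})

test_that("multiplicity is flagged, never dropped", {
  res <- condition_attractor(self_activator(), integer(0))
  expect_false(inherits(res, "attractor"))
  expect_true(attr(res, "multiple"))
  expect_length(res, 2)
})
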