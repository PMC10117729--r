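# A reference state for hand evaluation of single rules
ref_state <- function(...) {
  st <- c(Fe_ext = 0L, O2 = 0L, Fe_free = 0L, H2O2 = 0L, OxyR = 0L,
          Hpx = 1L, Fur = 0L, RyhB = 0L, "IscR-A" = 0L, "IscR-H" = 0L,
          Isc = 0L, Suf = 0L, ErpA = 0L, NfuA = 0L)
  over <- c(...)
  st[names(over)] <- over
  st
}

test_that("target_level scans rules highest-first with default 0", {
  m <- fes()
  # holo-IscR forms when apo-IscR, Isc present and no peroxide
  expect_equal(target_level(m, "IscR-H",
                            ref_state("IscR-A" = 1L, Isc = 1L, H2O2 = 0L)), 1)
  expect_equal(target_level(m, "IscR-H",
                            ref_state("IscR-A" = 1L, Isc = 1L, H2O2 = 1L)), 0)
  # RyhB fully derepressed when Fur is off
  expect_equal(target_level(m, "RyhB", ref_state(Fur = 0L)), 2)
  expect_equal(target_level(m, "RyhB", ref_state(Fur = 1L)), 1)
  # no rule satisfied -> 0
  expect_equal(target_level(m, "NfuA", ref_state("IscR-H" = 1L)), 0)
  expect_error(target_level(m, "NoSuchNode", ref_state()), "unknown node")
  expect_error(target_level(m, "Fe_ext", ref_state()), "input")
})

test_that("Fe_free targets match hand evaluation of the printed disjunctions", {
  m <- fes()
  # medium external iron, aerobic, Fur partial, no peroxide -> level 1
  # (third disjunct of the level-1 rule)
  expect_equal(target_level(m, "Fe_free",
                            ref_state(Fe_ext = 1L, O2 = 1L, Fur = 1L)), 1)
  # high external iron with Fur below full repression -> level 2
  expect_equal(target_level(m, "Fe_free",
                            ref_state(Fe_ext = 2L, Fur = 1L)), 2)
  # high external iron, full Fur repression, RyhB low -> level 1
  expect_equal(target_level(m, "Fe_free",
                            ref_state(Fe_ext = 2L, Fur = 2L, RyhB = 1L)), 1)
  # starvation, sparing response at full strength -> level 1
  expect_equal(target_level(m, "Fe_free",
                            ref_state(Fe_ext = 0L, RyhB = 2L)), 1)
  # starvation without sparing or peroxide -> decays to 0
  expect_equal(target_level(m, "Fe_free", ref_state(Fe_ext = 0L)), 0)
})

test_that("at most one target rule holds per node across the whole space", {
  # mutual exclusivity of the encoded rule rows, asserted over all states
  m <- fes()
  S <- enumerate_states(m)
  for (nd in m$nodes) {
    if (length(nd$rules) < 2) next
    hits <- rowSums(vapply(nd$rules,
                           function(r) fesnet:::eval_expr(r$expr, S),
                           logical(nrow(S))))
    expect_lte(max(hits), 1)
  }
})

test_that("successors implement unitary asynchronous updating", {
  m <- fes()
  # stable state: no successors
  fix <- ref_state(Fe_ext = 1L, O2 = 1L, Fe_free = 1L, Hpx = 1L, Fur = 1L,
                   RyhB = 1L, "IscR-A" = 1L, Suf = 1L, ErpA = 1L, NfuA = 1L)
  expect_length(successors(m, fix, c(Fe_ext = 1L, O2 = 1L)), 0)

  # a ternary node steps one level toward its target, not directly to it
  st <- ref_state(Fur = 0L, RyhB = 0L)  # RyhB target is 2
  succ <- successors(m, st, c(Fe_ext = 0L, O2 = 0L))
  ryhb_next <- Filter(function(s) s[["RyhB"]] != 0L, succ)
  expect_length(ryhb_next, 1)
  expect_equal(ryhb_next[[1]][["RyhB"]], 1)

  # every successor differs in exactly one node by exactly one level,
  # and their count equals the number of nodes off target
  clamp <- c(Fe_ext = 2L, O2 = 2L)
  set.seed(7)
  S <- enumerate_states(m, clamp)
  for (i in sample(nrow(S), 25)) {
    st <- S[i, ]
    succ <- successors(m, st, clamp)
    n_off <- sum(vapply(internal_nodes(m), function(v) {
      target_level(m, v, st) != st[[v]]
    }, logical(1)))
    expect_length(succ, n_off)
    for (s2 in succ) {
      d <- abs(s2 - st)
      expect_equal(sum(d), 1)
      expect_equal(max(d), 1)
      expect_equal(unname(s2[names(clamp)]), unname(clamp))
    }
  }
})

test_that("state enumeration covers the clamped subspace exactly once", {
  m <- fes()
  expect_equal(nrow(enumerate_states(m)), 279936)  # 3^7 * 2^7
  S <- enumerate_states(m, c(Fe_ext = 0L, O2 = 2L))
  expect_equal(nrow(S), 31104)                     # 3^5 * 2^7
  expect_equal(anyDuplicated(S), 0)
  expect_true(all(S[, "Fe_ext"] == 0L & S[, "O2"] == 2L))

  one <- logical_model(list(node_spec("b", 1, rules = list("1" = "b"))))
  expect_equal(nrow(enumerate_states(one)), 2)

  # exact count on assorted small models
  for (seed in 1:5) {
    rm_ <- random_model(generator_config(5, 0.6, 1, 2, seed = seed))
    ml <- vapply(rm_$nodes, function(n) n$max_level, integer(1))
    S <- enumerate_states(rm_)
    expect_equal(nrow(S), prod(ml + 1))
    expect_equal(anyDuplicated(S), 0)
  }

  expect_error(enumerate_states(m, limit = 1000), "limit")
  expect_error(enumerate_states(m, c(Fe_ext = 5L, O2 = 0L)), "out of range")
  expect_error(successors(m, ref_state(), c(Fe_ext = 1L, O2 = 0L)),
               "disagrees")
})
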