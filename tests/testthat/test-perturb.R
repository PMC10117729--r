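test_that("perturbations are validated clamps over internal nodes", {
  m <- fes()
  p <- perturbation(c(Fur = 0L), m)
  expect_equal(p$label, "Fur KO")
  expect_equal(perturbation(c(Suf = 2L), m)$label, "Suf=2")
  expect_error(perturbation(c(Fe_ext = 0L), m), "input")
  expect_error(perturbation(c(Fur = 9L), m), "out of range")
  # Hpx KO is expressible: level 0 is reserved for exactly that
  expect_silent(perturbation(c(Hpx = 0L), m))

  # composition is clamp union; conflicts are errors
  q <- combine_perturbations(perturbation(c(Fur = 0L), m),
                             perturbation(c(OxyR = 0L), m), m)
  expect_equal(q$clamp, c(Fur = 0L, OxyR = 0L))
  expect_error(combine_perturbations(perturbation(c(Fur = 0L), m),
                                     perturbation(c(Fur = 2L), m), m),
               "conflicting")
})

test_that("mutant enumeration follows the per-level scheme", {
  m <- fes()
  single <- enumerate_single_mutants(m)
  expect_length(single, 29)  # 7 Boolean x 2 + 5 ternary x 3 internal nodes
  labs <- vapply(single, function(p) p$label, character(1))
  expect_equal(anyDuplicated(labs), 0)
  expect_length(enumerate_single_mutants(m, ko_only = TRUE), 12)
  expect_length(enumerate_double_kos(m), 66)

  one <- logical_model(list(node_spec("b", 1, rules = list("1" = "b"))))
  expect_length(enumerate_single_mutants(one), 2)
})

test_that("clamped nodes are constant in every mutant attractor state", {
  m <- fes()
  p <- perturbation(c(Fur = 0L, OxyR = 0L), m)
  for (cn in c("Fe_ext=0,O2=0", "Fe_ext=2,O2=2")) {
    a <- double_atlas()$entries[[cn]]$attractor
    expect_true(all(a$states[, "Fur"] == 0L))
    expect_true(all(a$states[, "OxyR"] == 0L))
  }
  # Fur KO forces full RyhB derepression in every condition
  for (e in fur_atlas()$entries) {
    expect_true(all(e$attractor$states[, "RyhB"] == 2L))
  }
})

test_that("single-module knockouts reproduce the predicted readouts", {
  # OxyR KO: under oxidative stress ErpA off, Suf at its medium level,
  # peroxide stuck on
  for (e in oxyr_atlas()$entries) {
    s <- e$summary
    if (e$inputs[["O2"]] == 2) {
      expect_equal(s$min[s$node == "ErpA"], 0)
      expect_equal(s$max[s$node == "ErpA"], 0)
      expect_equal(s$min[s$node == "Suf"], 1)
      expect_equal(s$max[s$node == "Suf"], 1)
      expect_equal(s$min[s$node == "H2O2"], 1)
    }
  }
  # Fur KO: Isc fully off everywhere, Suf turned up, H2O2 as in the WT
  wt <- wt_atlas()
  for (cn in names(fur_atlas()$entries)) {
    s <- fur_atlas()$entries[[cn]]$summary
    expect_equal(s$max[s$node == "Isc"], 0)
    expect_gte(s$min[s$node == "Suf"], 1)
    swt <- wt$entries[[cn]]$summary
    expect_equal(s[s$node == "H2O2", c("min", "max", "mean")],
                 swt[swt$node == "H2O2", c("min", "max", "mean")],
                 ignore_attr = TRUE)
  }
  # Fur+OxyR double KO: NfuA constitutively on, ErpA off
  for (e in double_atlas()$entries) {
    s <- e$summary
    expect_equal(s$min[s$node == "NfuA"], 1)
    expect_equal(s$max[s$node == "ErpA"], 0)
  }
})

test_that("growth-defect screen flags the two vulnerable knockouts", {
  rep1 <- ko_screen()
  flagged <- defective_perturbations(rep1)
  expect_setequal(flagged, c("IscR-A KO", "Suf KO"))
  # wild-type baseline is never flagged
  expect_false(any(rep1$defect[rep1$perturbation == "WT"]))
  # Suf KO is flagged at every iron-starvation condition
  suf_rows <- unique(rep1[rep1$perturbation == "Suf KO" & rep1$defect,
                          c("Fe_ext", "O2")])
  expect_true(all(c(0, 1, 2) %in% suf_rows$O2[suf_rows$Fe_ext == 0]))
  # IscR-A KO is flagged under iron starvation
  iscr_rows <- unique(rep1[rep1$perturbation == "IscR-A KO" & rep1$defect,
                           c("Fe_ext", "O2")])
  expect_true(any(iscr_rows$Fe_ext == 0))
  # defect flags are recomputable from the stored summaries
  chk <- stats::aggregate(max ~ perturbation + Fe_ext + O2,
                          data = rep1[rep1$node %in% c("Isc", "Suf"), ],
                          FUN = max)
  for (i in seq_len(nrow(chk))) {
    rows <- rep1$perturbation == chk$perturbation[i] &
      rep1$Fe_ext == chk$Fe_ext[i] & rep1$O2 == chk$O2[i]
    expect_equal(all(chk$max[i] == 0), unique(rep1$defect[rows]))
  }
})

test_that("every defect-bearing knockout pair contains IscR-A or Suf", {
  flagged <- defective_perturbations(double_screen())
  expect_gt(length(flagged), 0)
  expect_true(all(grepl("IscR-A KO|Suf KO", flagged)))
})
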