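# Molecular formulas, graphs, canonicalization and isomorphism.

test_that("Hill-notation formulas parse, render and validate", {
  f <- parse_formula("C32H22N4O")
  expect_equal(unclass(f)[c("C", "H", "N", "O")], c(C = 32L, H = 22L, N = 4L, O = 1L))
  expect_equal(format(f), "C32H22N4O")
  expect_equal(unclass(parse_formula("C"))[["C"]], 1L)
  expect_equal(unclass(parse_formula("C16H10N2O2"))[["O"]], 2L)
  # round trip through the text rendering
  for (s in c("C2H6O", "C10H14", "C8H10N4O2", "CH4"))
    expect_equal(format(parse_formula(s)), format(parse_formula(format(parse_formula(s)))))
  expect_error(parse_formula("C2Xx4"), "unknown element")
  expect_error(parse_formula("H2"), "non-hydrogen")
})

test_that("nominal mass matches the protonated-ion bookkeeping", {
  expect_equal(nominal_mass("C32H22N4O"), 478)   # MH+ at 479
  expect_equal(nominal_mass(parse_formula("C20H32O2")), 304)
  expect_equal(nominal_mass("CH4"), 16)
})

test_that("degree of unsaturation follows (2C + 2 + N - H - X)/2", {
  expect_equal(degree_of_unsaturation("C16H10N2O2"), 13)
  expect_equal(degree_of_unsaturation("C20H32O2"), 5)
  expect_equal(degree_of_unsaturation("CH4"), 0)
  expect_warning(dbe <- degree_of_unsaturation("C16H11BrN3O2"),
                 "half-integer")
  expect_equal(dbe, 12.5)
  expect_error(degree_of_unsaturation("C2H10"), "negative")
})

test_that("molecular graph validation enforces valence closure and connectivity", {
  expect_error(molgraph(c("C", "C"), c(4L, 4L), NULL), "connected")
  expect_error(molgraph(c("C", "C"), c(4L, 2L), rbind(c(1, 2, 1))), "valence")
  expect_error(molgraph("C", 4L, rbind(c(1, 1, 1))), "self-bonds")
  g <- molgraph(c("C", "C"), c(3L, 3L), rbind(c(1, 2, 1)))
  expect_equal(format(graph_formula(g)), "C2H6")
})

test_that("canonical keys are relabeling-invariant and separate non-isomorphs", {
  expect_equal(canonical_key(butane_graph()),
               canonical_key(random_relabel(butane_graph(), 7)))
  expect_false(canonical_key(butane_graph()) == canonical_key(isobutane_graph()))
  keys <- vapply(1:12, function(s) canonical_key(random_relabel(benzene_graph(), s)),
                 character(1))
  expect_equal(length(unique(keys)), 1L)
  expect_false(canonical_key(ethanol_graph()) == canonical_key(dme_graph()))
})

test_that("canonical_key is permutation-invariant over random molecules", {
  for (s in 1:40) {
    g <- random_molecule(sample(4:8, 1), seed = s)
    keys <- vapply(1:5, function(r) canonical_key(random_relabel(g, s * 100 + r)),
                   character(1))
    expect_equal(length(unique(keys)), 1L, info = sprintf("seed %d", s))
  }
})

test_that("are_isomorphic agrees with the independent backtracking matcher", {
  pool <- lapply(1:25, function(s) random_molecule(sample(4:8, 1), seed = 1000 + s))
  pool <- c(pool, list(butane_graph(), isobutane_graph(), ethanol_graph(),
                       dme_graph(), benzene_graph()))
  for (a in seq_along(pool)) {
    for (b in seq(a, length(pool))) {
      g1 <- pool[[a]]; g2 <- pool[[b]]
      if (length(g1$elements) != length(g2$elements)) next
      expect_equal(are_isomorphic(g1, g2), oracle_isomorphic(g1, g2),
                   info = sprintf("pair %d-%d", a, b))
    }
  }
  expect_true(are_isomorphic(butane_graph(), random_relabel(butane_graph(), 3)))
  expect_error(are_isomorphic(molgraph("C", 4L, NULL), NULL))
})

test_that("SDF round trip preserves structure and assigned shifts", {
  g <- ethanol_graph()
  tmp <- tempfile(fileext = ".sdf")
  write_sdf(list(g, benzene_graph()), tmp, titles = c("ethanol", "benzene"))
  recs <- read_sdf(tmp)
  expect_length(recs, 2L)
  expect_true(are_isomorphic(recs[[1]]$graph, g))
  expect_equal(recs[[1]]$graph$shifts[1:2], g$shifts[1:2], tolerance = 1e-4)
  expect_true(are_isomorphic(recs[[2]]$graph, benzene_graph()))
})

test_that("our SDF output parses identically through ChemmineR", {
  skip_if_not_installed("ChemmineR")
  tmp <- tempfile(fileext = ".sdf")
  write_sdf(list(butane_graph(), benzene_graph()), tmp)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  bb <- ChemmineR::bondblock(sdfs[[2]])
  expect_equal(nrow(bb), 6L)             # benzene bonds
  expect_equal(sort(as.integer(bb[, 3])), c(1L, 1L, 1L, 2L, 2L, 2L))
})
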