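# Environment codes, shift databases, incremental prediction, optimal
# assignment deviations, duplicate removal and ranking.

test_that("environment codes respect molecular symmetry and relabeling", {
  bz <- benzene_graph()
  for (d in 1:4) {
    codes <- vapply(1:6, function(a) hose_code(bz, a, d), character(1))
    expect_equal(length(unique(codes)), 1L)
  }
  neo <- molgraph(rep("C", 5), c(0L, 3L, 3L, 3L, 3L),
                  rbind(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1), c(1, 5, 1)))
  codes <- vapply(1:5, function(a) hose_code(neo, a, 4), character(1))
  expect_equal(length(unique(codes)), 2L)
  g <- random_molecule(7, seed = 5)
  gr <- random_relabel(g, 6)
  # each carbon's code survives relabeling somewhere in the permuted graph
  carbons_g <- which(g$elements == "C")
  carbons_gr <- which(gr$elements == "C")
  codes_g <- vapply(carbons_g, function(a) hose_code(g, a, 3), character(1))
  codes_gr <- vapply(carbons_gr, function(a) hose_code(gr, a, 3), character(1))
  expect_setequal(unique(codes_g), unique(codes_gr))
  expect_error(hose_code(ethanol_graph(), 3, 2), "carbon")
})

test_that("shift databases store every sphere depth with running statistics", {
  g <- ethanol_graph()
  db <- build_shift_db(list(g))
  # 2 inequivalent carbons x 4 depths
  expect_equal(db_size(db), 8L)
  db2 <- build_shift_db(list(g, g))
  expect_equal(db_size(db2), 8L)
  e1 <- casenmr:::db_lookup(db2, hose_code(g, 1, 4))
  expect_equal(e1$n, 2L)
  expect_equal(e1$mean, g$shifts[1])
  expect_error(build_shift_db(list(molgraph("C", 4L, NULL))), "unassigned")
})

test_that("leave-in prediction reproduces stored shifts exactly", {
  mols <- cached_fixtures()
  db <- cached_shift_db()
  for (nm in c("indole", "vanillin", "menthone_like")) {
    g <- mols[[nm]]
    pred <- predict_c13_hose(g, db)
    expect_equal(pred$shift, g$shifts[pred$atom], tolerance = 1e-9,
                 info = nm)
    expect_true(all(pred$matched_depth == 4L))
  }
  # held-out molecule: all carbons still matched at some depth, deviations finite
  held <- mols$coumarin
  db_rest <- build_shift_db(unname(mols[setdiff(names(mols), "coumarin")]))
  pred <- predict_c13_hose(held, db_rest)
  expect_true(all(is.finite(pred$shift)))
  expect_true(any(pred$matched_depth < 4L))
  # empty database: defaults plus flags
  pred0 <- predict_c13_hose(held, casenmr:::new_shift_db())
  expect_true(all(pred0$matched_depth == 0L))
})

test_that("shift databases round trip through the text table", {
  db <- cached_shift_db()
  tmp <- tempfile(fileext = ".tsv")
  write_shift_db(db, tmp)
  back <- read_shift_db(tmp)
  expect_equal(db_size(back), db_size(db))
  g <- cached_fixtures()$quinoline
  expect_equal(predict_c13_hose(g, back)$shift, predict_c13_hose(g, db)$shift,
               tolerance = 1e-3)
})

test_that("incremental prediction is additive in the table entries", {
  tab <- load_increments()
  methane <- molgraph("C", 4L, NULL)
  expect_equal(predict_c13_incremental(methane, tab)$shift, tab$sp3$base)
  ethane <- molgraph(c("C", "C"), c(3L, 3L), rbind(c(1, 2, 1)))
  expect_equal(predict_c13_incremental(ethane, tab)$shift[1],
               tab$sp3$base + tab$sp3$alpha_C)
  propane <- molgraph(rep("C", 3), c(3L, 2L, 3L),
                      rbind(c(1, 2, 1), c(2, 3, 1)))
  p <- predict_c13_incremental(propane, tab)$shift
  # terminal carbon gains exactly one beta increment over ethane's
  expect_equal(p[1] - (tab$sp3$base + tab$sp3$alpha_C), tab$sp3$beta_C)
  # central carbon has two alpha neighbors
  expect_equal(p[2], tab$sp3$base + 2 * tab$sp3$alpha_C)
})

test_that("deviation is an assignment optimum, not a positional comparison", {
  obs <- function(shifts, mult = NA) data.frame(shift = shifts,
                                                multiplicity = mult,
                                                degeneracy = 1L)
  expect_equal(deviation(c(10, 20), obs(c(20, 10))), 0)
  expect_equal(deviation(c(10, 20), obs(c(10, 20))), 0)
  expect_gt(deviation(c(10, 20), obs(c(12, 20))), 0)
  expect_error(deviation(c(10, 20), obs(30)), "count mismatch")
  # multiplicity classes restrict the polytope
  d_free <- deviation(c(10, 30), obs(c(12, 28)), respect_multiplicity = FALSE)
  d_cls <- deviation(c(10, 30), data.frame(shift = c(12, 28),
                                           multiplicity = c("CH2", "CH3"),
                                           degeneracy = 1L),
                     multiplicities = c("CH3", "CH2"))
  expect_gt(d_cls, d_free)
})

test_that("assignment deviation equals the exhaustive-permutation minimum", {
  set.seed(11)
  for (trial in 1:60) {
    n <- sample(2:7, 1)
    pred <- runif(n, 0, 200)
    obsv <- runif(n, 0, 200)
    d <- deviation(pred, data.frame(shift = obsv, multiplicity = NA,
                                    degeneracy = 1L))
    expect_equal(d, oracle_min_assignment(pred, obsv), tolerance = 1e-9)
  }
})

test_that("duplicate removal keeps each family's best-assigned member", {
  g1 <- butane_graph()
  g2 <- random_relabel(butane_graph(), 4)
  obs <- data.frame(shift = c(13.2, 25.0, 25.0, 13.2),
                    multiplicity = c("CH3", "CH2", "CH2", "CH3"),
                    degeneracy = 1L)
  cands <- list(list(graph = g1, d_I = 2.0), list(graph = g2, d_I = 1.5),
                list(graph = isobutane_graph(), d_I = 3.0))
  out <- remove_duplicates(cands, obs)
  expect_length(out, 2L)
  expect_equal(out[[1]]$d_I, 1.5)            # min of the duplicate family
  expect_equal(out[[2]]$d_I, 3.0)
  # all-distinct list passes through unchanged
  out2 <- remove_duplicates(list(list(graph = g1, d_I = 1),
                                 list(graph = isobutane_graph(), d_I = 2)), obs)
  expect_length(out2, 2L)
})

test_that("ranking is deterministic and flags suspicious best candidates", {
  suite <- cached_suite()
  cs <- Filter(function(x) x$name == "vanillin" && x$kind == "clean", suite)[[1]]
  set <- match_shifts(cs$simulated)
  out <- generate(build_mcd(set))
  db <- cached_shift_db()
  r1 <- rank_candidates(out, set$peaks_c13, db = db,
                        observed_h1 = set$peaks_h1)
  set.seed(3)
  r2 <- rank_candidates(sample(out), set$peaks_c13, db = db,
                        observed_h1 = set$peaks_h1)
  k1 <- vapply(r1, function(x) canonical_key(x$graph), character(1))
  k2 <- vapply(r2, function(x) canonical_key(x$graph), character(1))
  expect_equal(k1, k2)
  expect_equal(vapply(r1, `[[`, numeric(1), "rank"), seq_along(r1))
  expect_equal(canonical_key(r1[[1]]$graph), cs$truth)
  expect_equal(r1[[1]]$d_A, 0, tolerance = 1e-9)
  expect_false(isTRUE(attr(r1, "suspicious")))
  expect_false(is.na(r1[[1]]$d_H))
  # a deliberately wrong observed spectrum drives d_A beyond the threshold
  wrong <- set$peaks_c13
  wrong$shift <- wrong$shift + seq(8, 8 + nrow(wrong) - 1)
  r3 <- rank_candidates(out, wrong, db = db)
  expect_true(r3[[1]]$d_A > 5.5)
  expect_true(r3[[1]]$suspicious)
  expect_true(attr(r3, "suspicious"))
  # single candidate gets rank 1
  single <- rank_candidates(out[1], set$peaks_c13, db = db)
  expect_equal(single[[1]]$rank, 1L)
})
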