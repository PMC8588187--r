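# Fragment databases, tolerance-E search, MCD embedding.

test_that("fragment cutting emits spheres and rings with stable counts", {
  bz <- benzene_graph()
  bz$shifts <- rep(128.5, 6)
  db <- build_user_fragment_db(list(bz))
  keys <- vapply(db, function(f) canonical_key(f$graph), character(1))
  expect_true(canonical_key(bz) %in% keys)       # the ring fragment
  # two-atom structure with a large cap: one fragment, the whole molecule
  eth <- molgraph(c("C", "C"), c(3L, 3L), rbind(c(1, 2, 1)),
                  shifts = c(6.5, 6.5))
  expect_length(build_user_fragment_db(list(eth), size_cap = 8L), 1L)
  # determinism across runs
  mols <- cached_fixtures()[1:8]
  n1 <- length(build_user_fragment_db(unname(mols)))
  n2 <- length(build_user_fragment_db(unname(mols)))
  expect_equal(n1, n2)
  expect_gt(n1, 50L)
  expect_error(build_user_fragment_db(list(benzene_graph())), "unassigned")
})

test_that("search honors the tolerance threshold", {
  g <- molgraph(c("C", "C", "O"), c(3L, 2L, 1L),
                rbind(c(1, 2, 1), c(2, 3, 1)), shifts = c(18.3, 57.8, NA))
  db <- build_user_fragment_db(list(g))
  obs_exact <- data.frame(shift = c(18.3, 57.8),
                          multiplicity = c("CH3", "CH2"), degeneracy = 1L)
  found <- search_fragments(db, obs_exact, cfg = fragment_config(E = 0.01))
  expect_equal(length(found), length(db))
  obs_off <- data.frame(shift = c(18.3 + 3, 57.8),
                        multiplicity = c("CH3", "CH2"), degeneracy = 1L)
  found2 <- search_fragments(db, obs_off, cfg = fragment_config(E = 1.5))
  expect_lt(length(found2), length(db))          # 2E offset excludes CH3 frags
})

test_that("fragments cut from the truth are all found in its own spectrum", {
  for (nm in c("coumarin", "geraniol_like", "dimethyluracil")) {
    g <- cached_fixtures()[[nm]]
    db <- build_user_fragment_db(list(g))
    set <- match_shifts(simulate_correlations(g, sim_options(seed = 1)))
    mcd <- build_mcd(set)
    found <- search_fragments(db, set$peaks_c13, mcd_peak_constraints(mcd))
    expect_equal(length(found), length(db), info = nm)
  }
})

test_that("search degenerates to multiplicity matching as E grows", {
  g <- cached_fixtures()$vanillin
  db <- build_user_fragment_db(list(g))
  set <- match_shifts(simulate_correlations(g, sim_options(seed = 1)))
  n_tight <- length(search_fragments(db, set$peaks_c13,
                                     cfg = fragment_config(E = 0.1)))
  n_default <- length(search_fragments(db, set$peaks_c13,
                                       cfg = fragment_config(E = 1.5)))
  n_wide <- length(search_fragments(db, set$peaks_c13,
                                    cfg = fragment_config(E = 1e6)))
  expect_lte(n_tight, n_default)
  expect_lte(n_default, n_wide)
  expect_equal(n_wide, length(db))
})

test_that("embedding fixes bonds, shrinks the search and keeps the truth", {
  g <- cached_fixtures()$quinoline
  db <- build_user_fragment_db(list(g))
  set <- match_shifts(simulate_correlations(g, sim_options(seed = 1)))
  mcd <- build_mcd(set)
  found <- search_fragments(db, set$peaks_c13, mcd_peak_constraints(mcd))
  emb <- embed_fragments(mcd, found, fragment_config(min_fragments_per_mcd = 1L))
  expect_gt(length(emb), 0L)
  expect_gt(nrow(emb[[1]]$fixed_bonds), 0L)
  out0 <- generate(mcd)
  out1 <- generate(emb[[1]])
  expect_lt(attr(out1, "nodes"), attr(out0, "nodes"))
  expect_true(all(attr(out1, "keys") %in% attr(out0, "keys")))
  expect_true(canonical_key(g) %in% attr(out1, "keys"))
  # overlapping fragments are never co-embedded
  for (v in emb) {
    fb <- v$fixed_bonds
    expect_equal(anyDuplicated(paste(pmin(fb[, 1], fb[, 2]),
                                     pmax(fb[, 1], fb[, 2]))), 0L)
  }
})

test_that("an unreachable minimum fragment count yields an empty advisory result", {
  g <- cached_fixtures()$para_xylene
  db <- build_user_fragment_db(list(g))
  set <- match_shifts(simulate_correlations(g, sim_options(seed = 1)))
  mcd <- build_mcd(set)
  found <- search_fragments(db, set$peaks_c13, mcd_peak_constraints(mcd))
  expect_warning(out <- embed_fragments(mcd, found,
                                        fragment_config(min_fragments_per_mcd = 50L)),
                 "min_fragments_per_mcd")
  expect_length(out, 0L)
})
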