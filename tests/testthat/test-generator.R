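# Structure generation: soundness, completeness (vs the brute-force oracle),
# uniqueness, constraint handling, fuzzy generation.

test_that("unconstrained generation reproduces classic isomer counts", {
  counts <- c(C4H10 = 2L, C5H12 = 3L, C6H14 = 5L, C2H6O = 2L, C3H6 = 2L,
              CH4 = 1L)
  for (f in names(counts)) {
    out <- generate(mcd_from_formula(f))
    expect_length(out, counts[[f]])
    expect_true(attr(out, "complete"))
  }
})

test_that("generation equals the brute-force oracle on random constrained instances", {
  set.seed(42)
  for (trial in 1:12) {
    nC <- sample(3:5, 1)
    het <- sample(c("", "O", "N"), 1)
    val <- 4L * nC + switch(het, O = 2L, N = 3L, 0L)
    n <- nC + (het != "")
    extra <- sample(0:2, 1)
    h <- val - 2L * (n - 1L) - 2L * extra
    if (h < 0) next
    f <- paste0("C", nC, "H", h, het)
    cons <- list()
    ncon <- sample(0:2, 1)
    for (k in seq_len(ncon)) {
      p <- sample(n, 2)
      rng <- sample(list(c(1L, 1L), c(1L, 2L), c(2L, 3L)), 1)[[1]]
      cons[[k]] <- list(us = p[1], vs = p[2], dlo = rng[1], dhi = rng[2])
    }
    bf <- tryCatch(brute_force_enumerate(f, cons), error = function(e) NULL)
    if (is.null(bf)) next
    gen <- generate(mcd_from_formula(f, cons))
    expect_setequal(attr(gen, "keys") %||% character(0),
                    attr(bf, "keys") %||% character(0))
  }
})

test_that("verify_candidate audits constraints, hybridization and H bookkeeping", {
  cons <- list(list(us = 1L, vs = 2L, dlo = 1L, dhi = 1L))
  mcd <- mcd_from_formula("C2H6O", cons)
  eth <- molgraph(c("C", "C", "O"), c(3L, 2L, 1L),
                  rbind(c(1, 2, 1), c(2, 3, 1)))
  expect_true(verify_candidate(eth, mcd)$ok)
  dme <- molgraph(c("C", "C", "O"), c(3L, 3L, 0L),
                  rbind(c(1, 3, 1), c(2, 3, 1)))
  v <- verify_candidate(dme, mcd)
  expect_false(v$ok)
  expect_match(paste(v$violations, collapse = " "), "constraint")
  # sp2-flagged atom with zero pi bonds
  mcd2 <- mcd_from_formula("C2H6O")
  mcd2$atoms$hyb_mask[1] <- casenmr:::hyb_mask("sp2")
  v2 <- verify_candidate(eth, mcd2)
  expect_false(v2$ok)
  expect_match(paste(v2$violations, collapse = " "), "hybridization")
})

test_that("closed-loop truth always satisfies its own simulated MCD", {
  for (cs in Filter(function(x) x$kind == "clean", cached_suite())) {
    mcd <- build_mcd(match_shifts(cs$simulated))
    ga <- align_to_mcd(cs$structure, mcd)
    expect_true(verify_candidate(ga, mcd)$ok, info = cs$name)
  }
})

test_that("combination counting is exact in both modes", {
  expect_equal(count_combinations(60, 5), 5461512)
  expect_equal(count_combinations(60, 5) / 1e6, 5.5, tolerance = 0.01)
  expect_equal(count_combinations(10, 0), 1)
  expect_equal(count_combinations(5, 5), 1)
  expect_equal(count_combinations(5, 5, cumulative = TRUE), 31)
  expect_equal(count_combinations(10, 3, cumulative = TRUE),
               choose(10, 1) + choose(10, 2) + choose(10, 3))
})

test_that("adding a constraint never adds structures (monotonicity)", {
  set.seed(7)
  for (trial in 1:6) {
    f <- sample(c("C5H10", "C4H8O", "C5H12"), 1)
    base <- generate(mcd_from_formula(f))
    p <- sample(4, 2)
    cons <- list(list(us = p[1], vs = p[2], dlo = 1L, dhi = 2L))
    constrained <- generate(mcd_from_formula(f, cons))
    expect_true(all(attr(constrained, "keys") %in% attr(base, "keys")))
  }
})

test_that("fuzzy generation dominates common mode and honors its accounting", {
  suite <- cached_suite()
  cs <- Filter(function(x) x$name == "dimethyluracil" && x$kind == "clean",
               suite)[[1]]
  mcd <- build_mcd(match_shifts(cs$simulated))
  common <- generate(mcd)
  fz <- fuzzy_generate(mcd, fsg_options(m = 1, a = 1,
                                        restrict_to_suspicious = FALSE))
  # elongation only relaxes: common output is a subset, truth retained
  expect_true(all(attr(common, "keys") %in% attr(fz$structures, "keys")))
  expect_true(cs$truth %in% attr(fz$structures, "keys"))
  r <- fz$result
  expect_lte(r$n_real, r$n_math)
  expect_lte(r$k_unique, r$k_filtered)
  expect_lte(r$k_filtered, r$k_generated)
  expect_equal(r$n_math, sum(choose(length(mcd$constraints), 0:1)))
})

test_that("fuzzy generation recovers a truth hidden by a 4-bond response", {
  suite <- cached_suite()
  cs <- Filter(function(x) x$kind == "nsc" && x$name == "geraniol_like",
               suite)[[1]]
  mcd <- build_mcd(match_shifts(cs$simulated))
  common <- generate(mcd)
  expect_false(cs$truth %in% (attr(common, "keys") %||% character(0)))
  cc <- check_consistency(mcd)
  for (a in c(1L, 16L)) {
    fz <- fuzzy_generate(mcd, fsg_options(m = 1, a = a), consistency = cc)
    expect_true(cs$truth %in% attr(fz$structures, "keys"),
                info = sprintf("a = %d", a))
  }
})

test_that("the pre-test never skips a combination the truth needs", {
  suite <- cached_suite()
  for (nm in c("indole", "menthone_like")) {
    cs <- Filter(function(x) x$kind == "nsc" && x$name == nm, suite)[[1]]
    mcd <- build_mcd(match_shifts(cs$simulated))
    fz <- fuzzy_generate(mcd, fsg_options(m = 1, a = 16))
    expect_true(cs$truth %in% attr(fz$structures, "keys"), info = nm)
  }
})

test_that("symmetric fixtures terminate and dedup to the oracle class count", {
  g <- cached_fixtures()$para_xylene
  set <- match_shifts(simulate_correlations(g, sim_options(seed = 2)))
  out <- generate(build_mcd(set))
  expect_true(attr(out, "complete"))
  expect_equal(anyDuplicated(attr(out, "keys")), 0L)
  expect_true(canonical_key(g) %in% attr(out, "keys"))
  # degenerate-peak MCD admits the truth by assignment search too
  expect_true(admits_assignment(g, build_mcd(set)))
})

test_that("pentavalent-nitrogen exploration only widens the solution set", {
  m <- mcd_from_formula("CH3NO2")    # nitromethane needs N(5) in this model
  out4 <- generate(m)
  out5 <- generate(m, gen_options(explore_alt_valences = TRUE))
  expect_true(all((attr(out4, "keys") %||% character(0)) %in%
                  attr(out5, "keys")))
  expect_gte(length(out5), length(out4))
})
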