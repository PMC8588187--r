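# APCT property assignment, correlation translation, MCD construction and
# the contradiction-detection heuristic.

test_that("APCT assigns hybridization and hetero flags from shift ranges", {
  p <- apply_apct(90, "CH")
  expect_setequal(p$hyb, c("sp3", "sp2"))
  expect_equal(p$hetero, "undefined")
  p2 <- apply_apct(12, "CH3")
  expect_equal(p2$hyb, "sp3")
  expect_equal(p2$hetero, "fb")
  p3 <- apply_apct(170, "C")
  expect_equal(p3$hyb, "sp2")
  expect_equal(p3$hetero, "ob")
  expect_warning(p4 <- apply_apct(260), "outside")
  expect_setequal(p4$hyb, c("sp3", "sp2", "sp"))
})

test_that("correlation translation follows the H-carrier bond arithmetic", {
  # COSY strong, assumed 2-3 bonds between protons -> carrier carbons
  # 0-1 bonds apart, i.e. exactly adjacent once the geminal case collapses
  set <- correlation_set("C4H10O",
    peaks_c13 = data.frame(shift = c(15, 35, 60, 70),
                           multiplicity = c("CH3", "CH2", "CH", "CH2"),
                           intensity = 1, degeneracy = 1L),
    peaks_h1 = data.frame(shift = c(0.9, 1.5, 3.6, 3.4),
                          intensity = 1, degeneracy = 1L),
    correlations = rbind(
      data.frame(kind = "HSQC", shift_a = c(0.9, 1.5, 3.6, 3.4),
                 shift_b = c(15, 35, 60, 70), intensity_class = "strong"),
      data.frame(kind = "COSY", shift_a = 0.9, shift_b = 1.5,
                 intensity_class = "strong"),
      data.frame(kind = "COSY", shift_a = 0.9, shift_b = 3.6,
                 intensity_class = "weak"),
      data.frame(kind = "HMBC", shift_a = 0.9, shift_b = 60,
                 intensity_class = "strong")))
  set <- match_shifts(set)
  mcd <- build_mcd(set)
  cons <- mcd$constraints
  by_pair <- function(u, v) Filter(function(cn)
    identical(as.integer(sort(c(cn$us, cn$vs))), as.integer(sort(c(u, v)))), cons)
  cosy_s <- by_pair(1, 2)[[1]]
  expect_equal(c(cosy_s$dlo, cosy_s$dhi), c(1L, 1L))
  cosy_w_hmbc <- by_pair(1, 3)[[1]]
  # weak COSY gives [1,2]; the HMBC on the same pair also gives [1,2];
  # merged by intersection
  expect_equal(c(cosy_w_hmbc$dlo, cosy_w_hmbc$dhi), c(1L, 2L))
  expect_length(cons, 2L)
})

test_that("contradictory duplicate constraints are reported with their records", {
  set <- correlation_set("C5H12",
    peaks_c13 = data.frame(shift = c(10, 20, 30, 40, 50),
                           multiplicity = c("CH3", "CH2", "CH2", "CH2", "CH3"),
                           intensity = 1, degeneracy = 1L),
    peaks_h1 = data.frame(shift = c(1.0, 1.2, 1.4, 1.6, 1.8),
                          intensity = 1, degeneracy = 1L),
    correlations = rbind(
      data.frame(kind = "HSQC", shift_a = c(1.0, 1.2, 1.4, 1.6, 1.8),
                 shift_b = c(10, 20, 30, 40, 50), intensity_class = "strong"),
      data.frame(kind = "COSY", shift_a = 1.0, shift_b = 1.2,
                 intensity_class = "strong"),      # distance [1,1]
      data.frame(kind = "COSY", shift_a = 1.0, shift_b = 1.2,
                 intensity_class = "weak")))       # distance [1,2] -> fine
  expect_silent(mcd <- build_mcd(match_shifts(set)))
  cn <- Filter(function(x) identical(sort(c(x$us, x$vs)), c(1L, 2L)),
               mcd$constraints)[[1]]
  expect_equal(c(cn$dlo, cn$dhi), c(1L, 1L))       # intersection of the two
})

test_that("build_mcd lays out CHn groups, heteroatoms and free hydrogens", {
  set <- correlation_set("C2H6O",
    peaks_c13 = data.frame(shift = c(18.3, 57.8), multiplicity = c("CH3", "CH2"),
                           intensity = 1, degeneracy = 1L),
    peaks_h1 = data.frame(shift = c(1.2, 3.7), intensity = 1, degeneracy = 1L))
  mcd <- build_mcd(match_shifts(set))
  expect_equal(nrow(mcd$atoms), 3L)
  expect_equal(mcd$atoms$element, c("C", "C", "O"))
  expect_equal(mcd$free_h, 1L)                     # the OH proton
  expect_length(mcd$constraints, 0L)
  # formula-only input
  mcd2 <- mcd_from_formula("C6H14")
  expect_equal(nrow(mcd2$atoms), 6L)
  expect_length(mcd2$constraints, 0L)
  # H bookkeeping violations
  bad <- correlation_set("C2H4O",
    peaks_c13 = data.frame(shift = c(18.3, 57.8), multiplicity = c("CH3", "CH3"),
                           intensity = 1, degeneracy = 1L))
  expect_error(build_mcd(bad), "protons")
})

test_that("MCD atom counts always conserve the formula", {
  for (cs in cached_suite()[1:6]) {
    mcd <- build_mcd(match_shifts(cs$simulated))
    f <- cs$simulated$formula
    expect_equal(sum(mcd$atoms$element == "C"), casenmr:::formula_count(f, "C"))
    expect_equal(sum(mcd$atoms$hydrogens, na.rm = TRUE) + mcd$free_h,
                 casenmr:::formula_count(f, "H"))
  }
})

test_that("pigeonhole catches more forced neighbors than free valence", {
  cons <- lapply(2:5, function(v)
    list(us = 1L, vs = as.integer(v), dlo = 1L, dhi = 1L, origin = "HMBC",
         suspicious = FALSE, ambiguous = FALSE, sources = NA))
  mcd <- mcd_from_formula("C6H12", cons)
  mcd$atoms$hydrogens[1] <- 1L             # CH: free valence 3, 4 forced partners
  rep <- check_consistency(mcd, trial_generation = FALSE)
  expect_false(rep$feasible)
  expect_true(1L %in% rep$suspicious_atoms)
  expect_true(length(rep$suspicious_constraints) >= 4L)
})

test_that("ideal closed-loop data are never flagged; injected NSCs mostly are", {
  suite <- cached_suite()
  clean <- Filter(function(x) x$kind == "clean", suite)
  for (cs in clean[c(1, 4, 8, 11)]) {
    rep <- check_consistency(build_mcd(match_shifts(cs$simulated)))
    expect_true(rep$feasible, info = cs$name)
    expect_length(rep$suspicious_constraints, 0L)
  }
  nsc <- Filter(function(x) x$kind == "nsc", suite)
  det <- vapply(nsc, function(cs) {
    rep <- check_consistency(build_mcd(match_shifts(cs$simulated)))
    !rep$feasible && length(rep$suspicious_constraints) > 0L
  }, logical(1))
  expect_gte(mean(det), 0.5)   # the acceptance suite asserts the full target
})

test_that("MCDs survive JSON serialization for file-based editing", {
  suite <- cached_suite()
  cs <- Filter(function(x) x$name == "indole" && x$kind == "clean", suite)[[1]]
  mcd <- build_mcd(match_shifts(cs$simulated))
  tmp <- tempfile(fileext = ".json")
  mcd_to_json(mcd, tmp)
  back <- mcd_from_json(tmp)
  expect_equal(nrow(back$atoms), nrow(mcd$atoms))
  expect_equal(back$free_h, mcd$free_h)
  expect_length(back$constraints, length(mcd$constraints))
  expect_equal(back$constraints[[1]]$dlo, mcd$constraints[[1]]$dlo)
  out1 <- generate(mcd); out2 <- generate(back)
  expect_setequal(attr(out1, "keys"), attr(out2, "keys"))
})
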