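# Correlation-table I/O, shift matching, bond-range policy.

make_set_file <- function(lines) {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("record,f1,f2,f3,f4", lines), tmp)
  tmp
}

test_that("the default bond-range policy matches the assumed coupling lengths", {
  pol <- default_bond_policy()
  expect_equal(pol$COSY.strong, c(2L, 3L))
  expect_equal(pol$COSY.weak, c(3L, 4L))
  expect_equal(pol$HMBC.strong, c(2L, 3L))
  expect_equal(pol$HMBC.weak, c(2L, 3L))
})

test_that("correlation files parse with line-numbered errors for bad records", {
  path <- make_set_file(c("formula,C9H12,,,",
                          "C13,21.5,CH3,100,1",
                          "C13,137.8,C,40,1",
                          "H1,2.31,300,1,",
                          "COSY,7.59,8.86,strong,",
                          "policy,COSY,strong,2,4"))
  set <- read_correlation_set(path)
  expect_s3_class(set, "correlation_set")
  expect_equal(nrow(set$peaks_c13), 2L)
  expect_equal(set$correlations$kind, "COSY")
  expect_equal(set$policy$COSY.strong, c(2L, 4L))  # override applied
  expect_error(read_correlation_set(make_set_file("NOPE,1,2,strong,")),
               "line 2.*unknown record")
  expect_error(read_correlation_set(make_set_file(c("formula,C2H6O,,,",
                                                    "C13,abc,CH3,1,1"))),
               "line 3.*non-numeric")
})

test_that("a peaks-only file yields a correlation-free set", {
  path <- make_set_file(c("formula,C2H6O,,,", "C13,18.3,CH3,10,1",
                          "C13,57.8,CH2,10,1"))
  set <- read_correlation_set(path)
  expect_equal(nrow(set$correlations), 0L)
  set2 <- match_shifts(set)
  expect_true(set2$resolved)
})

test_that("2D coordinates snap to nearest peaks; ties are marked, not broken", {
  set <- correlation_set("C3H8O",
    peaks_c13 = data.frame(shift = c(70.0, 70.2, 25.0),
                           multiplicity = c("CH", "CH2", "CH3"),
                           intensity = 1, degeneracy = 1L),
    peaks_h1 = data.frame(shift = c(3.9, 1.1), intensity = 1, degeneracy = 1L),
    correlations = data.frame(kind = "HMBC", shift_a = 1.1, shift_b = 70.1,
                              intensity_class = "strong"))
  res <- match_shifts(set, tol_c = 0.3)
  expect_true(res$correlations$ambiguous[1])
  expect_equal(res$correlations$b_peaks[1], "1,2")
  res2 <- match_shifts(correlation_set("C3H8O",
    peaks_c13 = data.frame(shift = 128.0, multiplicity = "CH", intensity = 1,
                           degeneracy = 1L),
    peaks_h1 = data.frame(shift = 7.3, intensity = 1, degeneracy = 1L),
    correlations = data.frame(kind = "HMBC", shift_a = 7.3, shift_b = 128.05,
                              intensity_class = "strong")), tol_c = 0.2)
  expect_equal(res2$correlations$b_peaks[1], "1")
  expect_false(res2$correlations$ambiguous[1])
})

test_that("unmatched coordinates and HSQC overloads are errors", {
  set <- correlation_set("C2H6O",
    peaks_c13 = data.frame(shift = 18.3, multiplicity = "CH3", intensity = 1,
                           degeneracy = 1L),
    peaks_h1 = data.frame(shift = 2.1, intensity = 1, degeneracy = 1L),
    correlations = data.frame(kind = "HMBC", shift_a = 2.1, shift_b = 999999,
                              intensity_class = "strong"))
  expect_error(match_shifts(set), "no 13C peak within")
  over <- correlation_set("C4H8O",
    peaks_c13 = data.frame(shift = 30.0, multiplicity = "CH", intensity = 1,
                           degeneracy = 1L),
    peaks_h1 = data.frame(shift = c(1.0, 2.0), intensity = 1, degeneracy = 1L),
    correlations = data.frame(kind = "HSQC", shift_a = c(1.0, 2.0),
                              shift_b = c(30.0, 30.0),
                              intensity_class = "strong"))
  expect_error(match_shifts(over), "more than its H count")
})

test_that("correlation sets round trip through their text rendering", {
  g <- cached_fixtures()$para_xylene
  set <- simulate_correlations(g, sim_options(seed = 3))
  tmp <- tempfile(fileext = ".csv")
  write_correlation_set(set, tmp)
  back <- read_correlation_set(tmp)
  expect_equal(back$peaks_c13$shift, set$peaks_c13$shift, tolerance = 1e-6)
  expect_equal(back$peaks_c13$degeneracy, set$peaks_c13$degeneracy)
  expect_equal(nrow(back$correlations), nrow(set$correlations))
  expect_equal(back$correlations$shift_b, set$correlations$shift_b,
               tolerance = 1e-6)
  # closed loop: simulator output resolves with zero ambiguity at tight tol
  res <- match_shifts(back, tol_c = 0.01, tol_h = 0.005)
  expect_false(any(res$correlations$ambiguous))
})

test_that("write_report emits one SDF record per candidate and round-trips fields", {
  suite <- cached_suite()
  cs <- Filter(function(x) x$name == "para_xylene" && x$kind == "clean", suite)[[1]]
  set <- match_shifts(cs$simulated)
  out <- generate(build_mcd(set))
  ranked <- rank_candidates(out, set$peaks_c13, db = cached_shift_db())
  tmp <- tempfile(fileext = ".sdf")
  summary <- write_report(ranked, tmp)
  recs <- read_sdf(tmp)
  expect_length(recs, length(ranked))
  expect_equal(as.integer(recs[[1]]$data[["RANK"]]), 1L)
  expect_equal(as.numeric(recs[[1]]$data[["D_I"]]), ranked[[1]]$d_I,
               tolerance = 1e-4)
  expect_warning(write_report(list(), tempfile(fileext = ".sdf")), "no candidates")
})
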