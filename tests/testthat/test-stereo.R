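# Stereoisomer enumeration, NOE penalties, conformer embedding.

test_that("stereocenter and double-bond perception find the textbook elements", {
  expect_length(find_stereocenters(butane_graph()), 0L)
  bol <- molgraph(c("C", "C", "C", "C", "O"), c(3L, 1L, 2L, 3L, 1L),
                  rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(2, 5, 1)))
  expect_equal(find_stereocenters(bol), 2L)      # butan-2-ol
  expect_equal(nrow(find_stereo_double_bonds(butene2_graph())), 1L)
  # ring double bonds and terminal CH2= are not stereogenic
  expect_equal(nrow(find_stereo_double_bonds(benzene_graph())), 0L)
  propene <- molgraph(rep("C", 3), c(2L, 1L, 3L),
                      rbind(c(1, 2, 2), c(2, 3, 1)))
  expect_equal(nrow(find_stereo_double_bonds(propene)), 0L)
})

test_that("relative-configuration counts quotient mirror and symmetry", {
  bol <- molgraph(c("C", "C", "C", "C", "O"), c(3L, 1L, 2L, 3L, 1L),
                  rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(2, 5, 1)))
  expect_length(enumerate_stereoisomers(bol), 1L)    # mirror-collapsed
  # meso-symmetric two-center fixture: {RR~SS} and {RS~SR}
  bdiol <- molgraph(c("C", "C", "C", "C", "O", "O"), c(3L, 1L, 1L, 3L, 1L, 1L),
                    rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(2, 5, 1),
                          c(3, 6, 1)))
  cfgs <- enumerate_stereoisomers(bdiol)
  expect_length(cfgs, 2L)
  pats <- sort(vapply(cfgs, function(cf)
    paste(cf$parity[1] * cf$parity[2], collapse = ""), character(1)))
  expect_equal(pats, c("-1", "1"))   # opposite-parity (meso) and same-parity
  # raw count before reduction follows 2^k
  expect_equal(attr(enumerate_stereoisomers(bdiol), "n_raw"), 4)
  expect_length(enumerate_stereoisomers(butene2_graph()), 2L)  # E and Z
})

test_that("penalty arithmetic matches the distance-class definitions", {
  fake <- list(conformers = list(rbind(c(0, 0, 0), c(2.0, 0, 0))),
               h_index = c(1L, 2L), h_parent = c(10L, 20L), n_heavy = 0L)
  cons <- list(noe_constraint(10, 20, "strong"))
  expect_equal(noe_penalty(fake, cons), 0)
  fake$conformers <- list(rbind(c(0, 0, 0), c(3.5, 0, 0)))
  expect_equal(noe_penalty(fake, cons), (3.5 - 2.5)^2)
  expect_equal(noe_penalty(fake, list()), 0)
  # single conformer: r_eff is the geometric distance exactly
  fake$conformers <- list(rbind(c(0, 0, 0), c(4.2, 0, 0)))
  expect_equal(noe_penalty(fake, list(noe_constraint(10, 20, "weak"))), 0)
  expect_equal(noe_penalty(fake, list(noe_constraint(10, 20, "medium"))),
               (4.2 - 4.0)^2, tolerance = 1e-9)
  # invariance to constraint and conformer order
  fake$conformers <- list(rbind(c(0, 0, 0), c(2.2, 0, 0)),
                          rbind(c(0, 0, 0), c(3.0, 0, 0)))
  cons2 <- list(noe_constraint(10, 20, "strong"), noe_constraint(20, 10, "medium"))
  p1 <- noe_penalty(fake, cons2)
  p2 <- noe_penalty(fake, rev(cons2))
  fake_rev <- fake; fake_rev$conformers <- rev(fake$conformers)
  expect_equal(p1, p2)
  expect_equal(p1, noe_penalty(fake_rev, cons2))
})

test_that("r^-6 averaging weights close approaches more than far ones", {
  fake <- list(conformers = list(rbind(c(0, 0, 0), c(2.0, 0, 0)),
                                 rbind(c(0, 0, 0), c(5.0, 0, 0))),
               h_index = c(1L, 2L), h_parent = c(1L, 2L), n_heavy = 0L)
  r6 <- mean(c(2^-6, 5^-6))^(-1 / 6)
  expect_lt(r6, 3.5)                     # far below the arithmetic mean
  expect_equal(noe_penalty(fake, list(noe_constraint(1, 2, "strong"))),
               max(r6 - 2.5, 0)^2, tolerance = 1e-9)
})

test_that("a strong vinyl NOE selects cis over trans on 2-butene", {
  but <- butene2_graph()
  sel <- select_stereoisomer(but, list(noe_constraint(2, 3, "strong")), seed = 1)
  expect_equal(sel[[1]]$config$ez[["2-3"]], "Z")
  expect_lt(sel[[1]]$penalty, sel[[2]]$penalty)
  expect_equal(sel[[1]]$penalty, 0)
  # zero constraints: all penalties zero, ordered by energy proxy
  sel0 <- select_stereoisomer(but, list(), seed = 1)
  expect_true(all(vapply(sel0, `[[`, numeric(1), "penalty") == 0))
  # an unsatisfiable constraint still returns a minimum, with a warning:
  # the vinyl protons sit well under 4 A in either geometry, so a weak-class
  # response (4.0-5.0 A) cannot be satisfied by any configuration
  expect_warning(
    sel_bad <- select_stereoisomer(but, list(noe_constraint(2, 3, "weak")),
                                   seed = 1),
    "least-violating")
  expect_true(all(vapply(sel_bad, `[[`, numeric(1), "penalty") > 0))
})

test_that("penalties are mirror-invariant for chiral configurations", {
  bol <- molgraph(c("C", "C", "C", "C", "O"), c(3L, 1L, 2L, 3L, 1L),
                  rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(2, 5, 1)))
  cons <- list(noe_constraint(1, 3, "medium"))
  cfg <- list(parity = c(`2` = 1L), ez = character(0))
  cfg_m <- list(parity = c(`2` = -1L), ez = character(0))
  # the embedder restarts are stochastic, so enantiomer penalties agree only
  # up to the conformer-sampling spread
  p1 <- noe_penalty(embed_conformers(bol, cfg, n_conf = 8, seed = 5), cons)
  p2 <- noe_penalty(embed_conformers(bol, cfg_m, n_conf = 8, seed = 5), cons)
  expect_lt(abs(p1 - p2), 0.12)
})

test_that("the stereo report serializes ranked configurations", {
  sel <- select_stereoisomer(butene2_graph(),
                             list(noe_constraint(2, 3, "strong")), seed = 1)
  tmp <- tempfile(fileext = ".csv")
  df <- write_stereo_report(sel, tmp)
  back <- read.csv(tmp)
  expect_equal(back$rank, seq_along(sel))
  expect_equal(back$configuration[1], sel[[1]]$label)
})
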