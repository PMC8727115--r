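# The criteria operate on a shared state; scores here are cross-checked in
# two independent ways: against hand-composed expressions built only from
# the exported information estimators, and (for the greedy path) against the
# from-scratch scorer.

feats <- toyA[c("f1", "f2", "f3")]
cl <- toyA$class

test_that("every criterion reduces to the relevance I(f;C) at an empty selected set", {
  rel <- vapply(feats, mutual_information, numeric(1), y = cl)
  for (cr in list_criteria()) {
    expect_equal(score_candidates(feats, cl, cr), rel,
                 info = cr, tolerance = 1e-12)
  }
})

test_that("CIFE worked values on the duplicate fixture", {
  sc <- score_candidates(feats, cl, "cife", selected = "f1")
  expect_equal(sc[["f2"]], TOYA$I_f1_C - (1 - TOYA$H_f1_given_C),
               tolerance = 1e-9)  # about 0
  expect_equal(sc[["f3"]], 0 - (TOYA$I_f1_C - TOYA$I_f3_f1_given_C),
               tolerance = 1e-9)  # about +0.1226
})

test_that("JMI equals CIFE for a single selected feature and averages over duplicates", {
  one <- score_candidates(feats, cl, "jmi", selected = "f1")
  expect_equal(one, score_candidates(feats, cl, "cife", selected = "f1"))
  # duplicating a selected feature leaves the averaged penalty unchanged
  sc1 <- score_candidates(feats, cl, "jmi", selected = "f1",
                          candidates = "f3")
  sc2 <- score_candidates(feats, cl, "jmi", selected = c("f1", "f2"),
                          candidates = "f3")
  expect_equal(sc1[["f3"]], sc2[["f3"]], tolerance = 1e-12)
})

test_that("CMIM penalises via the worst selected feature", {
  sc <- score_candidates(feats, cl, "cmim", selected = "f1")
  expect_equal(sc[["f2"]], TOYA$I_f1_C - (1 - TOYA$H_f1_given_C),
               tolerance = 1e-9)
  # score(f3) = I(f3;C) - (I(f3;f1) - I(f3;f1|C)) = 0 + 0.1226
  expect_equal(sc[["f3"]],
               0 - (mutual_information(toyA$f3, toyA$f1) -
                      TOYA$I_f3_f1_given_C),
               tolerance = 1e-9)
  # with several selected features the max penalty governs
  xorf <- xor_fixture()
  x <- xorf[c("x", "y", "noise")]
  got <- score_candidates(x, xorf$class, "cmim", selected = c("y", "noise"))
  pen <- max(
    mutual_information(x$x, x$y) -
      conditional_mutual_information(x$x, x$y, xorf$class),
    mutual_information(x$x, x$noise) -
      conditional_mutual_information(x$x, x$noise, xorf$class))
  expect_equal(got[["x"]],
               mutual_information(x$x, xorf$class) - pen, tolerance = 1e-9)
})

test_that("NDCRFS rejects the exact duplicate and keeps the balanced column above it", {
  sc <- score_candidates(feats, cl, "ndcrfs", selected = "f1")
  expect_equal(sc[["f2"]], TOYA$ndcrfs_f2, tolerance = 1e-6)
  expect_equal(sc[["f3"]], TOYA$ndcrfs_f3, tolerance = 1e-6)
  expect_gt(sc[["f3"]], sc[["f2"]])
})

test_that("DWFS weight dynamics follow the normalised conditional-relevance multiplier", {
  # manual recomputation from the exported primitives
  manual_dwfs <- function(x, y, S, f) {
    w <- 1
    for (s in S) {
      w <- w * (2 * (conditional_mutual_information(x[[f]], y, x[[s]]) -
                       mutual_information(x[[f]], y)) /
                  (entropy(x[[f]]) + entropy(y)) + 1)
    }
    w * mutual_information(x[[f]], y)
  }
  sc <- score_candidates(feats, cl, "dwfs", selected = "f1")
  expect_equal(sc[["f2"]], manual_dwfs(feats, cl, "f1", "f2"),
               tolerance = 1e-9)
  # conditional relevance of the duplicate collapses: multiplier < 1
  expect_lt(sc[["f2"]], mutual_information(feats$f2, cl))
  # XOR: multiplier is exactly 2 for the partner
  xorf <- xor_fixture()
  x <- xorf[c("x", "y", "noise")]
  expect_equal(manual_dwfs(x, xorf$class, "y", "x"),
               2 * mutual_information(x$x, xorf$class))  # = 0 here
  mult <- 2 * (conditional_mutual_information(x$x, xorf$class, x$y) -
                 mutual_information(x$x, xorf$class)) /
    (entropy(x$x) + entropy(xorf$class)) + 1
  expect_equal(mult, 2)
})

test_that("DRJMIM equals its brute-force evaluation over selected features", {
  manual_drjmim <- function(x, y, S, f) {
    rel_f <- mutual_information(x[[f]], y)
    terms <- vapply(S, function(s) {
      ii <- interaction_information(x[[f]], x[[s]], y)
      cr <- 2 * (conditional_mutual_information(x[[f]], y, x[[s]]) - rel_f) /
        (entropy(x[[f]]) + entropy(y))
      ii * (rel_f + cr * mutual_information(x[[s]], y))
    }, numeric(1))
    min(terms)
  }
  set.seed(33)
  x <- as.data.frame(matrix(sample(0:2, 4 * 24, replace = TRUE), ncol = 4,
                            dimnames = list(NULL, paste0("g", 1:4))))
  y <- sample(0:1, 24, replace = TRUE)
  for (S in list("g1", c("g1", "g3"), c("g2", "g3", "g4"))) {
    f <- setdiff(names(x), S)[1L]
    expect_equal(score_candidates(x, y, "drjmim", selected = S)[[f]],
                 manual_drjmim(x, y, S, f), tolerance = 1e-9, info = f)
  }
})

test_that("DWUR redundancy factor zeroes out a duplicate at beta = 1", {
  # selected feature is an exact balanced copy of the candidate:
  # (1 - beta * I(f, copy)) = 1 - H(f) = 0
  x <- data.frame(a = rep(c(0, 1), 8), b = rep(c(0, 1), 8))
  y <- rep(c(0, 1, 1, 0), 4)
  sc <- score_candidates(x, y, "dwur", selected = "b", beta = 1)
  expect_equal(sc[["a"]], 0, tolerance = 1e-12)
  # independent features leave the redundancy factor at 1
  manual_dwur <- function(x, y, s, f, beta) {
    rel_f <- mutual_information(x[[f]], y)
    cr <- 2 * (conditional_mutual_information(x[[f]], y, x[[s]]) - rel_f) /
      (entropy(x[[f]]) + entropy(y))
    (1 - beta * mutual_information(x[[f]], x[[s]])) *
      (rel_f + cr * mutual_information(x[[s]], y))
  }
  sc2 <- score_candidates(feats, cl, "dwur", selected = "f1", beta = 0.5)
  expect_equal(sc2[["f3"]], manual_dwur(feats, cl, "f1", "f3", 0.5),
               tolerance = 1e-9)
})

test_that("greedy step scores equal the from-scratch no-cache recomputation", {
  set.seed(44)
  x <- as.data.frame(matrix(sample(0:2, 6 * 40, replace = TRUE), ncol = 6,
                            dimnames = list(NULL, paste0("g", 1:6))))
  y <- sample(0:2, 40, replace = TRUE)
  for (cr in list_criteria()) {
    rk <- select_features(x, y, criterion = cr, k = 4)
    for (step in seq_along(rk$order)) {
      S <- rk$order[seq_len(step - 1L)]
      fresh <- score_candidates(x, y, cr, selected = S,
                                candidates = rk$order[step])
      expect_equal(rk$scores[step], unname(fresh), tolerance = 1e-9,
                   info = paste(cr, "step", step))
    }
  }
})

test_that("synergy detection: conditional criteria boost the XOR partner, relevance alone cannot", {
  xorf <- xor_fixture()
  x <- xorf[c("x", "y", "noise")]
  for (cr in c("cife", "jmi", "cmim")) {
    sc <- score_candidates(x, xorf$class, cr, selected = "y")
    expect_gt(sc[["x"]], sc[["noise"]])
  }
  sc_mim <- score_candidates(x, xorf$class, "mim", selected = "y")
  expect_equal(sc_mim[["x"]], sc_mim[["noise"]])
  # the nonlinear dynamic conditional-relevance penalty reads conditional
  # dependence on a selected feature as redundancy, so the XOR partner is
  # penalised relative to noise (see the methods vignette)
  sc_nd <- score_candidates(x, xorf$class, "ndcrfs", selected = "y")
  expect_equal(sc_nd[["x"]], -1, tolerance = 1e-9)
  expect_equal(sc_nd[["noise"]], 0, tolerance = 1e-9)
})

test_that("scoring never mutates its inputs and is repeatable", {
  before <- feats
  s1 <- score_candidates(feats, cl, "ndcrfs", selected = "f1")
  s2 <- score_candidates(feats, cl, "ndcrfs", selected = "f1")
  expect_identical(feats, before)
  expect_identical(s1, s2)
})

test_that("unknown criteria and feature ids are rejected", {
  expect_error(score_candidates(feats, cl, "mrmr"), "unknown criterion")
  expect_error(score_candidates(feats, cl, "mim", selected = "nope"),
               "unknown feature")
  expect_error(score_candidates(feats, cl, "mim", selected = "f1",
                                candidates = "f1"), "disjoint")
})
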