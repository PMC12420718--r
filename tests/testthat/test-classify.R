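cfg23 <- scorecard_config(t_low = 2, t_high = 3)

test_that("axis categorization uses half-open bands with outer boundaries", {
  expect_equal(categorize_axis(-1.98, 2, 3), "CENTRAL")
  expect_equal(categorize_axis(-3.95, 2, 3), "EXTREME")
  expect_equal(categorize_axis(2.0, 2, 3), "MODERATE")
  expect_equal(categorize_axis(3.0, 2, 3), "EXTREME")
  expect_equal(categorize_axis(c(0, -2, 2.9, -3.1), 2, 3),
               c("CENTRAL", "MODERATE", "MODERATE", "EXTREME"))
  expect_error(categorize_axis(Inf, 2, 3), "finite")
})

test_that("quadrants follow fold-change signs with zero counted positive", {
  expect_equal(assign_quadrant(-3.95, -1.98), "Q3")
  expect_equal(assign_quadrant(1, -1), "Q4")
  expect_equal(assign_quadrant(0, 5), "Q1")
  expect_equal(assign_quadrant(c(1, -1, -1, 1, 0, -2), c(1, 1, -1, -1, 0, 0)),
               c("Q1", "Q2", "Q3", "Q4", "Q1", "Q2"))
})

test_that("a gene markedly down in one co-treatment only lands in Q3/D", {
  # x = -3.95 (extreme), y = -1.98 (central) at thresholds (2, 3)
  res <- classify_point(-3.95, -1.98, cfg23)
  expect_equal(res$quadrant, "Q3")
  expect_equal(res$region, "D")
  # companion case: the y-axis condition is the markedly changed one
  res2 <- classify_point(-1.98, -3.95, cfg23)
  expect_equal(res2$quadrant, "Q3")
  expect_equal(res2$region, "E")
})

test_that("mode masks restrict which regions are reported", {
  std <- scorecard_config(2, 3, mode = "standard")
  fw <- scorecard_config(2, 3, mode = "fourway")
  # both central: never reported
  for (cfg in list(cfg23, std, fw)) {
    r <- classify_point(1.0, 1.5, cfg)
    expect_false(r$reported)
    expect_true(is.na(r$region))
  }
  # moderate/moderate: M in full, masked in standard, quadrant in fourway
  expect_equal(classify_point(2.5, 2.5, cfg23)$region, "M")
  expect_equal(classify_point(2.5, 2.5, cfg23)$quadrant, "Q1")
  expect_false(classify_point(2.5, 2.5, std)$reported)
  rfw <- classify_point(2.5, 2.5, fw)
  expect_true(rfw$reported)
  expect_equal(rfw$quadrant, "Q1")
  expect_true(is.na(rfw$region))
  # moderate-x / extreme-y is B
  expect_equal(classify_point(2.5, 3.5, cfg23)$region, "B")
  expect_equal(classify_point(2.5, 3.5, std)$region, "B")
})

test_that("the letter-axis convention switch swaps paired letters", {
  swapped <- scorecard_config(2, 3, swap_letter_axes = TRUE)
  expect_equal(classify_point(-3.95, -1.98, swapped)$region, "E")
  expect_equal(classify_point(2.5, 3.5, swapped)$region, "C")
  expect_equal(classify_point(3.5, 3.5, swapped)$region, "A")
  expect_equal(classify_point(2.5, 1.0, swapped)$region, "R")
})

test_that("significance policies test the intended axes", {
  cfg_nc <- scorecard_config(2, 3, significance_policy = "non_central_axes")
  cfg_both <- scorecard_config(2, 3, significance_policy = "both_axes")
  cfg_either <- scorecard_config(2, 3, significance_policy = "either_axis")
  # D-region gene: x extreme (tested), y central (exempt under default)
  expect_true(passes_significance(0.01, 0.9, "EXTREME", "CENTRAL", cfg_nc))
  expect_false(passes_significance(0.01, 0.9, "EXTREME", "CENTRAL", cfg_both))
  expect_true(passes_significance(NA, 0.01, "EXTREME", "EXTREME", cfg_either))
  expect_false(passes_significance(NA, 0.01, "EXTREME", "EXTREME", cfg_nc))
  expect_false(passes_significance(NA, NA, "EXTREME", "EXTREME", cfg_either))
  # boundary: p equal to alpha passes
  expect_true(passes_significance(0.05, 0.05, "EXTREME", "EXTREME", cfg_both))
  # missing_p = "pass" lifts the missing-p failure
  cfg_pass <- scorecard_config(2, 3, missing_p = "pass")
  expect_true(passes_significance(NA, NA, "EXTREME", "MODERATE", cfg_pass))
})

test_that("swap symmetry: transposing axes swaps paired letters and Q2/Q4", {
  grid <- c(0, 1, -1, 2, -2, 2.5, -2.5, 3, -3, 5, -5)
  letter_swap <- c(A = "A", B = "C", C = "B", D = "E", E = "D",
                   M = "M", S = "R", R = "S")
  quad_swap <- c(Q1 = "Q1", Q2 = "Q4", Q3 = "Q3", Q4 = "Q2")
  for (x in grid) {
    for (y in grid) {
      a <- classify_point(x, y, cfg23)
      b <- classify_point(y, x, cfg23)
      expect_equal(a$reported, b$reported)
      if (a$reported) {
        expect_equal(unname(quad_swap[a$quadrant]), b$quadrant)
        expect_equal(unname(letter_swap[a$region]), b$region)
      }
    }
  }
})

test_that("mode nesting: standard within full within fourway at t_low", {
  set.seed(31)
  x <- runif(500, -6, 6)
  y <- runif(500, -6, 6)
  std <- classify_point(x, y, scorecard_config(2, 3, mode = "standard"))
  full <- classify_point(x, y, cfg23)
  fw <- classify_point(x, y, scorecard_config(2, 3, mode = "fourway"))
  expect_true(all(!std$reported | full$reported))
  expect_true(all(!full$reported | fw$reported))
})

test_that("radial monotonicity: scaling up never unreports or demotes", {
  set.seed(32)
  x <- runif(300, -6, 6)
  y <- runif(300, -6, 6)
  base <- classify_point(x, y, cfg23)
  rank_of <- function(v) c(CENTRAL = 0, MODERATE = 1, EXTREME = 2)[v]
  for (c_mult in c(1, 1.3, 2, 5)) {
    scaled <- classify_point(c_mult * x, c_mult * y, cfg23)
    idx <- base$reported
    expect_true(all(scaled$reported[idx]))
    bx <- rank_of(categorize_axis(x[idx], 2, 3))
    sx <- rank_of(categorize_axis(c_mult * x[idx], 2, 3))
    by <- rank_of(categorize_axis(y[idx], 2, 3))
    sy <- rank_of(categorize_axis(c_mult * y[idx], 2, 3))
    expect_true(all(sx >= bx))
    expect_true(all(sy >= by))
  }
})

test_that("classifier agrees with the brute-force oracle", {
  set.seed(33)
  n <- 10000
  x <- runif(n, -6, 6)
  y <- runif(n, -6, 6)
  for (th in list(c(2, 3), c(2, 4))) {
    cfg <- scorecard_config(th[1], th[2])
    got <- classify_point(x, y, cfg)
    exp <- lapply(seq_len(n), function(i) {
      oracle_classify(x[i], y[i], th[1], th[2])
    })
    expect_equal(got$region, vapply(exp, `[[`, character(1), "region"))
    expect_equal(got$quadrant, vapply(exp, `[[`, character(1), "quadrant"))
    expect_equal(got$reported, vapply(exp, `[[`, logical(1), "reported"))
  }
})

test_that("every finite point falls in exactly one of the nine cells", {
  set.seed(34)
  v <- runif(2000, -10, 10)
  cats <- categorize_axis(v, 2, 3)
  expect_true(all(cats %in% c("CENTRAL", "MODERATE", "EXTREME")))
  # determinism
  expect_identical(categorize_axis(v, 2, 3), cats)
})

test_that("config validation rejects inverted thresholds and bad alpha", {
  expect_error(scorecard_config(t_low = 3, t_high = 2), "t_high")
  expect_error(scorecard_config(t_low = -1, t_high = 2), "t_low")
  expect_error(scorecard_config(2, 3, alpha = 1.5), "alpha")
  # t_high from the multiplication factor
  expect_equal(scorecard_config(2, factor = 1.5)$t_high, 3)
  expect_equal(scorecard_config(2, factor = 2)$t_high, 4)
})
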