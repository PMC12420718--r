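test_that("region count matrix is complete, ordered and conservative", {
  coll <- tiny_collection()
  m <- region_count_matrix(coll)
  expect_equal(nrow(m), 3)
  cells <- as.vector(t(outer(paste0("Q", 1:4),
                             c("A", "B", "C", "D", "E", "M", "S", "R"),
                             paste)))
  expect_equal(names(m), c("x_comparison", "y_comparison", cells))
  counts <- as.matrix(m[, cells])
  entries_per <- vapply(coll$scorecards, function(sc) nrow(sc$entries), 1L)
  expect_equal(unname(rowSums(counts)), unname(entries_per))
  # grand total conservation across the three summaries
  occ <- gene_occurrence(coll)
  expect_equal(sum(counts), sum(entries_per))
  expect_equal(sum(occ$count), sum(entries_per))
})

test_that("a planted cell shows its exact count in the matrix", {
  fx <- generate_fixture(fixture_spec(n_conditions = 2,
                                      genes_per_cell = c("Q3 D" = 7),
                                      noise_genes = 30, seed = 13))
  coll <- build_scorecards(fx$comparisons, scorecard_config(2, 3))
  m <- region_count_matrix(coll)
  expect_equal(m[["Q3 D"]], 7)
  expect_equal(sum(as.matrix(m[, -(1:2)])), 7)
})

test_that("occurrence counts scorecards, not regions, and bounds hold", {
  coll <- tiny_collection()
  occ <- gene_occurrence(coll)
  expect_true(all(occ$count >= 1))
  expect_true(all(occ$count <= length(coll$scorecards)))
  # g4 is central everywhere: never reported
  expect_false("g4" %in% occ$gene_id)
  for (i in seq_len(nrow(occ))) {
    expect_equal(nrow(occ$where[[i]]), occ$count[i])
  }
})

test_that("a gene extreme in two of four conditions hits five of six cards", {
  # extreme+significant on conditions 1-2, central elsewhere: reported in
  # every pair except the all-central (3,4) pair
  mk <- function(nm, fc) make_comparison(nm, "g_target", fc, 0.01)
  cmps <- list(mk("c1", 3.5), mk("c2", -3.6), mk("c3", 0.5), mk("c4", 0.2))
  coll <- suppressWarnings(
    build_scorecards(cmps, scorecard_config(2, 3)))
  occ <- gene_occurrence(coll)
  expect_equal(occ$count[occ$gene_id == "g_target"], 5L)
  seen <- paste(occ$where[[1]]$x_comparison, "vs",
                occ$where[[1]]$y_comparison)
  expect_equal(setdiff(names(coll$scorecards), seen), "c3 vs c4")
})

test_that("exclusive genes are exactly the occurrence-one genes", {
  fx <- generate_fixture(fixture_spec(n_conditions = 3, genes_per_cell = 1,
                                      noise_genes = 50, seed = 17))
  coll <- build_scorecards(fx$comparisons, scorecard_config(2, 3))
  occ <- gene_occurrence(coll)
  excl <- exclusive_genes(coll)
  expect_setequal(excl$gene_id, occ$gene_id[occ$count == 1])
  # partition: exclusives plus multi-occurrence genes = all reported genes
  expect_setequal(c(excl$gene_id, occ$gene_id[occ$count >= 2]), occ$gene_id)
  # every plant is pair-exclusive by construction here
  expect_equal(nrow(excl), nrow(fx$truth))
  m <- match(excl$gene_id, fx$truth$gene_id)
  expect_equal(excl$quadrant, fx$truth$quadrant[m])
  expect_equal(excl$region, fx$truth$region[m])
  expect_error(
    exclusive_genes(scorecard_collection(coll$scorecards[1])),
    "at least 2")
})

test_that("difference ranking is ordered, truncated and recomputable", {
  coll <- tiny_collection()
  rk <- rank_by_difference(coll, top_n = 100)
  expect_true(all(diff(rk$difference) <= 0))
  expect_equal(rk$difference, abs(rk$x_fc - rk$y_fc))
  # the worked pair: 6.92 vs 1.7 differ by 5.22
  c1 <- make_comparison("L", "sa1", 6.92, 0.01)
  c2 <- make_comparison("K", "sa1", 1.7, 0.01)
  cc <- scorecard_collection(list(
    build_scorecard(c1, c2, scorecard_config(2, 3))))
  expect_equal(rank_by_difference(cc)$difference, 5.22)
  top2 <- rank_by_difference(coll, top_n = 2)
  expect_equal(nrow(top2), 2)
  expect_equal(top2$difference, sort(rk$difference, decreasing = TRUE)[1:2])
})

test_that("keyword frequency counts entries case-insensitively", {
  coll <- tiny_collection()
  # g1 ("ABC transporter permease") is reported in all 3 scorecards and
  # g3 ("ABC transporter ATPase") in 2; g2 ("nitrate reductase") carries
  # its annotation into 2 scorecards
  kf <- keyword_frequency(coll, c("abc transporter", "nitrate reductase",
                                  "absent term"))
  expect_equal(kf$count, c(5L, 2L, 0L))
  expect_gt(attr(kf, "total_annotations"), 0)
  empty <- keyword_frequency(coll, character())
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "total_annotations"),
               attr(kf, "total_annotations"))
  expect_error(keyword_frequency(coll, c("ok", "")), "non-empty")
})

test_that("series tracking agrees with direct per-scorecard lookup", {
  fx <- generate_longitudinal_fixture(
    list(g1 = c("M", "A", "A", NA), g2 = c(NA, "E", "S", "S")),
    noise_genes = 10, seed = 21)
  coll <- build_scorecards(fx$comparisons, scorecard_config(2, 3),
                           pairs = fx$pairs)
  for (g in c("g1", "g2", "ghost")) {
    track <- track_regions_over_series(coll, g, fx$series)
    direct <- lapply(fx$series, function(k) {
      ent <- coll$scorecards[[k]]$entries
      i <- match(g, ent$gene_id)
      if (is.na(i)) c(NA_character_, NA_character_) else
        c(ent$quadrant[i], ent$region[i])
    })
    expect_equal(track$quadrant, vapply(direct, `[`, character(1), 1))
    expect_equal(track$region, vapply(direct, `[`, character(1), 2))
  }
  expect_error(track_regions_over_series(coll, "g1", "no such pair"),
               "unknown pair")
})

test_that("merged overview preserves groups, sizes and coordinates", {
  coll <- tiny_collection()
  ov <- merged_overview(coll)
  expect_equal(names(ov), names(coll$scorecards))
  for (k in names(ov)) {
    sc <- coll$scorecards[[k]]
    expect_equal(nrow(ov[[k]]), nrow(sc$entries))
    expect_equal(ov[[k]]$x_fc, sc$entries$x_fc)
    expect_equal(ov[[k]]$y_fc, sc$entries$y_fc)
  }
  # empty scorecards keep an (empty) group
  empty_coll <- build_scorecards(
    list(make_comparison("A", "g", 0.1, 0.9),
         make_comparison("B", "g", 0.1, 0.9)),
    scorecard_config(2, 3))
  expect_equal(nrow(merged_overview(empty_coll)[[1]]), 0)
  expect_equal(length(merged_overview(empty_coll)), 1)
})
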