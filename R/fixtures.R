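#' Specification for a synthetic planted-region fixture
#'
#' Describes a seeded synthetic study in which genes are planted at known
#' (quadrant, region) cells of known scorecards, so that every analysis
#' step can be validated against exact ground truth. Planted coordinates
#' are drawn at band midpoints plus a jitter strictly smaller than the
#' distance to the nearest band boundary, which makes the planted cell a
#' certainty rather than a probability. Planted genes exist only in the
#' two comparisons of their target pair (they are dropped as missing
#' partners everywhere else); noise genes are central and non-significant
#' in every comparison and are never reported.
#'
#' Significant genes receive `p ~ Uniform(0, 0.8 * alpha)` on both axes
#' and non-significant ones `p ~ Uniform(1.2 * alpha, 1)`, keeping a
#' guard band around `alpha`.
#'
#' @param n_conditions Number of comparisons (>= 2); all
#'   `choose(n, 2)` pairs are planted.
#' @param genes_per_cell Genes planted per (quadrant, region) cell per
#'   pair: a single count applied to all 32 cells, or a named integer
#'   vector keyed `"Q1 A"`, ... (missing cells get 0).
#' @param noise_genes Number of central, non-significant background genes
#'   shared by all comparisons.
#' @param t_low,t_high,alpha Thresholds and significance level the
#'   fixture is built for.
#' @param jitter Coordinate noise half-width; must be strictly less than
#'   `min(t_low, t_high - t_low) / 2` so no draw can cross a band
#'   boundary.
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_conditions = 4, genes_per_cell = 5,
                         noise_genes = 2000, t_low = 2, t_high = 3,
                         alpha = 0.05, jitter = 0.2, seed = 1) {
  stopifnot(n_conditions >= 2, t_low > 0, t_high > t_low,
            alpha > 0, alpha < 1, noise_genes >= 0, jitter >= 0)
  bound <- min(t_low, t_high - t_low) / 2
  if (jitter >= bound) {
    stop("jitter (", jitter, ") must be strictly less than half the ",
         "narrowest band width (", bound, ")", call. = FALSE)
  }
  cells <- region_columns("full")
  if (length(genes_per_cell) == 1 && is.null(names(genes_per_cell))) {
    genes_per_cell <- setNames(rep(as.integer(genes_per_cell),
                                   length(cells)), cells)
  } else {
    bad <- setdiff(names(genes_per_cell), cells)
    if (length(bad) > 0) {
      stop("unknown cell: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    full <- setNames(integer(length(cells)), cells)
    full[names(genes_per_cell)] <- as.integer(genes_per_cell)
    genes_per_cell <- full
  }
  structure(
    list(n_conditions = n_conditions, genes_per_cell = genes_per_cell,
         noise_genes = as.integer(noise_genes), t_low = t_low,
         t_high = t_high, alpha = alpha, jitter = jitter,
         seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# region letter -> x/y band under the package letter convention
REGION_BANDS <- list(
  A = c(x = "EXTREME", y = "EXTREME"),
  B = c(x = "MODERATE", y = "EXTREME"),
  C = c(x = "EXTREME", y = "MODERATE"),
  D = c(x = "EXTREME", y = "CENTRAL"),
  E = c(x = "CENTRAL", y = "EXTREME"),
  M = c(x = "MODERATE", y = "MODERATE"),
  S = c(x = "MODERATE", y = "CENTRAL"),
  R = c(x = "CENTRAL", y = "MODERATE")
)

QUADRANT_SIGNS <- list(Q1 = c(1, 1), Q2 = c(-1, 1), Q3 = c(-1, -1),
                       Q4 = c(1, -1))

# signed coordinate at the band midpoint +- jitter; midpoints keep the
# extreme band bounded away from the clamping cap
band_coordinate <- function(band, sign, spec) {
  mid <- switch(band,
    CENTRAL = spec$t_low / 2,
    MODERATE = (spec$t_low + spec$t_high) / 2,
    EXTREME = spec$t_high + (spec$t_high - spec$t_low) / 2
  )
  sign * (mid + runif(1, -spec$jitter, spec$jitter))
}

#' Generate a synthetic study with genes planted in known regions
#'
#' Builds the comparisons of a [fixture_spec()] and the exact ground
#' truth of where each planted gene must appear: for every enumerated
#' pair, `genes_per_cell` genes per (quadrant, region) cell land in that
#' cell by construction, with both p-values significant so that every
#' significance policy reports them. The returned truth is derived from
#' the construction, independently of the classifier.
#'
#' @param spec A [fixture_spec()].
#' @return List with `comparisons` (named list of [comparison()]
#'   objects), `pairs` (tibble as from [enumerate_scorecard_pairs()])
#'   and `truth` (tibble: `gene_id`, `x_comparison`, `y_comparison`,
#'   `quadrant`, `region`, `x_fc`, `y_fc` for every planted gene).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  cond_names <- sprintf("cond%02d", seq_len(spec$n_conditions))
  pairs <- enumerate_scorecard_pairs(cond_names)

  recs <- setNames(
    lapply(cond_names, function(nm) {
      list(gene_id = character(), log2fc = numeric(), p_value = numeric())
    }),
    cond_names
  )
  add_rec <- function(cond, gid, fc, p) {
    recs[[cond]]$gene_id <<- c(recs[[cond]]$gene_id, gid)
    recs[[cond]]$log2fc <<- c(recs[[cond]]$log2fc, fc)
    recs[[cond]]$p_value <<- c(recs[[cond]]$p_value, p)
  }

  truth <- list()
  for (pi in seq_len(nrow(pairs))) {
    for (q in QUADRANTS) {
      for (r in REGION_LETTERS) {
        n_genes <- spec$genes_per_cell[[paste(q, r)]]
        if (n_genes == 0) next
        bands <- REGION_BANDS[[r]]
        signs <- QUADRANT_SIGNS[[q]]
        for (g in seq_len(n_genes)) {
          gid <- sprintf("plant_p%02d_%s%s_%02d", pi, q, r, g)
          x_fc <- band_coordinate(bands[["x"]], signs[1], spec)
          y_fc <- band_coordinate(bands[["y"]], signs[2], spec)
          add_rec(pairs$x[pi], gid, x_fc, runif(1, 0, 0.8 * spec$alpha))
          add_rec(pairs$y[pi], gid, y_fc, runif(1, 0, 0.8 * spec$alpha))
          truth[[length(truth) + 1]] <- tibble::tibble(
            gene_id = gid, x_comparison = pairs$x[pi],
            y_comparison = pairs$y[pi], quadrant = q, region = r,
            x_fc = x_fc, y_fc = y_fc
          )
        }
      }
    }
  }

  if (spec$noise_genes > 0) {
    noise_ids <- sprintf("noise_%05d", seq_len(spec$noise_genes))
    for (cond in cond_names) {
      fc <- runif(spec$noise_genes, -1, 1) * (spec$t_low - spec$jitter) * 0.9
      p <- runif(spec$noise_genes, 1.2 * spec$alpha, 1)
      recs[[cond]]$gene_id <- c(recs[[cond]]$gene_id, noise_ids)
      recs[[cond]]$log2fc <- c(recs[[cond]]$log2fc, fc)
      recs[[cond]]$p_value <- c(recs[[cond]]$p_value, p)
    }
  }

  comparisons <- lapply(cond_names, function(nm) {
    comparison(nm, tibble::as_tibble(recs[[nm]]))
  })
  names(comparisons) <- cond_names
  list(comparisons = comparisons, pairs = pairs,
       truth = dplyr::bind_rows(truth))
}

#' Generate a longitudinal fixture following a region drift script
#'
#' Emulates a time-course design (one scorecard per time point, e.g. a
#' coated versus uncoated material sampled at increasing exposure times):
#' for each scripted gene, plants it at the scripted (quadrant, region)
#' cell of each time point's scorecard, or centrally (unreported) where
#' the script says `NA`. Tracking the gene over the series must recover
#' the script exactly.
#'
#' @param drift Named list: gene id -> character vector of length `T`
#'   with region letters (A, B, C, D, E, M, S, R) or `NA` for
#'   not-reported time points. All scripts must share one length.
#' @param quadrant Quadrant the scripted genes are planted in
#'   (default `"Q1"`).
#' @param noise_genes Central background genes per time point.
#' @param t_low,t_high,alpha,jitter,seed As in [fixture_spec()].
#' @return List with `comparisons`, `pairs` (tibble, one row per time
#'   point in order), `series` (pair keys in time order), `time_key`, and
#'   `truth` (the drift list).
#' @export
generate_longitudinal_fixture <- function(drift, quadrant = "Q1",
                                          noise_genes = 100, t_low = 2,
                                          t_high = 3, alpha = 0.05,
                                          jitter = 0.2, seed = 1) {
  stopifnot(is.list(drift), length(drift) >= 1,
            !is.null(names(drift)), all(nzchar(names(drift))),
            quadrant %in% QUADRANTS)
  lens <- vapply(drift, length, 1L)
  if (length(unique(lens)) != 1) {
    stop("all drift scripts must have the same length", call. = FALSE)
  }
  n_time <- lens[[1]]
  spec <- fixture_spec(n_conditions = 2, genes_per_cell = 0,
                       noise_genes = noise_genes, t_low = t_low,
                       t_high = t_high, alpha = alpha, jitter = jitter,
                       seed = seed)
  set.seed(spec$seed)
  signs <- QUADRANT_SIGNS[[quadrant]]

  comparisons <- list()
  pairs <- tibble::tibble(x = character(), y = character())
  for (t in seq_len(n_time)) {
    xn <- sprintf("trt_t%02d", t)
    yn <- sprintf("ref_t%02d", t)
    gid <- names(drift)
    coords <- vapply(drift, function(script) {
      r <- script[t]
      if (is.na(r)) {
        c(band_coordinate("CENTRAL", signs[1], spec),
          band_coordinate("CENTRAL", signs[2], spec))
      } else {
        bands <- REGION_BANDS[[r]]
        c(band_coordinate(bands[["x"]], signs[1], spec),
          band_coordinate(bands[["y"]], signs[2], spec))
      }
    }, numeric(2))
    noise_ids <- if (noise_genes > 0) sprintf("noise_%05d", seq_len(noise_genes)) else character()
    mk <- function(fc_row) {
      noise_fc <- runif(noise_genes, -1, 1) * (t_low - jitter) * 0.9
      tibble::tibble(
        gene_id = c(gid, noise_ids),
        log2fc = c(coords[fc_row, ], noise_fc),
        p_value = c(runif(length(gid), 0, 0.8 * alpha),
                    runif(noise_genes, 1.2 * alpha, 1))
      )
    }
    comparisons[[xn]] <- comparison(xn, mk(1))
    comparisons[[yn]] <- comparison(yn, mk(2))
    pairs <- dplyr::bind_rows(pairs, tibble::tibble(x = xn, y = yn))
  }
  series <- paste(pairs$x, "vs", pairs$y)
  list(comparisons = comparisons, pairs = pairs, series = series,
       time_key = setNames(seq_len(n_time), series), truth = drift)
}
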