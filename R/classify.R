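#' Categorize a log2 fold-change against the two thresholds
#'
#' An axis value is `CENTRAL` when `|v| < t_low`, `MODERATE` when
#' `t_low <= |v| < t_high`, and `EXTREME` when `|v| >= t_high`; a value
#' exactly at a threshold belongs to the outer band.
#'
#' @param v Numeric vector of finite log2 fold-changes.
#' @param t_low,t_high Thresholds, `0 < t_low < t_high` (`t_high` may be
#'   `Inf`, in which case no value is `EXTREME`).
#' @return Character vector in `{"CENTRAL", "MODERATE", "EXTREME"}`.
#' @examples
#' categorize_axis(c(-1.98, -3.95, 2, 3), 2, 3)
#' @export
categorize_axis <- function(v, t_low, t_high) {
  stopifnot(t_low > 0, t_high > t_low)
  if (any(!is.finite(v))) {
    stop("log2 fold-changes must be finite; sanitize on load", call. = FALSE)
  }
  a <- abs(v)
  ifelse(a >= t_high, "EXTREME", ifelse(a >= t_low, "MODERATE", "CENTRAL"))
}

#' Assign the Cartesian quadrant of a fold-change pair
#'
#' Q1 and Q3 hold genes moving in the same direction in both conditions
#' (both up, both down); Q2 and Q4 hold discordant genes. A zero
#' coordinate counts as positive, which only matters for genes lying
#' exactly on an axis.
#'
#' @param x,y Numeric vectors of finite log2 fold-changes.
#' @return Character vector in `{"Q1", "Q2", "Q3", "Q4"}`.
#' @export
assign_quadrant <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  xp <- x >= 0
  yp <- y >= 0
  ifelse(xp & yp, "Q1", ifelse(!xp & yp, "Q2", ifelse(!xp & !yp, "Q3", "Q4")))
}

# (x category, y category) -> region letter under the default convention:
# x-dominant letters are C (extreme x / moderate y), D (extreme x /
# central y), S (moderate x / central y); y-dominant are B, E, R.
REGION_MAP <- c(
  "EXTREME.EXTREME"   = "A",
  "EXTREME.MODERATE"  = "C",
  "MODERATE.EXTREME"  = "B",
  "EXTREME.CENTRAL"   = "D",
  "CENTRAL.EXTREME"   = "E",
  "MODERATE.MODERATE" = "M",
  "MODERATE.CENTRAL"  = "S",
  "CENTRAL.MODERATE"  = "R",
  "CENTRAL.CENTRAL"   = NA_character_
)

LETTER_SWAP <- c(A = "A", B = "C", C = "B", D = "E", E = "D",
                 M = "M", S = "R", R = "S")

#' Classify fold-change pairs into scorecard regions
#'
#' The core classifier: maps each `(x, y)` log2 fold-change pair to a
#' quadrant and a region of interest under the configuration's thresholds
#' and mode. Genes central on both axes are never reported; `"standard"`
#' mode additionally masks the moderate-only regions M, S, R; `"fourway"`
#' mode uses only `t_low` and reports quadrant membership without region
#' letters.
#'
#' @param x,y Numeric vectors of finite log2 fold-changes (recycled to a
#'   common length).
#' @param config A [scorecard_config()].
#' @return Tibble with columns `quadrant`, `region` (letter or `NA`) and
#'   `reported` (logical). Unreported points have `NA` quadrant and
#'   region; reported points in `"fourway"` mode have a quadrant but `NA`
#'   region.
#' @examples
#' cfg <- scorecard_config(t_low = 2, t_high = 3)
#' classify_point(-3.95, -1.98, cfg)  # Q3, region D
#' @export
classify_point <- function(x, y, config) {
  stopifnot(inherits(config, "scorecard_config"))
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  t_low <- config$t_low
  t_high <- if (config$mode == "fourway") Inf else config$t_high
  cx <- categorize_axis(x, t_low, t_high)
  cy <- categorize_axis(y, t_low, t_high)
  quad <- assign_quadrant(x, y)
  region <- unname(REGION_MAP[paste(cx, cy, sep = ".")])
  if (config$swap_letter_axes) {
    region <- ifelse(is.na(region), region, unname(LETTER_SWAP[region]))
  }
  reported <- !(cx == "CENTRAL" & cy == "CENTRAL")
  if (config$mode == "standard") {
    reported <- reported & region %in% c("A", "B", "C", "D", "E")
  }
  if (config$mode == "fourway") {
    region <- rep(NA_character_, n)
  }
  quad[!reported] <- NA_character_
  region[!reported] <- NA_character_
  tibble::tibble(quadrant = quad, region = region, reported = reported)
}

#' Apply the significance filter to classified genes
#'
#' Decides, per gene, whether its p-values support reporting it given the
#' axis categories of its position. Under `"non_central_axes"` (the
#' default) each axis whose category is moderate or extreme must have
#' `p <= alpha`; central axes are exempt, so a gene markedly changed in
#' one condition and flat in the other (regions D/E) is judged only on
#' the changed axis. `"both_axes"` and `"either_axis"` test both axes
#' regardless of category. A missing p-value fails its axis test unless
#' `config$missing_p = "pass"`.
#'
#' @param x_p,y_p Numeric vectors of p-values (may contain `NA`).
#' @param x_cat,y_cat Axis categories from [categorize_axis()].
#' @param config A [scorecard_config()].
#' @return Logical vector.
#' @export
passes_significance <- function(x_p, y_p, x_cat, y_cat, config) {
  stopifnot(inherits(config, "scorecard_config"))
  alpha <- config$alpha
  missing_ok <- config$missing_p == "pass"
  ok <- function(p) ifelse(is.na(p), missing_ok, p <= alpha)
  switch(config$significance_policy,
    both_axes = ok(x_p) & ok(y_p),
    either_axis = ok(x_p) | ok(y_p),
    non_central_axes =
      (x_cat == "CENTRAL" | ok(x_p)) & (y_cat == "CENTRAL" | ok(y_p))
  )
}

#' Build a scorecard from two comparisons
#'
#' Intersects the gene sets of the x- and y-axis comparisons, classifies
#' every shared gene, applies the significance filter, and returns the
#' reported entries together with exhaustive drop accounting: genes
#' present in only one comparison (`missing_partner`), genes whose
#' position is not reported in the chosen mode (`central`), and genes
#' failing the significance filter (`not_significant`). Entries plus
#' drops always account for the full union of the two gene sets.
#'
#' @param cx,cy [comparison()] objects for the x- and y-axis.
#' @param config A [scorecard_config()].
#' @return An object of class `scorecard`: a list with `x_comparison`,
#'   `y_comparison`, `config`, `entries` (tibble: `gene_id`, `x_fc`,
#'   `y_fc`, `x_p`, `y_p`, `quadrant`, `region`, `annotation`) and
#'   `dropped` (named integer vector).
#' @export
build_scorecard <- function(cx, cy, config) {
  stopifnot(inherits(cx, "de_comparison"), inherits(cy, "de_comparison"),
            inherits(config, "scorecard_config"))
  if (identical(cx$name, cy$name)) {
    stop("x and y comparisons must differ", call. = FALSE)
  }
  common <- intersect(cx$records$gene_id, cy$records$gene_id)
  n_union <- length(union(cx$records$gene_id, cy$records$gene_id))
  if (length(common) == 0) {
    warning("comparisons '", cx$name, "' and '", cy$name,
            "' share no genes; scorecard is empty", call. = FALSE)
  }
  rx <- cx$records[match(common, cx$records$gene_id), ]
  ry <- cy$records[match(common, cy$records$gene_id), ]
  cls <- classify_point(rx$log2fc, ry$log2fc, config)
  t_high_eff <- if (config$mode == "fourway") Inf else config$t_high
  xcat <- categorize_axis(rx$log2fc, config$t_low, t_high_eff)
  ycat <- categorize_axis(ry$log2fc, config$t_low, t_high_eff)
  sig <- passes_significance(rx$p_value, ry$p_value, xcat, ycat, config)
  keep <- cls$reported & sig
  ann <- ifelse(is.na(rx$annotation), ry$annotation, rx$annotation)
  entries <- tibble::tibble(
    gene_id = common[keep],
    x_fc = rx$log2fc[keep],
    y_fc = ry$log2fc[keep],
    x_p = rx$p_value[keep],
    y_p = ry$p_value[keep],
    quadrant = cls$quadrant[keep],
    region = cls$region[keep],
    annotation = ann[keep]
  )
  dropped <- c(
    missing_partner = n_union - length(common),
    central = sum(!cls$reported),
    not_significant = sum(cls$reported & !sig)
  )
  structure(
    list(
      x_comparison = cx$name,
      y_comparison = cy$name,
      config = config,
      entries = entries,
      dropped = dropped
    ),
    class = "scorecard"
  )
}

#' @export
print.scorecard <- function(x, ...) {
  cat(sprintf("<scorecard> %s (x) vs %s (y): %d reported genes\n",
              x$x_comparison, x$y_comparison, nrow(x$entries)))
  cat(sprintf("  dropped: %d missing partner, %d central/unreported, %d not significant\n",
              x$dropped[["missing_partner"]], x$dropped[["central"]],
              x$dropped[["not_significant"]]))
  invisible(x)
}

#' Key identifying a scorecard's ordered comparison pair
#'
#' @param sc A `scorecard`.
#' @return String `"<x> vs <y>"`.
#' @export
pair_key <- function(sc) {
  paste(sc$x_comparison, "vs", sc$y_comparison)
}
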