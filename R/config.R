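#' Scorecard configuration
#'
#' Bundles the parameters that define how genes are classified on the
#' pairwise log2 fold-change plane: the two fold-change thresholds, the
#' significance level, the scorecard mode and the significance policy.
#'
#' Both thresholds are on the log2 scale: a gene whose absolute log2
#' fold-change is below `t_low` on an axis is *central* on that axis,
#' between `t_low` and `t_high` it is *moderate*, and at or beyond `t_high`
#' it is *extreme*. Values exactly at a threshold belong to the outer band,
#' and `p == alpha` passes the significance filter.
#'
#' Three modes are supported. `"full"` reports all eight region letters
#' (A, B, C, D, E plus the moderate-only M, S, R); `"standard"` reports
#' only regions involving an extreme axis (A--E); `"fourway"` is the
#' classic four-way plot: a single threshold (`t_low`), quadrant-only
#' assignment, no region letters.
#'
#' @param t_low Inner log2 fold-change threshold (> 0).
#' @param t_high Outer log2 fold-change threshold (> `t_low`). Defaults to
#'   `t_low * factor`. Ignored by the classifier in `"fourway"` mode.
#' @param factor Multiplication factor used to derive `t_high` when
#'   `t_high` is not given directly (default 1.5, e.g. thresholds 2 and 3).
#' @param alpha Significance level in (0, 1); entries need `p <= alpha` on
#'   the axes their policy tests.
#' @param mode One of `"full"`, `"standard"`, `"fourway"`.
#' @param significance_policy Which axes must be significant:
#'   `"non_central_axes"` (default; every non-central axis must pass,
#'   central axes are exempt), `"both_axes"`, or `"either_axis"`.
#' @param missing_p How a missing p-value resolves on a tested axis:
#'   `"fail"` (default, conservative) or `"pass"` (use when p-values are
#'   structurally absent, e.g. contrasts derived from an expression table).
#' @param region_colors Named character vector mapping the eight region
#'   letters to colors; defaults to a colorblind-safe palette.
#' @param swap_letter_axes If `TRUE`, swap the x/y letter convention
#'   (B with C, D with E, S with R). The default convention makes C, D, S
#'   the x-dominant letters.
#'
#' @return An object of class `scorecard_config`.
#' @examples
#' scorecard_config(t_low = 2, t_high = 3, alpha = 0.05, mode = "full")
#' scorecard_config(t_low = 2, factor = 2, alpha = 0.001, mode = "standard")
#' @export
scorecard_config <- function(t_low = 2,
                             t_high = NULL,
                             factor = 1.5,
                             alpha = 0.05,
                             mode = c("full", "standard", "fourway"),
                             significance_policy = c("non_central_axes",
                                                     "both_axes",
                                                     "either_axis"),
                             missing_p = c("fail", "pass"),
                             region_colors = NULL,
                             swap_letter_axes = FALSE) {
  mode <- match.arg(mode)
  significance_policy <- match.arg(significance_policy)
  missing_p <- match.arg(missing_p)
  stopifnot(is.numeric(t_low), length(t_low) == 1, is.finite(t_low))
  if (t_low <= 0) stop("`t_low` must be positive", call. = FALSE)
  if (is.null(t_high)) {
    stopifnot(is.numeric(factor), length(factor) == 1, factor > 1)
    t_high <- t_low * factor
  }
  stopifnot(is.numeric(t_high), length(t_high) == 1, is.finite(t_high))
  if (t_high <= t_low) {
    stop("`t_high` must be greater than `t_low`", call. = FALSE)
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (is.null(region_colors)) region_colors <- default_region_colors()
  if (!all(REGION_LETTERS %in% names(region_colors))) {
    stop("`region_colors` must name all eight region letters A-E, M, S, R",
         call. = FALSE)
  }
  structure(
    list(
      t_low = t_low,
      t_high = t_high,
      alpha = alpha,
      mode = mode,
      significance_policy = significance_policy,
      missing_p = missing_p,
      region_colors = region_colors[REGION_LETTERS],
      swap_letter_axes = isTRUE(swap_letter_axes)
    ),
    class = "scorecard_config"
  )
}

#' Default region color palette
#'
#' A colorblind-safe (Okabe-Ito) mapping of the eight region letters.
#'
#' @return Named character vector of hex colors.
#' @export
default_region_colors <- function() {
  c(A = "#D55E00", B = "#0072B2", C = "#009E73", D = "#CC79A7",
    E = "#56B4E9", M = "#E69F00", S = "#999999", R = "#F0E442")
}

#' @export
print.scorecard_config <- function(x, ...) {
  cat("<scorecard_config>\n")
  cat(sprintf("  thresholds : t_low = %g, t_high = %g (log2FC)\n",
              x$t_low, x$t_high))
  cat(sprintf("  alpha      : %g\n", x$alpha))
  cat(sprintf("  mode       : %s\n", x$mode))
  cat(sprintf("  policy     : %s (missing p -> %s)\n",
              x$significance_policy, x$missing_p))
  invisible(x)
}

# configs must agree on classification-relevant fields to be aggregated
config_compatible <- function(a, b) {
  isTRUE(all.equal(a[c("t_low", "t_high", "alpha", "mode",
                       "significance_policy", "missing_p",
                       "swap_letter_axes")],
                   b[c("t_low", "t_high", "alpha", "mode",
                       "significance_policy", "missing_p",
                       "swap_letter_axes")]))
}
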