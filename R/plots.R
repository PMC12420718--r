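#' Plot rendering options
#'
#' Shared options for the four figure types. Every plotting function
#' returns a `scorecard_plot` object holding both the `ggplot` and a
#' machine-checkable manifest (marker/dot/bar coordinates, colors,
#' counts), so figures can be verified without inspecting pixels.
#'
#' @param path Optional output file (png/svg/pdf by extension); when
#'   given, the figure is written with [ggplot2::ggsave()].
#' @param width,height Figure size in inches.
#' @param declutter If `TRUE`, label at most `max_labels` genes, chosen
#'   deterministically by distance from the origin (ties by gene id).
#' @param max_labels Label budget under decluttering.
#' @param seed Seed recorded for deterministic rendering.
#' @return An object of class `plot_spec`.
#' @export
plot_spec <- function(path = NULL, width = 7, height = 6,
                      declutter = FALSE, max_labels = 25, seed = 0) {
  structure(
    list(path = path, width = width, height = height,
         declutter = isTRUE(declutter), max_labels = max_labels,
         seed = as.integer(seed)),
    class = "plot_spec"
  )
}

#' @export
print.scorecard_plot <- function(x, ...) {
  cat(sprintf("<scorecard_plot> kind=%s, %d plotted elements\n",
              x$manifest$kind, x$manifest$n_elements))
  invisible(x)
}

finish_plot <- function(p, manifest, spec) {
  if (!is.null(spec$path)) {
    ggplot2::ggsave(spec$path, plot = p, width = spec$width,
                    height = spec$height)
    manifest$file <- spec$path
  }
  structure(list(plot = p, manifest = manifest), class = "scorecard_plot")
}

region_color_of <- function(region, quadrant, colors) {
  # fourway entries have no region letter; color by quadrant sign pattern
  ifelse(is.na(region),
         ifelse(quadrant %in% c("Q1", "Q3"), "#444444", "#888888"),
         unname(colors[region]))
}

#' Scorecard scatter plot
#'
#' The core figure: each reported gene as one marker on the (x, y) log2
#' fold-change plane, colored by region, with dashed guide lines at the
#' thresholds on both axes (only the inner threshold in fourway mode).
#'
#' @param sc A [build_scorecard()] scorecard.
#' @param spec A [plot_spec()].
#' @return A `scorecard_plot`; its manifest lists `markers` (tibble of
#'   gene, coordinates, region, color), `guides` (threshold positions)
#'   and `labels`.
#' @export
plot_scorecard <- function(sc, spec = plot_spec()) {
  stopifnot(inherits(sc, "scorecard"), inherits(spec, "plot_spec"))
  cfg <- sc$config
  guides <- if (cfg$mode == "fourway") c(-cfg$t_low, cfg$t_low) else
    c(-cfg$t_high, -cfg$t_low, cfg$t_low, cfg$t_high)
  ent <- sc$entries
  markers <- tibble::tibble(
    gene_id = ent$gene_id, x = ent$x_fc, y = ent$y_fc,
    region = ent$region, quadrant = ent$quadrant,
    color = region_color_of(ent$region, ent$quadrant, cfg$region_colors)
  )
  labels <- markers$gene_id
  if (spec$declutter && nrow(markers) > spec$max_labels) {
    ord <- order(-(abs(markers$x) + abs(markers$y)), markers$gene_id)
    labels <- markers$gene_id[sort(ord[seq_len(spec$max_labels)])]
  }
  markers$label <- ifelse(markers$gene_id %in% labels, markers$gene_id, "")

  p <- ggplot2::ggplot(markers, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = guides, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_vline(xintercept = guides, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_point(color = markers$color, size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.5,
                       vjust = -0.8, check_overlap = FALSE) +
    ggplot2::labs(
      x = paste0("log2 fold-change: ", sc$x_comparison),
      y = paste0("log2 fold-change: ", sc$y_comparison),
      title = paste(sc$x_comparison, "vs", sc$y_comparison)
    ) +
    ggplot2::theme_minimal()
  finish_plot(p, list(kind = "scorecard_scatter", markers = markers,
                      guides = guides, labels = labels,
                      n_elements = nrow(markers)), spec)
}

#' Radial merged overview of all scorecards
#'
#' Summarizes a whole collection on one circular layout: one radius per
#' scorecard; each reported gene places one dot on either side of its
#' radius (x-axis fold-change on one side, y-axis on the other), joined
#' by a chord whose length shows the between-condition variation. The
#' radial scale is linear in log2 fold-change; the zero ring sits at the
#' largest absolute fold-change so all dots have non-negative radius.
#'
#' @param coll A [scorecard_collection()].
#' @param spec A [plot_spec()].
#' @return A `scorecard_plot`; its manifest lists `radii` (one per
#'   scorecard), `dots` (two per entry) and `chords` (one per entry).
#' @export
plot_radial_overview <- function(coll, spec = plot_spec()) {
  stopifnot(inherits(coll, "scorecard_collection"),
            inherits(spec, "plot_spec"))
  groups <- merged_overview(coll)
  n <- length(groups)
  angles <- (seq_len(n) - 1) * 2 * pi / n
  delta <- min(pi / n * 0.3, 0.12)
  all_fc <- unlist(lapply(groups, function(g) c(g$x_fc, g$y_fc)))
  r0 <- if (length(all_fc) > 0) max(abs(all_fc)) else coll$config$t_high
  colors <- coll$config$region_colors

  radii <- tibble::tibble(key = names(groups), angle = angles)
  dots <- list()
  for (i in seq_len(n)) {
    g <- groups[[i]]
    if (nrow(g) == 0) next
    for (side in c("x", "y")) {
      fc <- if (side == "x") g$x_fc else g$y_fc
      ang <- angles[i] + if (side == "x") -delta else delta
      dots[[length(dots) + 1]] <- tibble::tibble(
        key = names(groups)[i], gene_id = g$gene_id, side = side,
        fc = fc, radius = r0 + fc,
        px = (r0 + fc) * cos(ang), py = (r0 + fc) * sin(ang),
        color = region_color_of(g$region, NA_character_, colors)
      )
    }
  }
  dots <- if (length(dots) > 0) dplyr::bind_rows(dots) else
    tibble::tibble(key = character(), gene_id = character(),
                   side = character(), fc = numeric(), radius = numeric(),
                   px = numeric(), py = numeric(), color = character())
  chords <- if (nrow(dots) > 0) {
    ch <- dplyr::inner_join(
      dots[dots$side == "x", c("key", "gene_id", "fc", "px", "py", "color")],
      dots[dots$side == "y", c("key", "gene_id", "fc", "px", "py")],
      by = c("key", "gene_id"), suffix = c("", "_y")
    )
    ch$variation <- abs(ch$fc - ch$fc_y)
    ch
  } else {
    tibble::tibble(key = character(), gene_id = character(),
                   fc = numeric(), px = numeric(), py = numeric(),
                   color = character(), fc_y = numeric(), px_y = numeric(),
                   py_y = numeric(), variation = numeric())
  }

  spokes <- tibble::tibble(
    xend = 2 * r0 * cos(angles), yend = 2 * r0 * sin(angles),
    key = names(groups)
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = spokes,
                          ggplot2::aes(x = 0, y = 0, xend = .data$xend,
                                       yend = .data$yend),
                          color = "grey70") +
    ggplot2::annotate("path", x = r0 * cos(seq(0, 2 * pi, length.out = 120)),
                      y = r0 * sin(seq(0, 2 * pi, length.out = 120)),
                      linetype = "dashed", color = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = coll$study_label,
                  caption = "dashed ring: log2FC = 0") +
    ggplot2::theme_void()
  if (nrow(chords) > 0) {
    p <- p + ggplot2::geom_segment(
      data = chords,
      ggplot2::aes(x = .data$px, y = .data$py, xend = .data$px_y,
                   yend = .data$py_y),
      color = chords$color, alpha = 0.6)
  }
  if (nrow(dots) > 0) {
    p <- p + ggplot2::geom_point(
      data = dots, ggplot2::aes(x = .data$px, y = .data$py),
      color = dots$color, size = 1.5)
  }
  finish_plot(p, list(kind = "radial_overview", radii = radii, dots = dots,
                      chords = chords, zero_ring = r0,
                      n_elements = nrow(dots)), spec)
}

#' Paired bar plot of one scorecard's fold-changes
#'
#' Per reported gene, two adjacent signed bars (the x- and y-axis log2
#' fold-changes) colored by region; genes are ordered by region letter
#' and then by decreasing between-condition difference, so the most
#' divergent genes of each region lead.
#'
#' @param sc A [build_scorecard()] scorecard.
#' @param spec A [plot_spec()].
#' @return A `scorecard_plot`; its manifest lists `bars` (two rows per
#'   gene: gene, axis, height, color).
#' @export
plot_paired_bars <- function(sc, spec = plot_spec()) {
  stopifnot(inherits(sc, "scorecard"), inherits(spec, "plot_spec"))
  ent <- sc$entries
  ord <- order(ent$region, -abs(ent$x_fc - ent$y_fc), ent$gene_id)
  ent <- ent[ord, ]
  bars <- tidyr::pivot_longer(
    tibble::tibble(
      gene_id = ent$gene_id, region = ent$region, quadrant = ent$quadrant,
      x = ent$x_fc, y = ent$y_fc
    ),
    cols = c("x", "y"), names_to = "axis", values_to = "height"
  )
  bars$color <- region_color_of(bars$region, bars$quadrant,
                                sc$config$region_colors)
  bars$gene_id <- factor(bars$gene_id, levels = unique(ent$gene_id))
  p <- ggplot2::ggplot(bars,
                       ggplot2::aes(x = .data$gene_id, y = .data$height,
                                    group = .data$axis)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      fill = bars$color,
                      alpha = ifelse(bars$axis == "x", 1, 0.6),
                      width = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = NULL, y = "log2 fold-change",
      title = paste(sc$x_comparison, "(solid) vs", sc$y_comparison,
                    "(light)")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
  finish_plot(p, list(kind = "paired_bars", bars = bars,
                      n_elements = nrow(bars)), spec)
}

#' Heatmap of the region count matrix
#'
#' Rows are comparison pairs, columns the (quadrant, region) cells in
#' fixed order Q1..Q4 by A..R, each annotated with its gene count; zero
#' cells are drawn in a distinct neutral fill.
#'
#' @param matrix A [region_count_matrix()] tibble.
#' @param spec A [plot_spec()].
#' @return A `scorecard_plot`; its manifest lists `cells` (pair, cell,
#'   count).
#' @export
plot_region_heatmap <- function(matrix, spec = plot_spec()) {
  stopifnot(is.data.frame(matrix), inherits(spec, "plot_spec"))
  cell_cols <- setdiff(names(matrix), c("x_comparison", "y_comparison"))
  long <- tidyr::pivot_longer(matrix, cols = dplyr::all_of(cell_cols),
                              names_to = "cell", values_to = "count")
  long$pair <- paste(long$x_comparison, "vs", long$y_comparison)
  long$cell <- factor(long$cell, levels = cell_cols)
  long$pair <- factor(long$pair, levels = unique(long$pair))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$cell, y = .data$pair,
                                          fill = .data$count)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "#D55E00") +
    ggplot2::labs(x = NULL, y = NULL, fill = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
  finish_plot(p, list(kind = "region_heatmap",
                      cells = long[, c("pair", "cell", "count")],
                      n_elements = nrow(long)), spec)
}
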