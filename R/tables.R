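#' Write the study's summary tables
#'
#' Emits the five standard tables of a scorecard study as CSV files with
#' deterministic row order: the region count matrix, the exclusive-gene
#' table (X-axis, Y-axis, quadrant + region, gene symbol), the gene
#' occurrence table (gene, frequency, notes), the difference ranking,
#' and a run summary (thresholds, alpha, mode, policy, per-scorecard
#' entry and drop counts).
#'
#' @param coll A [scorecard_collection()].
#' @param dir Output directory (created if needed).
#' @param format Output format; `"csv"`.
#' @param top_n Rows kept in the difference ranking (default 30).
#' @return Named character vector of the files written, invisibly.
#' @export
write_tables <- function(coll, dir, format = "csv", top_n = 30) {
  stopifnot(inherits(coll, "scorecard_collection"))
  format <- match.arg(format, "csv")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }

  occ <- gene_occurrence(coll)
  occ_tab <- tibble::tibble(
    gene = occ$gene_id,
    frequency = occ$count,
    notes = NA_character_
  )
  # notes column: first non-missing annotation seen for the gene
  ent <- collection_entries(coll)
  first_ann <- ent[!is.na(ent$annotation), c("gene_id", "annotation")]
  first_ann <- first_ann[!duplicated(first_ann$gene_id), ]
  occ_tab$notes <- first_ann$annotation[match(occ_tab$gene,
                                              first_ann$gene_id)]

  excl <- if (length(coll$scorecards) >= 2) exclusive_genes(coll) else
    tibble::tibble(x_comparison = character(), y_comparison = character(),
                   quadrant = character(), region = character(),
                   gene_id = character())
  excl_tab <- tibble::tibble(
    x_axis = excl$x_comparison, y_axis = excl$y_comparison,
    quadrant_roi = paste(excl$quadrant, excl$region),
    symbol = excl$gene_id
  )
  if (nrow(excl) == 0) excl_tab <- excl_tab[0, ]

  cfg <- coll$config
  summary_tab <- dplyr::bind_rows(lapply(unname(coll$scorecards), function(sc) {
    tibble::tibble(
      x_comparison = sc$x_comparison, y_comparison = sc$y_comparison,
      t_low = cfg$t_low, t_high = cfg$t_high, alpha = cfg$alpha,
      mode = cfg$mode, significance_policy = cfg$significance_policy,
      entries = nrow(sc$entries),
      dropped_missing_partner = sc$dropped[["missing_partner"]],
      dropped_central = sc$dropped[["central"]],
      dropped_not_significant = sc$dropped[["not_significant"]]
    )
  }))

  files <- c(
    region_counts = file.path(dir, "region_counts.csv"),
    exclusive_genes = file.path(dir, "exclusive_genes.csv"),
    gene_occurrence = file.path(dir, "gene_occurrence.csv"),
    difference_ranking = file.path(dir, "difference_ranking.csv"),
    run_summary = file.path(dir, "run_summary.csv")
  )
  readr::write_csv(region_count_matrix(coll), files[["region_counts"]],
                   na = "")
  readr::write_csv(excl_tab, files[["exclusive_genes"]], na = "")
  readr::write_csv(occ_tab, files[["gene_occurrence"]], na = "")
  readr::write_csv(rank_by_difference(coll, top_n = top_n),
                   files[["difference_ranking"]], na = "")
  readr::write_csv(summary_tab, files[["run_summary"]], na = "")
  invisible(files)
}

#' Write a human-readable, machine-parseable study log
#'
#' One section per scorecard, one subsection per occupied (quadrant,
#' region) cell, one line per reported gene with its coordinates and
#' p-values. The line grammar is documented in the file header so the
#' log can be parsed back (e.g. to recount gene occurrences). Contains
#' no timestamps, so identical inputs give byte-identical logs.
#'
#' @param coll A [scorecard_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_log <- function(coll, path) {
  stopifnot(inherits(coll, "scorecard_collection"))
  cfg <- coll$config
  lines <- c(
    "# descorecard study log",
    "# grammar:",
    "#   scorecard section : '== <x_comparison> vs <y_comparison> (<n> entries) =='",
    "#   region subsection  : '-- <quadrant> <region> (<n> entries) --'",
    "#   entry line         : 'gene<TAB>x_fc<TAB>y_fc<TAB>x_p<TAB>y_p'",
    sprintf("# config: t_low=%.15g t_high=%.15g alpha=%.15g mode=%s policy=%s",
            cfg$t_low, cfg$t_high, cfg$alpha, cfg$mode,
            cfg$significance_policy)
  )
  fmt_p <- function(p) ifelse(is.na(p), "NA", sprintf("%.15g", p))
  for (sc in coll$scorecards) {
    lines <- c(lines, sprintf("== %s vs %s (%d entries) ==",
                              sc$x_comparison, sc$y_comparison,
                              nrow(sc$entries)))
    if (nrow(sc$entries) == 0) next
    cell <- if (cfg$mode == "fourway") sc$entries$quadrant else
      paste(sc$entries$quadrant, sc$entries$region)
    for (lab in intersect(region_columns(cfg$mode), unique(cell))) {
      rows <- sc$entries[cell == lab, ]
      rows <- rows[order(rows$gene_id), ]
      lines <- c(lines,
                 sprintf("-- %s (%d entries) --", lab, nrow(rows)),
                 sprintf("%s\t%.15g\t%.15g\t%s\t%s", rows$gene_id,
                         rows$x_fc, rows$y_fc, fmt_p(rows$x_p),
                         fmt_p(rows$y_p)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
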