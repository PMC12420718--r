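#' Collect scorecards for a study
#'
#' A collection holds every scorecard of a study (one per ordered
#' comparison pair) under a single shared configuration, and is the input
#' to all cross-scorecard aggregation: region count matrices, gene
#' occurrence, exclusive genes, difference rankings, keyword frequencies
#' and longitudinal tracking.
#'
#' @param scorecards List of [build_scorecard()] objects.
#' @param study_label Free-text label for the study.
#' @param time_key Optional named numeric vector mapping pair keys (see
#'   [pair_key()]) to ordinal times, for longitudinal designs.
#' @return An object of class `scorecard_collection`.
#' @export
scorecard_collection <- function(scorecards, study_label = "study",
                                 time_key = NULL) {
  stopifnot(is.list(scorecards), length(scorecards) >= 1)
  lapply(scorecards, function(sc) stopifnot(inherits(sc, "scorecard")))
  keys <- vapply(scorecards, pair_key, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate scorecard pair: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  cfg <- scorecards[[1]]$config
  for (sc in scorecards[-1]) {
    if (!config_compatible(cfg, sc$config)) {
      stop("all scorecards in a collection must share one configuration",
           call. = FALSE)
    }
  }
  names(scorecards) <- keys
  structure(
    list(scorecards = scorecards, config = cfg, study_label = study_label,
         time_key = time_key),
    class = "scorecard_collection"
  )
}

#' @export
print.scorecard_collection <- function(x, ...) {
  cat(sprintf("<scorecard_collection> '%s': %d scorecards, %d reported entries\n",
              x$study_label, length(x$scorecards),
              sum(vapply(x$scorecards, function(sc) nrow(sc$entries), 1L))))
  invisible(x)
}

#' Build all scorecards of a study
#'
#' Convenience wrapper: enumerates the comparison pairs (or takes an
#' explicit pair table) and builds one scorecard per pair into a
#' collection.
#'
#' @param comparisons Named list of [comparison()] objects.
#' @param config A [scorecard_config()].
#' @param pairs Optional tibble with columns `x`, `y` of comparison names;
#'   defaults to [enumerate_scorecard_pairs()] over all comparisons.
#' @inheritParams scorecard_collection
#' @return A [scorecard_collection()].
#' @export
build_scorecards <- function(comparisons, config, pairs = NULL,
                             study_label = "study", time_key = NULL) {
  nms <- vapply(comparisons, function(cmp) cmp$name, character(1))
  names(comparisons) <- nms
  if (is.null(pairs)) pairs <- enumerate_scorecard_pairs(comparisons)
  missing <- setdiff(unique(c(pairs$x, pairs$y)), nms)
  if (length(missing) > 0) {
    stop("unknown comparison in pairs: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cards <- lapply(seq_len(nrow(pairs)), function(i) {
    build_scorecard(comparisons[[pairs$x[i]]], comparisons[[pairs$y[i]]],
                    config)
  })
  scorecard_collection(cards, study_label = study_label, time_key = time_key)
}

# all (quadrant, region) column labels in canonical order; fourway mode
# counts per quadrant only
region_columns <- function(mode) {
  if (mode == "fourway") return(QUADRANTS)
  as.vector(t(outer(QUADRANTS, REGION_LETTERS, paste)))
}

# one tidy row per reported entry across the collection
collection_entries <- function(coll) {
  rows <- lapply(coll$scorecards, function(sc) {
    if (nrow(sc$entries) == 0) {
      return(tibble::tibble(
        x_comparison = character(), y_comparison = character(),
        gene_id = character(), x_fc = numeric(), y_fc = numeric(),
        x_p = numeric(), y_p = numeric(), quadrant = character(),
        region = character(), annotation = character()
      ))
    }
    tibble::tibble(
      x_comparison = sc$x_comparison, y_comparison = sc$y_comparison,
      sc$entries
    )
  })
  dplyr::bind_rows(rows)
}

#' Region count matrix across a collection
#'
#' One row per scorecard, one column per (quadrant, region) cell, giving
#' the number of reported genes in that cell; the shape of the study-wide
#' summary tables and of the region heatmap. Columns are zero-filled and
#' ordered Q1..Q4 by A, B, C, D, E, M, S, R (quadrants only in
#' `"fourway"` mode); each row sums to that scorecard's entry count.
#'
#' @param coll A [scorecard_collection()].
#' @return Tibble with `x_comparison`, `y_comparison` and one integer
#'   column per cell.
#' @export
region_count_matrix <- function(coll) {
  stopifnot(inherits(coll, "scorecard_collection"))
  cols <- region_columns(coll$config$mode)
  rows <- lapply(coll$scorecards, function(sc) {
    lab <- if (coll$config$mode == "fourway") sc$entries$quadrant else
      paste(sc$entries$quadrant, sc$entries$region)
    counts <- table(factor(lab, levels = cols))
    tibble::tibble(
      x_comparison = sc$x_comparison, y_comparison = sc$y_comparison,
      !!!setNames(as.list(as.integer(counts)), cols)
    )
  })
  dplyr::bind_rows(rows)
}

#' Gene occurrence across scorecards
#'
#' Counts, for every gene reported anywhere in the collection, the number
#' of scorecards reporting it; the basis for frequency tables ("appeared
#' on 65 scorecards") and for exclusive-gene detection. Genes never
#' reported are omitted.
#'
#' @param coll A [scorecard_collection()].
#' @return Tibble with `gene_id`, `count` and a list-column `where`
#'   (tibbles of `x_comparison`, `y_comparison`, `quadrant`, `region`),
#'   sorted by decreasing count then gene id.
#' @export
gene_occurrence <- function(coll) {
  stopifnot(inherits(coll, "scorecard_collection"))
  ent <- collection_entries(coll)
  if (nrow(ent) == 0) {
    return(tibble::tibble(gene_id = character(), count = integer(),
                          where = list()))
  }
  ent %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      count = dplyr::n(),
      where = list(dplyr::pick(dplyr::all_of(
        c("x_comparison", "y_comparison", "quadrant", "region")))),
      .groups = "drop"
    ) %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$gene_id)
}

#' Genes reported in exactly one scorecard
#'
#' Detects condition-specific signatures: genes biologically active in
#' only one of the study's comparisons. Requires at least two scorecards
#' (exclusivity is undefined otherwise).
#'
#' @param coll A [scorecard_collection()].
#' @return Tibble with `x_comparison`, `y_comparison`, `quadrant`,
#'   `region`, `gene_id`, sorted by pair (input order), region, gene id.
#' @export
exclusive_genes <- function(coll) {
  stopifnot(inherits(coll, "scorecard_collection"))
  if (length(coll$scorecards) < 2) {
    stop("exclusivity needs at least 2 scorecards", call. = FALSE)
  }
  occ <- gene_occurrence(coll)
  excl <- occ[occ$count == 1, ]
  if (nrow(excl) == 0) {
    return(tibble::tibble(x_comparison = character(),
                          y_comparison = character(),
                          quadrant = character(), region = character(),
                          gene_id = character()))
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(excl)), function(i) {
    tibble::tibble(excl$where[[i]], gene_id = excl$gene_id[i])
  }))
  pair_order <- names(coll$scorecards)
  out$.pair <- match(paste(out$x_comparison, "vs", out$y_comparison),
                     pair_order)
  out <- dplyr::arrange(out, .data$.pair, .data$region, .data$gene_id)
  out$.pair <- NULL
  out[, c("x_comparison", "y_comparison", "quadrant", "region", "gene_id")]
}

#' Rank reported genes by expression difference between conditions
#'
#' Orders every reported entry of the collection by the absolute
#' difference of its two log2 fold-changes, largest first — the genes
#' whose behavior differs most between the paired conditions. Ties break
#' by pair order (input order) then gene id, for reproducible tables.
#'
#' @param coll A [scorecard_collection()].
#' @param top_n Number of rows to keep (default 30).
#' @return Tibble with `x_comparison`, `y_comparison`, `quadrant`,
#'   `region`, `gene_id`, `x_fc`, `y_fc`, `difference`.
#' @export
rank_by_difference <- function(coll, top_n = 30) {
  stopifnot(inherits(coll, "scorecard_collection"),
            is.numeric(top_n), top_n >= 1)
  ent <- collection_entries(coll)
  ent$difference <- abs(ent$x_fc - ent$y_fc)
  pair_order <- names(coll$scorecards)
  ent$.pair <- match(paste(ent$x_comparison, "vs", ent$y_comparison),
                     pair_order)
  ent <- dplyr::arrange(ent, dplyr::desc(.data$difference), .data$.pair,
                        .data$gene_id)
  ent$.pair <- NULL
  head(ent[, c("x_comparison", "y_comparison", "quadrant", "region",
               "gene_id", "x_fc", "y_fc", "difference")], top_n)
}

#' Keyword frequency over reported-gene annotations
#'
#' Scans the free-text annotation of every reported entry (with
#' repetition across scorecards, matching how recurring biological
#' processes are counted over all gene descriptions in a study) for
#' case-insensitive substring matches of each keyword.
#'
#' @param coll A [scorecard_collection()].
#' @param keywords Character vector of non-empty search terms.
#' @return Tibble with `keyword`, `count`; the total number of annotation
#'   strings scanned is attached as attribute `"total_annotations"`.
#' @export
keyword_frequency <- function(coll, keywords) {
  stopifnot(inherits(coll, "scorecard_collection"), is.character(keywords))
  if (any(!nzchar(keywords))) {
    stop("keywords must be non-empty strings", call. = FALSE)
  }
  ann <- collection_entries(coll)$annotation
  ann <- ann[!is.na(ann) & nzchar(ann)]
  ann_lc <- tolower(ann)
  counts <- vapply(keywords, function(kw) {
    sum(grepl(tolower(kw), ann_lc, fixed = TRUE))
  }, integer(1))
  out <- tibble::tibble(keyword = keywords, count = unname(counts))
  attr(out, "total_annotations") <- length(ann)
  out
}

#' Track a gene's region across an ordered series of scorecards
#'
#' For longitudinal designs, follows one gene through a time-ordered
#' series of scorecards to expose shifts between regions of interest
#' (e.g. moderate at 3 minutes, extreme from 6 minutes on).
#'
#' @param coll A [scorecard_collection()].
#' @param gene_id Gene identifier.
#' @param series Character vector of pair keys (see [pair_key()]) naming
#'   scorecards in `coll`, in series order.
#' @return Tibble with one row per series element: `key`, `quadrant`,
#'   `region`, `reported` (`FALSE` with `NA` cells where the gene is not
#'   reported).
#' @export
track_regions_over_series <- function(coll, gene_id, series) {
  stopifnot(inherits(coll, "scorecard_collection"), is.character(series),
            length(series) >= 1)
  unknown <- setdiff(series, names(coll$scorecards))
  if (length(unknown) > 0) {
    stop("unknown pair key: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(series, function(k) {
    ent <- coll$scorecards[[k]]$entries
    i <- match(gene_id, ent$gene_id)
    if (is.na(i)) {
      tibble::tibble(key = k, quadrant = NA_character_,
                     region = NA_character_, reported = FALSE)
    } else {
      tibble::tibble(key = k, quadrant = ent$quadrant[i],
                     region = ent$region[i], reported = TRUE)
    }
  })
  dplyr::bind_rows(rows)
}

#' Merged per-pair overview of all reported genes
#'
#' Restructures the collection for the radial merged plot: one group per
#' scorecard, carrying each reported gene's two coordinates and region.
#' Empty scorecards yield empty (zero-row) groups, so every comparison
#' pair keeps its radius.
#'
#' @param coll A [scorecard_collection()].
#' @return Named list (by pair key) of tibbles with `gene_id`, `x_fc`,
#'   `y_fc`, `region`.
#' @export
merged_overview <- function(coll) {
  stopifnot(inherits(coll, "scorecard_collection"))
  lapply(coll$scorecards, function(sc) {
    sc$entries[, c("gene_id", "x_fc", "y_fc", "region")]
  })
}
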