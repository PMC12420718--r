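#' Create a differential-expression comparison
#'
#' A comparison holds the per-gene log2 fold-changes and (optionally
#' adjusted) p-values for one condition-versus-reference contrast. It is
#' one axis of a scorecard.
#'
#' @param name Unique label for the contrast (e.g. `"VAN_vs_untreated"`).
#' @param records Data frame with columns `gene_id`, `log2fc`, and
#'   optionally `p_value` and `annotation`.
#' @param numerator,reference Condition labels (default parsed from `name`
#'   when it contains `"_vs_"`, otherwise `name` and `""`).
#'
#' @return An object of class `de_comparison`.
#' @export
comparison <- function(name, records, numerator = NULL, reference = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  records <- tibble::as_tibble(records)
  if (!all(c("gene_id", "log2fc") %in% names(records))) {
    stop("`records` must have columns `gene_id` and `log2fc`", call. = FALSE)
  }
  if (!"p_value" %in% names(records)) records$p_value <- NA_real_
  if (!"annotation" %in% names(records)) records$annotation <- NA_character_
  records <- records[, c("gene_id", "log2fc", "p_value", "annotation")]
  records$gene_id <- as.character(records$gene_id)
  records$log2fc <- as.numeric(records$log2fc)
  records$p_value <- as.numeric(records$p_value)
  records$annotation <- as.character(records$annotation)
  if (any(!nzchar(records$gene_id)) || anyNA(records$gene_id)) {
    stop("gene_id must be non-empty", call. = FALSE)
  }
  dup <- unique(records$gene_id[duplicated(records$gene_id)])
  if (length(dup) > 0) {
    stop("duplicate gene_id in comparison '", name, "': ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(records$log2fc))) {
    stop("log2fc must be finite (sanitize upstream or use ",
         "read_comparison_table())", call. = FALSE)
  }
  bad_p <- !is.na(records$p_value) &
    (records$p_value < 0 | records$p_value > 1)
  if (any(bad_p)) stop("p_value must be in [0, 1]", call. = FALSE)
  if (is.null(numerator) || is.null(reference)) {
    parts <- strsplit(name, "_vs_", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      numerator <- numerator %||% parts[1]
      reference <- reference %||% parts[2]
    } else {
      numerator <- numerator %||% name
      reference <- reference %||% ""
    }
  }
  structure(
    list(name = name, numerator = numerator, reference = reference,
         records = records),
    class = "de_comparison"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.de_comparison <- function(x, ...) {
  cat(sprintf("<de_comparison> %s: %d genes\n", x$name, nrow(x$records)))
  invisible(x)
}

#' Read per-comparison differential-expression results from a CSV file
#'
#' Reads a wide table (one gene-identifier column plus one or more
#' fold-change / p-value column pairs, one pair per contrast) and returns
#' one comparison per declared pair, together with a load report.
#'
#' Sanitization: rows whose fold-change cell does not parse as a number
#' (e.g. the text `"NA"`) are dropped from that comparison and counted;
#' non-finite fold-changes (infinities from zero denominators upstream)
#' are clamped to `fc_cap` and counted; unparseable p-values become
#' missing p (resolved later by the significance policy).
#'
#' @param path CSV file (RFC-4180, UTF-8, header row required).
#' @param gene_col Name of the gene-identifier column.
#' @param comparisons Named list describing the column pairs, e.g.
#'   `list(VAN = c(fc = "fc_VAN", p = "p_VAN", annotation = "desc"))`.
#'   The `p` and `annotation` entries are optional per comparison.
#' @param log2_input If `FALSE`, fold-change columns hold raw ratios and
#'   are converted with `log2()` on load (non-positive ratios are dropped
#'   as unparseable).
#' @param fc_cap Clamp for non-finite / out-of-range log2 fold-changes
#'   (default 20).
#'
#' @return A list with `comparisons` (named list of [comparison()] objects)
#'   and `report` (tibble with one row per comparison: rows read, kept,
#'   dropped as unparseable, clamped).
#' @export
read_comparison_table <- function(path, gene_col, comparisons,
                                  log2_input = TRUE, fc_cap = 20) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(is.list(comparisons), length(comparisons) >= 1,
            !is.null(names(comparisons)), all(nzchar(names(comparisons))))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (!gene_col %in% names(raw)) {
    stop("missing declared column: ", gene_col, call. = FALSE)
  }
  gene_ids <- as.character(raw[[gene_col]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stop("duplicate gene_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }

  out <- list()
  report <- list()
  for (nm in names(comparisons)) {
    map <- comparisons[[nm]]
    fc_col <- unname(map[["fc"]])
    if (is.null(fc_col) || is.na(fc_col)) {
      stop("comparison '", nm, "' must declare an `fc` column", call. = FALSE)
    }
    p_col <- if ("p" %in% names(map)) unname(map[["p"]]) else NULL
    a_col <- if ("annotation" %in% names(map)) unname(map[["annotation"]]) else NULL
    for (col in c(fc_col, p_col, a_col)) {
      if (!col %in% names(raw)) {
        stop("missing declared column: ", col, call. = FALSE)
      }
    }
    fc <- suppressWarnings(as.numeric(raw[[fc_col]]))
    if (!log2_input) {
      fc <- ifelse(!is.na(fc) & fc > 0, log2(fc), NA_real_)
    }
    n_clamped <- sum(is.infinite(fc) | (!is.na(fc) & abs(fc) > fc_cap))
    fc <- pmin(pmax(fc, -fc_cap), fc_cap)
    keep <- !is.na(fc)
    p <- if (is.null(p_col)) rep(NA_real_, nrow(raw)) else
      suppressWarnings(as.numeric(raw[[p_col]]))
    p[!is.na(p) & (p < 0 | p > 1)] <- NA_real_
    ann <- if (is.null(a_col)) rep(NA_character_, nrow(raw)) else
      as.character(raw[[a_col]])
    out[[nm]] <- comparison(
      name = nm,
      records = tibble::tibble(
        gene_id = gene_ids[keep],
        log2fc = fc[keep],
        p_value = p[keep],
        annotation = ann[keep]
      )
    )
    report[[nm]] <- tibble::tibble(
      comparison = nm,
      rows_read = nrow(raw),
      rows_kept = sum(keep),
      rows_dropped_unparseable = sum(!keep),
      values_clamped = n_clamped
    )
  }
  list(comparisons = out, report = dplyr::bind_rows(report))
}

#' Write comparisons to a wide CSV table
#'
#' Inverse of [read_comparison_table()]: one gene column plus
#' `fc_<name>` / `p_<name>` / `annot_<name>` columns per comparison.
#' Genes absent from a comparison get empty cells.
#'
#' @param comparisons Named list of [comparison()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparisons_csv <- function(comparisons, path) {
  stopifnot(length(comparisons) >= 1)
  tabs <- lapply(comparisons, function(cmp) {
    tb <- cmp$records
    names(tb) <- c("gene_id", paste0("fc_", cmp$name), paste0("p_", cmp$name),
                   paste0("annot_", cmp$name))
    tb
  })
  wide <- Reduce(function(a, b) dplyr::full_join(a, b, by = "gene_id"), tabs)
  wide <- dplyr::arrange(wide, .data$gene_id)
  readr::write_csv(wide, path, na = "")
  invisible(path)
}

#' Derive pairwise comparisons from a condition-by-gene expression table
#'
#' For studies that release only replicate-averaged expression values
#' (e.g. FPKM) per condition, builds one comparison per unordered
#' condition pair with `log2fc = log2((A + pseudocount) / (B + pseudocount))`
#' per gene. P-values are left missing; set
#' `scorecard_config(missing_p = "pass")` to classify such contrasts
#' without a significance filter.
#'
#' @param expr Data frame with a gene-identifier column and one numeric,
#'   non-negative column per condition.
#' @param gene_col Name of the gene-identifier column (default first column).
#' @param annotation_col Optional annotation column name.
#' @param pseudocount Positive value added to both sides of the ratio
#'   (default 1, standard practice for FPKM).
#'
#' @return Named list of [comparison()] objects, one per unordered pair
#'   (earlier condition in column order is the numerator), named
#'   `"A_vs_B"`.
#' @export
derive_pairwise_comparisons <- function(expr, gene_col = names(expr)[1],
                                        annotation_col = NULL,
                                        pseudocount = 1) {
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1,
            pseudocount > 0)
  expr <- tibble::as_tibble(expr)
  cond_cols <- setdiff(names(expr), c(gene_col, annotation_col))
  if (length(cond_cols) < 2) {
    stop("need at least 2 condition columns", call. = FALSE)
  }
  vals <- as.matrix(expr[, cond_cols])
  storage.mode(vals) <- "double"
  if (anyNA(vals) || any(vals < 0)) {
    stop("expression values must be non-negative and complete", call. = FALSE)
  }
  genes <- as.character(expr[[gene_col]])
  ann <- if (is.null(annotation_col)) rep(NA_character_, length(genes)) else
    as.character(expr[[annotation_col]])
  out <- list()
  for (i in seq_len(length(cond_cols) - 1)) {
    for (j in seq(i + 1, length(cond_cols))) {
      a <- cond_cols[i]
      b <- cond_cols[j]
      nm <- paste0(a, "_vs_", b)
      out[[nm]] <- comparison(
        name = nm, numerator = a, reference = b,
        records = tibble::tibble(
          gene_id = genes,
          log2fc = log2((vals[, a] + pseudocount) / (vals[, b] + pseudocount)),
          p_value = NA_real_,
          annotation = ann
        )
      )
    }
  }
  out
}

#' Enumerate the scorecard pairs of a set of comparisons
#'
#' Every unordered pair of comparisons yields one scorecard; with `n`
#' comparisons there are `choose(n, 2)` of them (e.g. 6 from 4
#' treatment-versus-control contrasts, 105 from the 15 pairwise contrasts
#' of a 6-condition design). Axis order is deterministic: the comparison
#' earlier in the input list goes on the x-axis.
#'
#' @param comparisons List of [comparison()] objects (or their names).
#' @return Tibble with columns `x` and `y` (comparison names).
#' @export
enumerate_scorecard_pairs <- function(comparisons) {
  nms <- if (is.character(comparisons)) comparisons else
    vapply(comparisons, function(cmp) cmp$name, character(1))
  if (length(nms) < 2) stop("need at least 2 comparisons", call. = FALSE)
  if (anyDuplicated(nms)) stop("comparison names must be unique", call. = FALSE)
  idx <- utils::combn(length(nms), 2)
  tibble::tibble(x = nms[idx[1, ]], y = nms[idx[2, ]])
}
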