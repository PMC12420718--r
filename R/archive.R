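ARCHIVE_SCHEMA_VERSION <- "1.0"

#' Export a scorecard collection as a JSON archive
#'
#' Writes the whole collection — configuration, every scorecard's entries
#' and drop accounting, study label and time key — to a versioned JSON
#' archive for retrieval and further evaluation. Numbers are serialized
#' with 17 significant digits so that [import_archive()] restores every
#' double exactly. Provenance (input names, package version) is kept in a
#' block separate from the data sections; a timestamp is recorded only
#' when supplied, so repeated exports of the same collection are
#' byte-identical by default.
#'
#' @param coll A [scorecard_collection()].
#' @param path Output file path.
#' @param inputs Optional character vector of input file names to record.
#' @param timestamp Optional timestamp string to record.
#' @return `path`, invisibly.
#' @export
export_archive <- function(coll, path, inputs = NULL, timestamp = NULL) {
  stopifnot(inherits(coll, "scorecard_collection"))
  cfg <- coll$config
  obj <- list(
    schema_version = ARCHIVE_SCHEMA_VERSION,
    study_label = coll$study_label,
    config = list(
      t_low = cfg$t_low, t_high = cfg$t_high, alpha = cfg$alpha,
      mode = cfg$mode, significance_policy = cfg$significance_policy,
      missing_p = cfg$missing_p,
      region_colors = as.list(cfg$region_colors),
      swap_letter_axes = cfg$swap_letter_axes
    ),
    time_key = if (is.null(coll$time_key)) NULL else as.list(coll$time_key),
    scorecards = lapply(unname(coll$scorecards), function(sc) {
      list(
        x_comparison = sc$x_comparison,
        y_comparison = sc$y_comparison,
        dropped = as.list(sc$dropped),
        entries = as.list(sc$entries)
      )
    }),
    provenance = list(
      inputs = as.list(inputs),
      software = paste0("descorecard ", utils::packageVersion("descorecard")),
      created = timestamp
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Import a scorecard collection from a JSON archive
#'
#' Restores the collection written by [export_archive()]; import followed
#' by export is the identity on all data fields. Archives with an
#' unknown schema version are rejected.
#'
#' @param path Archive file path.
#' @return A [scorecard_collection()].
#' @export
import_archive <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("corrupt archive: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(obj$schema_version)) {
    stop("corrupt archive: missing schema_version", call. = FALSE)
  }
  if (!identical(obj$schema_version, ARCHIVE_SCHEMA_VERSION)) {
    stop("unsupported archive schema_version '", obj$schema_version,
         "' (expected '", ARCHIVE_SCHEMA_VERSION, "')", call. = FALSE)
  }
  c_ <- obj$config
  for (f in c("t_low", "t_high", "alpha", "mode", "significance_policy")) {
    if (is.null(c_[[f]])) {
      stop("corrupt archive: config missing '", f, "'", call. = FALSE)
    }
  }
  cfg <- scorecard_config(
    t_low = as.numeric(c_$t_low), t_high = as.numeric(c_$t_high),
    alpha = as.numeric(c_$alpha),
    mode = c_$mode, significance_policy = c_$significance_policy,
    missing_p = c_$missing_p %||% "fail",
    region_colors = unlist(c_$region_colors),
    swap_letter_axes = isTRUE(c_$swap_letter_axes)
  )
  cards <- lapply(seq_along(obj$scorecards), function(i) {
    s <- obj$scorecards[[i]]
    if (is.null(s$x_comparison) || is.null(s$y_comparison)) {
      stop("corrupt archive: scorecard ", i, " missing comparison names",
           call. = FALSE)
    }
    ent <- s$entries
    as_chr <- function(v) vapply(v, function(e)
      if (is.null(e)) NA_character_ else as.character(e), character(1))
    as_num <- function(v) vapply(v, function(e)
      if (is.null(e)) NA_real_ else as.numeric(e), numeric(1))
    entries <- tibble::tibble(
      gene_id = as_chr(ent$gene_id),
      x_fc = as_num(ent$x_fc),
      y_fc = as_num(ent$y_fc),
      x_p = as_num(ent$x_p),
      y_p = as_num(ent$y_p),
      quadrant = as_chr(ent$quadrant),
      region = as_chr(ent$region),
      annotation = as_chr(ent$annotation)
    )
    structure(
      list(
        x_comparison = s$x_comparison,
        y_comparison = s$y_comparison,
        config = cfg,
        entries = entries,
        dropped = c(
          missing_partner = as.integer(s$dropped$missing_partner %||% 0L),
          central = as.integer(s$dropped$central %||% 0L),
          not_significant = as.integer(s$dropped$not_significant %||% 0L)
        )
      ),
      class = "scorecard"
    )
  })
  scorecard_collection(
    cards,
    study_label = obj$study_label %||% "study",
    time_key = if (is.null(obj$time_key)) NULL else
      unlist(obj$time_key)
  )
}
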