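#' @title Screen file formats
#' @description
#' All tables are tab-delimited UTF-8 with '.' decimal separators. The count
#' matrix TSV has `plate_id` and `well_id` as its first two columns followed
#' by one column per probe. Normalized matrices are a distinct file carrying
#' a `#sigscreen normalized=true` header line so raw and normalized data can
#' never be confused. Reports are JSON with a `schema_version` field.
#' @name screen-io
NULL

.fmt_num <- function(x) {
  # fixed 6-significant-digit formatting for deterministic writers
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

#' Write a screen bundle to a directory
#'
#' Writes `counts.tsv`, `layout.tsv`, `panel.tsv` and, when ground truth is
#' present, `truth.json`. Writers are deterministic: rows keep their input
#' order and numbers are formatted at 6 significant digits.
#'
#' @param screen a `"rasl_screen"` list as returned by [simulate_screen()]
#'   or [load_screen()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(screen, dir) {
  stopifnot(is.list(screen), !is.null(screen$counts), !is.null(screen$wells),
            !is.null(screen$panel))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- data.frame(plate_id = screen$wells$plate_id,
                   well_id = screen$wells$well_id,
                   screen$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(cm, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wl <- screen$wells
  wl$cell_count <- .fmt_num(wl$cell_count)
  utils::write.table(wl, file.path(dir, "layout.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(screen$panel, file.path(dir, "panel.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(screen$truth)) {
    jsonlite::write_json(
      list(schema_version = 1L,
           compounds = screen$truth$compounds,
           genes = screen$truth$genes),
      file.path(dir, "truth.json"),
      dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}

#' @keywords internal
.collect <- function(errs, cond, msg, items = NULL) {
  if (!cond) return(errs)
  if (!is.null(items) && length(items))
    msg <- paste0(msg, ": ", paste(items, collapse = ", "))
  c(errs, msg)
}

#' Load and cross-validate a screen bundle
#'
#' Reads the three TSVs of a screen (counts, plate layout, probe panel) and
#' validates them into one consistent bundle. All identifier mismatches are
#' reported exhaustively in a single error rather than one at a time.
#'
#' @param counts_path TSV with `plate_id`, `well_id` then one column per
#'   probe, nonnegative integer counts.
#' @param layout_path TSV with `plate_id`, `well_id`, `genotype`
#'   (`WT`/`KO`), `treatment` (`untreated`/`compound`), `compound_id`
#'   (empty iff untreated) and `cell_count`.
#' @param panel_path TSV with `probe_id`, `gene_symbol`, `category` and
#'   `is_housekeeping`.
#' @return a `"rasl_screen"` list (no `truth` element).
#' @export
load_screen <- function(counts_path, layout_path, panel_path) {
  for (p in c(counts_path, layout_path, panel_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  read_tsv <- function(p) utils::read.delim(p, sep = "\t", check.names = FALSE,
                                            stringsAsFactors = FALSE,
                                            comment.char = "#")
  cm <- read_tsv(counts_path)
  wells <- read_tsv(layout_path)
  panel <- read_tsv(panel_path)
  errs <- character(0)

  need_w <- c("plate_id", "well_id", "genotype", "treatment", "compound_id",
              "cell_count")
  errs <- .collect(errs, !all(need_w %in% names(wells)),
                   "layout is missing columns",
                   setdiff(need_w, names(wells)))
  need_p <- c("probe_id", "gene_symbol", "category", "is_housekeeping")
  errs <- .collect(errs, !all(need_p %in% names(panel)),
                   "panel is missing columns", setdiff(need_p, names(panel)))
  errs <- .collect(errs, !all(c("plate_id", "well_id") %in% names(cm)),
                   "counts must start with plate_id and well_id columns")
  if (length(errs)) stop(paste(errs, collapse = "\n"), call. = FALSE)

  wells$compound_id[is.na(wells$compound_id)] <- ""
  key <- function(d) paste(d$plate_id, d$well_id, sep = ":")
  wk <- key(wells); ck <- key(cm)
  errs <- .collect(errs, anyDuplicated(wk) > 0,
                   "duplicate (plate_id, well_id) in layout",
                   unique(wk[duplicated(wk)]))
  errs <- .collect(errs, anyDuplicated(ck) > 0,
                   "duplicate (plate_id, well_id) in counts",
                   unique(ck[duplicated(ck)]))
  errs <- .collect(errs, anyDuplicated(panel$probe_id) > 0,
                   "duplicate probe_id in panel",
                   unique(panel$probe_id[duplicated(panel$probe_id)]))
  errs <- .collect(errs, length(setdiff(wk, ck)) > 0,
                   "layout wells absent from count matrix", setdiff(wk, ck))
  errs <- .collect(errs, length(setdiff(ck, wk)) > 0,
                   "count-matrix wells absent from layout", setdiff(ck, wk))
  probe_cols <- setdiff(names(cm), c("plate_id", "well_id"))
  errs <- .collect(errs, length(setdiff(probe_cols, panel$probe_id)) > 0,
                   "count columns absent from panel",
                   setdiff(probe_cols, panel$probe_id))
  errs <- .collect(errs, length(setdiff(panel$probe_id, probe_cols)) > 0,
                   "panel probes absent from count matrix",
                   setdiff(panel$probe_id, probe_cols))
  panel$is_housekeeping <- as.logical(panel$is_housekeeping)
  errs <- .collect(errs, sum(panel$is_housekeeping) < 1,
                   "panel must contain at least one housekeeping probe")
  errs <- .collect(errs, sum(panel$category == "target") > 1,
                   "panel may flag at most one probe as category = target")
  errs <- .collect(errs,
                   !all(wells$genotype %in% c("WT", "KO")),
                   "genotype must be WT or KO",
                   unique(wells$genotype[!wells$genotype %in% c("WT", "KO")]))
  errs <- .collect(errs,
                   !all(wells$treatment %in% c("untreated", "compound")),
                   "treatment must be untreated or compound")
  errs <- .collect(errs,
                   any((wells$treatment == "compound") != nzchar(wells$compound_id)),
                   "compound_id must be set iff treatment = compound",
                   wk[(wells$treatment == "compound") != nzchar(wells$compound_id)])
  errs <- .collect(errs, any(wells$cell_count < 0, na.rm = TRUE),
                   "negative cell_count in layout")
  counts <- as.matrix(cm[, probe_cols, drop = FALSE])
  errs <- .collect(errs, any(counts < 0, na.rm = TRUE),
                   "negative counts in matrix")
  errs <- .collect(errs, any(counts != round(counts), na.rm = TRUE),
                   "non-integer counts in raw matrix")
  if (length(errs))
    stop("screen validation failed:\n  ",
         paste(errs, collapse = "\n  "), call. = FALSE)

  if (any(wells$treatment == "compound" & wells$genotype != "KO"))
    warning("compound-treated wells with genotype != KO present; ",
            "this screen design treats KO cells only", call. = FALSE)

  # align counts to the layout's row order and the panel's probe order
  counts <- counts[match(wk, ck), panel$probe_id, drop = FALSE]
  storage.mode(counts) <- "double"
  rownames(counts) <- wk
  structure(list(counts = counts, wells = wells, panel = panel),
            class = "rasl_screen")
}

#' Write a QC report as JSON
#'
#' @param report a `"qc_report"` object (see [filter_wells()],
#'   [filter_probes()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(
    c(list(schema_version = 1L), unclass(report)),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a QC report written by [write_qc_report()]
#' @param path JSON file.
#' @return a `"qc_report"` object.
#' @export
read_qc_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$schema_version <- NULL
  structure(x, class = "qc_report")
}

#' Write a score table as TSV
#'
#' Deterministic column order, numbers at 6 significant digits, and a
#' `#sigscreen score_table v1` header line.
#'
#' @param scores data.frame as returned by [call_hits()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  cols <- c("plate_id", "well_id", "compound_id", "distance", "d_ref",
            "relative_score", "rank", "is_hit")
  stopifnot(all(cols %in% names(scores)))
  out <- scores[, cols]
  for (nc in c("distance", "d_ref", "relative_score"))
    out[[nc]] <- .fmt_num(out[[nc]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#sigscreen score_table v1", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#' @param path TSV file.
#' @return data.frame with the score-table columns.
#' @export
read_score_table <- function(path) {
  x <- utils::read.delim(path, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  x$is_hit <- as.logical(x$is_hit)
  x
}

#' Write a normalized matrix as TSV
#'
#' The file carries a `#sigscreen normalized=true` header line so that a
#' normalized matrix can never be mistaken for (and re-normalized as) raw
#' counts.
#'
#' @param norm a `"norm_screen"` object from [normalize_housekeeping()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(norm, path) {
  stopifnot(inherits(norm, "norm_screen"))
  out <- data.frame(plate_id = norm$wells$plate_id,
                    well_id = norm$wells$well_id,
                    apply(norm$values, 2, .fmt_num),
                    check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#sigscreen normalized=true v1", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
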