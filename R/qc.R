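#' Well-level quality filtering
#'
#' Removes wells by the screen's two well-level rules: a well is dropped iff
#' its cell count falls strictly below `cell_frac` times the mean cell count
#' of the untreated wells on the same plate (both genotypes pooled), or its
#' total read count falls strictly below `min_total_reads`. Both reasons are
#' recorded when both hold. Retained wells' counts are never altered.
#'
#' Filter order in the pipeline is fixed: wells first, then probes
#' ([filter_probes()]), because removing a well changes per-plate probe
#' totals but never another well's pass/fail status.
#'
#' @param screen a `"rasl_screen"` bundle.
#' @param cell_frac cell-count threshold as a fraction of the per-plate
#'   untreated mean (default 0.40).
#' @param min_total_reads minimum per-well total reads (default 100000).
#' @return list with `screen` (retained wells) and `report`, a
#'   `"qc_report"` holding `removed_wells` (plate_id, well_id, reason,
#'   value, threshold), `n_wells_removed`, `n_compounds_removed` (distinct
#'   compounds all of whose wells were removed) and the thresholds used.
#' @export
filter_wells <- function(screen, cell_frac = 0.40, min_total_reads = 1e5) {
  wells <- screen$wells
  counts <- screen$counts
  untr <- wells$treatment == "untreated"
  if (!any(untr))
    stop("no untreated wells: cell-count reference mean is undefined",
         call. = FALSE)
  plates <- unique(wells$plate_id)
  ref <- vapply(plates, function(p) {
    sel <- untr & wells$plate_id == p
    if (!any(sel))
      stop("plate ", p, " has no untreated wells for the cell-count reference",
           call. = FALSE)
    mean(wells$cell_count[sel])
  }, numeric(1))
  names(ref) <- plates

  cell_thresh <- cell_frac * ref[wells$plate_id]
  total_reads <- rowSums(counts)
  low_cell <- wells$cell_count < cell_thresh
  low_reads <- total_reads < min_total_reads
  removed <- low_cell | low_reads

  rw <- rbind(
    data.frame(plate_id = wells$plate_id[low_cell],
               well_id = wells$well_id[low_cell],
               reason = rep("low_cell_count", sum(low_cell)),
               value = wells$cell_count[low_cell],
               threshold = unname(cell_thresh[low_cell]),
               stringsAsFactors = FALSE),
    data.frame(plate_id = wells$plate_id[low_reads],
               well_id = wells$well_id[low_reads],
               reason = rep("low_total_reads", sum(low_reads)),
               value = unname(total_reads[low_reads]),
               threshold = rep(min_total_reads, sum(low_reads)),
               stringsAsFactors = FALSE))
  rw <- rw[order(rw$plate_id, rw$well_id, rw$reason), , drop = FALSE]
  rownames(rw) <- NULL

  comp_all <- unique(wells$compound_id[nzchar(wells$compound_id)])
  comp_kept <- unique(wells$compound_id[!removed & nzchar(wells$compound_id)])
  report <- structure(list(
    removed_wells = rw,
    n_wells_removed = sum(removed),
    n_compounds_removed = length(setdiff(comp_all, comp_kept)),
    thresholds = list(cell_frac = cell_frac,
                      min_total_reads = min_total_reads)),
    class = "qc_report")

  out <- screen
  out$counts <- counts[!removed, , drop = FALSE]
  out$wells <- wells[!removed, , drop = FALSE]
  rownames(out$wells) <- NULL
  list(screen = out, report = report)
}

#' Probe-level quality filtering
#'
#' Computes each probe's total reads per plate over the retained wells and
#' drops from the combined analysis any probe whose total falls strictly
#' below `min_probe_plate_total` on ANY plate; the failing plates are
#' recorded per probe. Dropping globally (rather than per plate) keeps the
#' combined matrix rectangular, which the downstream plate combination
#' requires. A housekeeping probe failing the filter triggers a warning
#' naming it, since it weakens the normalization denominator.
#'
#' @param screen a `"rasl_screen"` bundle (after [filter_wells()]).
#' @param min_probe_plate_total minimum per-plate probe total (default 2000).
#' @return list with `screen` (retained probes) and `report`
#'   (`removed_probes`: probe_id, plate_id, plate_total, threshold).
#' @export
filter_probes <- function(screen, min_probe_plate_total = 2000) {
  counts <- screen$counts
  plates <- unique(screen$wells$plate_id)
  plate_totals <- do.call(rbind, lapply(plates, function(p) {
    colSums(counts[screen$wells$plate_id == p, , drop = FALSE])
  }))
  rownames(plate_totals) <- plates

  fail <- plate_totals < min_probe_plate_total          # plates x probes
  drop_probe <- apply(fail, 2, any)
  if (all(drop_probe))
    stop("all probes fail the per-plate total-read filter (< ",
         min_probe_plate_total, ")", call. = FALSE)

  idx <- which(fail, arr.ind = TRUE)
  rp <- data.frame(probe_id = colnames(counts)[idx[, "col"]],
                   plate_id = plates[idx[, "row"]],
                   plate_total = plate_totals[idx],
                   threshold = rep(min_probe_plate_total, nrow(idx)),
                   stringsAsFactors = FALSE)
  rp <- rp[order(rp$probe_id, rp$plate_id), , drop = FALSE]
  rownames(rp) <- NULL

  hk_dropped <- intersect(colnames(counts)[drop_probe],
                          screen$panel$probe_id[screen$panel$is_housekeeping])
  if (length(hk_dropped))
    warning("housekeeping probe(s) failed the per-plate read filter: ",
            paste(hk_dropped, collapse = ", "), call. = FALSE)

  out <- screen
  out$counts <- counts[, !drop_probe, drop = FALSE]
  out$panel <- screen$panel[screen$panel$probe_id %in%
                              colnames(out$counts), , drop = FALSE]
  rownames(out$panel) <- NULL
  report <- structure(list(
    removed_probes = rp,
    thresholds = list(min_probe_plate_total = min_probe_plate_total)),
    class = "qc_report")
  list(screen = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  if (!is.null(x$removed_wells))
    cat(sprintf("qc_report: %d well removal record(s), %d compound(s) lost\n",
                nrow(x$removed_wells), x$n_compounds_removed))
  if (!is.null(x$removed_probes))
    cat(sprintf("qc_report: %d probe/plate failure record(s)\n",
                nrow(x$removed_probes)))
  invisible(x)
}
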