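#' Run the full screen analysis pipeline
#'
#' Chains the stages in their fixed order: well QC, probe QC, per-plate
#' housekeeping normalization, plate combination, signature derivation with
#' one-shot control-outlier removal, standardization of the signature
#' genes, distance scoring against the WT centroid and hit calling.
#'
#' @param screen a `"rasl_screen"` bundle ([simulate_screen()] or
#'   [load_screen()]).
#' @param cell_frac,min_total_reads well-filter thresholds
#'   (see [filter_wells()]).
#' @param min_probe_plate_total probe-filter threshold
#'   (see [filter_probes()]).
#' @param fc_thresh,p_thresh signature thresholds
#'   (see [differential_signature()]).
#' @param fit standardization fit population (see [standardize()]).
#' @param zscore if `FALSE`, skip per-gene standardization and compute
#'   distances on the housekeeping-normalized values directly (sensitivity
#'   analysis; the default standardized scoring gives every signature gene
#'   equal weight).
#' @return a `"screen_result"` list: `scores` (the `"score_table"`),
#'   `signature`, `outliers`, `qc_wells`, `qc_probes`, `norm`, `std`, and
#'   `n_hits`.
#' @examples
#' scr <- simulate_screen(sim_config(n_plates = 2, n_compounds = 100,
#'                                   wells_per_plate = 96, seed = 3))
#' res <- run_screen_pipeline(scr)
#' res$n_hits
#' @export
run_screen_pipeline <- function(screen,
                                cell_frac = 0.40,
                                min_total_reads = 1e5,
                                min_probe_plate_total = 2000,
                                fc_thresh = 1.5,
                                p_thresh = 0.05,
                                fit = c("all", "controls"),
                                zscore = TRUE) {
  fit <- match.arg(fit)
  fw <- filter_wells(screen, cell_frac, min_total_reads)
  fp <- filter_probes(fw$screen, min_probe_plate_total)
  norm <- combine_plates(lapply(split_screen_plates(fp$screen),
                                normalize_housekeeping))
  sig <- derive_signature(norm, fc_thresh, p_thresh)
  if (sig$signature$n_dimensions < 1)
    stop("no signature genes pass FC/p thresholds; nothing to score",
         call. = FALSE)
  excl <- if (!is.null(sig$outliers)) sig$outliers$flagged else NULL

  if (zscore) {
    std <- standardize(norm, sig$signature, fit = fit, exclude_wells = excl)
  } else {
    # identity "standardization": distances on normalized values as-is
    std <- standardize(norm, sig$signature, fit = fit, exclude_wells = excl)
    keep_keys <- paste(std$wells$plate_id, std$wells$well_id, sep = ":")
    norm_keys <- paste(norm$wells$plate_id, norm$wells$well_id, sep = ":")
    raw <- norm$values[match(keep_keys, norm_keys),
                       sig$signature$genes, drop = FALSE]
    std$values <- raw
    std$constants$m <- 0
    std$constants$s <- 1
  }
  scores <- call_hits(std)
  structure(list(scores = scores,
                 signature = sig$signature,
                 outliers = sig$outliers,
                 qc_wells = fw$report,
                 qc_probes = fp$report,
                 norm = norm,
                 std = std,
                 n_hits = sum(scores$is_hit)),
            class = "screen_result")
}

#' @keywords internal
# per-plate split of a raw screen bundle (QC'd), for plate-wise
# normalization before combination
split_screen_plates <- function(screen) {
  plates <- unique(screen$wells$plate_id)
  out <- lapply(plates, function(p) {
    sel <- screen$wells$plate_id == p
    s <- screen
    s$counts <- screen$counts[sel, , drop = FALSE]
    s$wells <- screen$wells[sel, , drop = FALSE]
    s
  })
  names(out) <- plates
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(paste0("screen_result: %d signature gene(s); %d scored",
                     " compound well(s); %d hit(s) (d < d_ref = %.4g)\n"),
              x$signature$n_dimensions, nrow(x$scores), x$n_hits,
              x$scores$d_ref[1]))
  if (!is.null(x$outliers) && nrow(x$outliers$flagged))
    cat(sprintf("  %d control outlier(s) removed by Ward clustering\n",
                nrow(x$outliers$flagged)))
  cat(sprintf("  distances: %.4g - %.4g, mean %.4g\n",
              min(x$scores$distance), max(x$scores$distance),
              mean(x$scores$distance)))
  invisible(x)
}

#' Recompute the screen's headline statistics from a deposited dataset
#'
#' Runs the full pipeline on a screen bundle stored as `counts.tsv`,
#' `layout.tsv` and `panel.tsv` in `dir` — intended for the study's own
#' deposited supplementary screen data once placed there by the user — and
#' returns the headline statistics of the screen: compounds removed by QC,
#' signature size, hit count, and the distance range and mean of the
#' compound wells.
#'
#' @param dir directory holding the three TSVs.
#' @param ... passed to [run_screen_pipeline()].
#' @return list with `n_compounds_removed`, `n_signature_genes`, `n_hits`,
#'   `distance_min`, `distance_max`, `distance_mean` and the full
#'   `"screen_result"` as `result`.
#' @export
reproduce_screen_statistics <- function(dir, ...) {
  scr <- load_screen(file.path(dir, "counts.tsv"),
                     file.path(dir, "layout.tsv"),
                     file.path(dir, "panel.tsv"))
  res <- run_screen_pipeline(scr, ...)
  list(n_compounds_removed = res$qc_wells$n_compounds_removed,
       n_signature_genes = res$signature$n_dimensions,
       n_hits = res$n_hits,
       distance_min = min(res$scores$distance),
       distance_max = max(res$scores$distance),
       distance_mean = mean(res$scores$distance),
       result = res)
}
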