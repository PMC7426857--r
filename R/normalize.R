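#' Housekeeping-sum normalization
#'
#' Divides each well's counts by that well's summed counts over the
#' housekeeping probes, the assay's per-well normalization. The result is
#' invariant to any uniform rescaling of a well's raw counts (library size
#' cancels), and the housekeeping probes themselves sum to exactly 1 in
#' every retained well. Wells whose housekeeping sum is zero carry no
#' normalization reference and are removed and reported.
#'
#' No further scale factor is applied: a constant factor would cancel in
#' the per-gene standardization that precedes distance scoring.
#'
#' @param screen a `"rasl_screen"` bundle (typically after QC).
#' @return a `"norm_screen"` list: `values` (wells x probes reals),
#'   `wells`, `panel`, `housekeeping_sum` (per retained well), `provenance`
#'   (source plate ids) and `removed_wells` (reason `zero_housekeeping`,
#'   empty when none).
#' @export
normalize_housekeeping <- function(screen) {
  hk <- screen$panel$probe_id[screen$panel$is_housekeeping]
  hk <- intersect(hk, colnames(screen$counts))
  if (length(hk) == 0)
    stop("no housekeeping probes remain: normalization denominator undefined",
         call. = FALSE)
  hk_sum <- rowSums(screen$counts[, hk, drop = FALSE])
  bad <- hk_sum == 0
  removed <- data.frame(plate_id = screen$wells$plate_id[bad],
                        well_id = screen$wells$well_id[bad],
                        reason = if (any(bad)) "zero_housekeeping" else character(0),
                        stringsAsFactors = FALSE)
  values <- screen$counts[!bad, , drop = FALSE] / hk_sum[!bad]
  structure(list(values = values,
                 wells = screen$wells[!bad, , drop = FALSE],
                 panel = screen$panel,
                 housekeeping_sum = unname(hk_sum[!bad]),
                 provenance = unique(screen$wells$plate_id[!bad]),
                 removed_wells = removed),
            class = "norm_screen")
}

#' Combine per-plate normalized matrices
#'
#' Row-concatenates normalized matrices from several plates into one
#' analysis matrix. Requires an identical probe set on every plate (the QC
#' module's global probe drop guarantees this); no rescaling is applied
#' beyond the housekeeping normalization already done per well.
#'
#' @param norm_list list of `"norm_screen"` objects.
#' @return a single `"norm_screen"` with provenance recording the source
#'   plates in order.
#' @export
combine_plates <- function(norm_list) {
  stopifnot(length(norm_list) >= 1,
            all(vapply(norm_list, inherits, logical(1), "norm_screen")))
  ref <- colnames(norm_list[[1]]$values)
  for (i in seq_along(norm_list)) {
    got <- colnames(norm_list[[i]]$values)
    if (!identical(sort(got), sort(ref))) {
      stop("probe sets differ between plates:\n  only in first: ",
           paste(setdiff(ref, got), collapse = ", "),
           "\n  only in element ", i, ": ",
           paste(setdiff(got, ref), collapse = ", "), call. = FALSE)
    }
  }
  values <- do.call(rbind, lapply(norm_list,
                                  function(x) x$values[, ref, drop = FALSE]))
  wells <- do.call(rbind, lapply(norm_list, `[[`, "wells"))
  rownames(wells) <- NULL
  structure(list(values = values,
                 wells = wells,
                 panel = norm_list[[1]]$panel,
                 housekeeping_sum = unlist(lapply(norm_list, `[[`,
                                                  "housekeeping_sum"),
                                           use.names = FALSE),
                 provenance = unlist(lapply(norm_list, `[[`, "provenance"),
                                     use.names = FALSE),
                 removed_wells = do.call(rbind, lapply(norm_list, `[[`,
                                                       "removed_wells"))),
            class = "norm_screen")
}

#' Split a normalized bundle by plate
#'
#' Convenience inverse of [combine_plates()]: one `"norm_screen"` per plate.
#' @param norm a `"norm_screen"`.
#' @return named list of per-plate `"norm_screen"` objects.
#' @export
split_plates <- function(norm) {
  stopifnot(inherits(norm, "norm_screen"))
  plates <- unique(norm$wells$plate_id)
  out <- lapply(plates, function(p) {
    sel <- norm$wells$plate_id == p
    structure(list(values = norm$values[sel, , drop = FALSE],
                   wells = norm$wells[sel, , drop = FALSE],
                   panel = norm$panel,
                   housekeeping_sum = norm$housekeeping_sum[sel],
                   provenance = p,
                   removed_wells = norm$removed_wells[
                     norm$removed_wells$plate_id == p, , drop = FALSE]),
              class = "norm_screen")
  })
  names(out) <- plates
  out
}

#' @export
print.norm_screen <- function(x, ...) {
  cat(sprintf("norm_screen: %d wells x %d probes (plates: %s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$provenance, collapse = ", ")))
  invisible(x)
}
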