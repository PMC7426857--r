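#' Normalize per-well phenotype measurements to the KO mean
#'
#' Orthogonal per-well phenotype readouts (e.g. a fluorescent cysteine-
#' cathepsin activity probe) measured on different experiment days carry
#' batch-level multiplicative gain. Batches are made poolable by dividing
#' every raw value by the mean raw value of the untreated KO wells of the
#' same batch, so the KO reference mean is exactly 1 within every batch.
#' Vehicle-treated wells count as untreated when flagged so in `treatment`.
#'
#' Downstream group comparisons (Welch t, ANOVA with Dunnett contrasts,
#' Kruskal-Wallis) are left to the standard routines; this function only
#' prepares the pooled table.
#'
#' @param records data.frame with columns `batch_id`, `genotype`
#'   (`WT`/`KO`), `treatment` (`untreated` or `vehicle` marking reference
#'   wells; anything else is a treated well) and `raw_value`; any further
#'   columns (plate, well, compound, concentration) pass through.
#' @return `records` with a `normalized_value` column appended.
#' @export
normalize_activity <- function(records) {
  need <- c("batch_id", "genotype", "treatment", "raw_value")
  missing_c <- setdiff(need, names(records))
  if (length(missing_c))
    stop("activity records missing column(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  is_ref <- records$genotype == "KO" &
    records$treatment %in% c("untreated", "vehicle")
  batches <- unique(records$batch_id)
  ref_mean <- vapply(batches, function(b) {
    sel <- is_ref & records$batch_id == b
    if (!any(sel))
      stop("batch '", b, "' has no untreated KO reference wells",
           call. = FALSE)
    mean(records$raw_value[sel])
  }, numeric(1))
  names(ref_mean) <- batches
  records$normalized_value <- records$raw_value /
    ref_mean[as.character(records$batch_id)]
  records
}
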