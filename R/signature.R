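#' Derive the KO-vs-WT differential signature
#'
#' Compares untreated KO and WT control wells on the housekeeping-normalized
#' values, gene by gene. Fold change is the ratio of KO mean to WT mean of
#' normalized values; the p-value comes from Welch's two-sample t-test on
#' log2(normalized + eps), with eps equal to half the smallest positive
#' normalized value in the matrix (a scale-free guard against log of zero).
#' A gene is selected when `fc > fc_thresh` or `fc < 1/fc_thresh` and
#' `p_value < p_thresh` — at the default 1.5 this is the FC > 1.5 or
#' < 0.667, p < 0.05 rule. No multiple-testing correction is applied; the
#' thresholds are on raw p-values by design.
#'
#' The target-gene probe (the knocked-out gene, `category == "target"`) is
#' tested and reported like any other gene but force-excluded from the
#' signature set: its expression difference reflects the knockout itself,
#' not the downstream signature, and compounds cannot restore it at the
#' probe level. A gene whose WT mean is zero has an undefined ratio; it is
#' reported with `fc = Inf` and excluded from selection.
#'
#' @param norm a `"norm_screen"`.
#' @param fc_thresh fold-change threshold (default 1.5).
#' @param p_thresh p-value threshold (default 0.05).
#' @param exclude_wells optional data.frame with `plate_id`, `well_id` of
#'   control wells to leave out (e.g. flagged outliers).
#' @return a `"signature_set"` list: `table` (per-gene gene_symbol, fc,
#'   log2fc, p_value, direction, selected), `genes` (ordered selected gene
#'   symbols, target excluded), `excluded_target`, `n_dimensions`,
#'   `thresholds`, `eps`, and the control well counts used.
#' @export
differential_signature <- function(norm, fc_thresh = 1.5, p_thresh = 0.05,
                                   exclude_wells = NULL) {
  stopifnot(inherits(norm, "norm_screen"), fc_thresh > 1, p_thresh > 0)
  wells <- norm$wells
  keep <- rep(TRUE, nrow(wells))
  if (!is.null(exclude_wells) && nrow(exclude_wells)) {
    drop_key <- paste(exclude_wells$plate_id, exclude_wells$well_id, sep = ":")
    keep <- !(paste(wells$plate_id, wells$well_id, sep = ":") %in% drop_key)
  }
  is_wt <- keep & wells$genotype == "WT" & wells$treatment == "untreated"
  is_ko <- keep & wells$genotype == "KO" & wells$treatment == "untreated"
  if (sum(is_wt) < 2 || sum(is_ko) < 2)
    stop("need >= 2 WT and >= 2 KO untreated control wells (have ",
         sum(is_wt), " WT, ", sum(is_ko), " KO)", call. = FALSE)

  v <- norm$values
  pos <- v[v > 0]
  eps <- if (length(pos)) min(pos) / 2 else .Machine$double.eps
  lw <- log2(v[is_wt, , drop = FALSE] + eps)
  lk <- log2(v[is_ko, , drop = FALSE] + eps)

  mean_wt <- colMeans(v[is_wt, , drop = FALSE])
  mean_ko <- colMeans(v[is_ko, , drop = FALSE])
  fc <- ifelse(mean_wt > 0, mean_ko / mean_wt, Inf)

  pvals <- vapply(seq_len(ncol(v)), function(j) {
    x <- lk[, j]; y <- lw[, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    stats::t.test(x, y)$p.value
  }, numeric(1))

  tab <- data.frame(
    gene_symbol = colnames(v),
    fc = fc,
    log2fc = log2(fc),
    p_value = pvals,
    direction = ifelse(fc >= 1, "up_in_KO", "down_in_KO"),
    stringsAsFactors = FALSE
  )
  tab$selected <- is.finite(tab$fc) &
    (tab$fc > fc_thresh | tab$fc < 1 / fc_thresh) &
    tab$p_value < p_thresh

  target <- norm$panel$probe_id[norm$panel$category == "target"]
  target <- intersect(target, tab$gene_symbol)
  genes <- tab$gene_symbol[tab$selected & !(tab$gene_symbol %in% target)]

  structure(list(table = tab,
                 genes = genes,
                 excluded_target = if (length(target)) target else NA_character_,
                 n_dimensions = length(genes),
                 thresholds = list(fc_thresh = fc_thresh, p_thresh = p_thresh),
                 eps = eps,
                 n_wt = sum(is_wt), n_ko = sum(is_ko)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d gene(s) at FC > %.3g or < %.3g, p < %.3g\n",
              x$n_dimensions, x$thresholds$fc_thresh,
              1 / x$thresholds$fc_thresh, x$thresholds$p_thresh))
  if (x$n_dimensions) cat("  ", paste(x$genes, collapse = ", "), "\n")
  if (!is.na(x$excluded_target))
    cat("  target probe excluded:", x$excluded_target, "\n")
  invisible(x)
}

#' @keywords internal
# per-gene z-scoring with the sample (n-1) standard deviation -- the fixed
# convention for every standardization in this package
.zscore_cols <- function(m) {
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sweep(sweep(m, 2, mu, "-"), 2, ifelse(sd > 0, sd, 1), "/")
}

#' Detect control-well outliers by unbiased clustering
#'
#' Clusters the untreated control wells on the per-gene z-scored signature
#' values with Ward-linkage hierarchical clustering (`ward.D2`, which
#' minimizes within-cluster variance on Euclidean distances) cut at k = 2.
#' A control well whose genotype is the minority of its assigned cluster is
#' flagged as an outlier. Detection is single-pass: flagged wells should be
#' excluded and the signature recomputed once (see [derive_signature()]),
#' not iterated.
#'
#' @param norm a `"norm_screen"`.
#' @param signature a `"signature_set"` (its `genes` define the space).
#' @return an `"outlier_report"` list: `flagged` (plate_id, well_id,
#'   genotype, assigned_cluster), `clusters` (per control well), and
#'   `linkage = "ward.D2"`.
#' @export
detect_outlier_controls <- function(norm, signature) {
  stopifnot(inherits(norm, "norm_screen"), inherits(signature, "signature_set"))
  if (signature$n_dimensions < 1)
    stop("signature set is empty; outlier clustering has no feature space",
         call. = FALSE)
  ctrl <- norm$wells$treatment == "untreated"
  wells <- norm$wells[ctrl, , drop = FALSE]
  if (sum(wells$genotype == "WT") < 3 || sum(wells$genotype == "KO") < 3)
    stop("need >= 3 controls per genotype for outlier clustering", call. = FALSE)
  m <- norm$values[ctrl, signature$genes, drop = FALSE]
  z <- .zscore_cols(m)
  d <- stats::dist(z, method = "euclidean")
  if (all(d == 0)) {
    warning("all control wells identical; clustering degenerate, no outliers",
            call. = FALSE)
    cl <- rep(1L, nrow(wells))
  } else {
    cl <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = 2)
  }
  flagged <- logical(nrow(wells))
  for (k in unique(cl)) {
    in_k <- cl == k
    tabg <- table(wells$genotype[in_k])
    if (length(tabg) > 1 && min(tabg) < max(tabg)) {
      minority <- names(tabg)[which.min(tabg)]
      flagged[in_k & wells$genotype == minority] <- TRUE
    }
  }
  structure(list(
    flagged = data.frame(plate_id = wells$plate_id[flagged],
                         well_id = wells$well_id[flagged],
                         genotype = wells$genotype[flagged],
                         assigned_cluster = unname(cl[flagged]),
                         stringsAsFactors = FALSE),
    clusters = data.frame(plate_id = wells$plate_id,
                          well_id = wells$well_id,
                          genotype = wells$genotype,
                          cluster = unname(cl),
                          stringsAsFactors = FALSE),
    linkage = "ward.D2"),
    class = "outlier_report")
}

#' Signature derivation with one-shot outlier removal
#'
#' The full control-well workflow: derive the signature, cluster the
#' controls to flag outlier wells, and — if any were flagged — recompute
#' the signature once with those wells excluded. No iteration beyond that
#' single pass.
#'
#' @inheritParams differential_signature
#' @return list with `signature` (final `"signature_set"`), `outliers`
#'   (the `"outlier_report"`, or NULL when controls were too few to
#'   cluster) and `initial_signature`.
#' @export
derive_signature <- function(norm, fc_thresh = 1.5, p_thresh = 0.05) {
  sig0 <- differential_signature(norm, fc_thresh, p_thresh)
  out <- NULL
  sig <- sig0
  if (sig0$n_dimensions >= 1) {
    ctrl <- norm$wells[norm$wells$treatment == "untreated", ]
    if (sum(ctrl$genotype == "WT") >= 3 && sum(ctrl$genotype == "KO") >= 3) {
      out <- detect_outlier_controls(norm, sig0)
      if (nrow(out$flagged) > 0)
        sig <- differential_signature(norm, fc_thresh, p_thresh,
                                      exclude_wells = out$flagged)
    }
  }
  list(signature = sig, outliers = out, initial_signature = sig0)
}

#' Deterministic Ward dendrogram leaf order
#'
#' Computes the leaf ordering of a Ward-linkage (`ward.D2`) / Euclidean
#' hierarchical clustering of the rows (`margin = 1`) or columns
#' (`margin = 2`) of a matrix, for heatmap export. The ordering is fully
#' deterministic: `hclust` breaks ties by input index.
#'
#' @param m numeric matrix.
#' @param margin 1 to order rows, 2 to order columns.
#' @return integer vector of indices (a permutation).
#' @export
ward_order <- function(m, margin = 1) {
  stopifnot(is.matrix(m), margin %in% c(1, 2))
  if (margin == 2) m <- t(m)
  if (nrow(m) < 2) return(seq_len(nrow(m)))
  stats::hclust(stats::dist(m, method = "euclidean"),
                method = "ward.D2")$order
}
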