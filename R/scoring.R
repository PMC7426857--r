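#' Standardize signature genes
#'
#' Centers and scales each signature gene of the normalized matrix to mean
#' 0 and sample (n-1) standard deviation 1, fitting the constants over a
#' stated well set and applying them to all wells. The standardized values
#' are the per-gene coordinates used by the distance score, so
#' standardization gives every signature gene equal weight regardless of
#' its absolute expression level.
#'
#' By default the constants are fitted over all retained wells (controls
#' and treated together); `fit = "controls"` restricts the fit to untreated
#' wells as a sensitivity analysis.
#'
#' @param norm a `"norm_screen"`.
#' @param signature a `"signature_set"`; its genes are the dimensions.
#' @param fit `"all"` (default) or `"controls"`.
#' @param exclude_wells optional data.frame with `plate_id`, `well_id`
#'   (e.g. flagged outlier controls) to drop from both fit and output.
#' @return a `"std_matrix"` list: `values` (wells x signature genes),
#'   `wells`, `constants` (per-gene mean `m` and sd `s`), `fit_wells`
#'   (which wells the constants were fitted on).
#' @export
standardize <- function(norm, signature, fit = c("all", "controls"),
                        exclude_wells = NULL) {
  stopifnot(inherits(norm, "norm_screen"), inherits(signature, "signature_set"))
  fit <- match.arg(fit)
  if (signature$n_dimensions < 1)
    stop("signature set is empty; nothing to standardize", call. = FALSE)
  missing_g <- setdiff(signature$genes, colnames(norm$values))
  if (length(missing_g))
    stop("signature gene(s) absent from normalized matrix: ",
         paste(missing_g, collapse = ", "), call. = FALSE)

  wells <- norm$wells
  keep <- rep(TRUE, nrow(wells))
  if (!is.null(exclude_wells) && nrow(exclude_wells)) {
    drop_key <- paste(exclude_wells$plate_id, exclude_wells$well_id, sep = ":")
    keep <- !(paste(wells$plate_id, wells$well_id, sep = ":") %in% drop_key)
  }
  v <- norm$values[keep, signature$genes, drop = FALSE]
  wells <- wells[keep, , drop = FALSE]

  fit_sel <- if (fit == "controls") wells$treatment == "untreated" else
    rep(TRUE, nrow(wells))
  if (sum(fit_sel) < 2)
    stop("need >= 2 wells to fit standardization constants", call. = FALSE)
  m <- colMeans(v[fit_sel, , drop = FALSE])
  s <- apply(v[fit_sel, , drop = FALSE], 2, stats::sd)
  if (any(s <= 0))
    stop("zero variance over the fit wells for signature gene(s): ",
         paste(names(s)[s <= 0], collapse = ", "), call. = FALSE)

  z <- sweep(sweep(v, 2, m, "-"), 2, s, "/")
  structure(list(values = z, wells = wells,
                 constants = data.frame(gene_symbol = signature$genes,
                                        m = unname(m), s = unname(s),
                                        stringsAsFactors = FALSE),
                 fit_wells = data.frame(plate_id = wells$plate_id[fit_sel],
                                        well_id = wells$well_id[fit_sel],
                                        stringsAsFactors = FALSE)),
            class = "std_matrix")
}

#' Per-group centroid of standardized values
#'
#' @param std a `"std_matrix"`.
#' @param genotype `"WT"` or `"KO"`.
#' @return a `"centroid"` list: per-gene means `p`, `group`, `n_wells`.
#' @export
group_centroid <- function(std, genotype = c("WT", "KO")) {
  stopifnot(inherits(std, "std_matrix"))
  genotype <- match.arg(genotype)
  sel <- std$wells$genotype == genotype & std$wells$treatment == "untreated"
  if (sum(sel) < 2)
    stop("fewer than 2 untreated ", genotype,
         " control wells for the centroid", call. = FALSE)
  structure(list(p = colMeans(std$values[sel, , drop = FALSE]),
                 group = genotype, n_wells = sum(sel)),
            class = "centroid")
}

#' Euclidean distance of wells to a centroid
#'
#' The score of the screen: for a well with standardized signature-gene
#' coordinates q_i and a centroid with coordinates p_i,
#' `d = sqrt(sum_i (q_i - p_i)^2)` over the signature genes. Wells with a
#' missing value in any signature dimension cannot be scored; they are
#' dropped with a warning naming them.
#'
#' @param std a `"std_matrix"`.
#' @param centroid a `"centroid"` (typically the WT controls).
#' @return named numeric vector of distances, one per scoreable well
#'   (names are `plate:well` keys).
#' @export
euclidean_score <- function(std, centroid) {
  stopifnot(inherits(std, "std_matrix"), inherits(centroid, "centroid"))
  if (!identical(colnames(std$values), names(centroid$p)))
    stop("centroid dimensions do not match the standardized matrix",
         call. = FALSE)
  keys <- paste(std$wells$plate_id, std$wells$well_id, sep = ":")
  ok <- stats::complete.cases(std$values)
  if (any(!ok))
    warning("well(s) with missing signature values excluded from scoring: ",
            paste(keys[!ok], collapse = ", "), call. = FALSE)
  q <- std$values[ok, , drop = FALSE]
  d <- sqrt(rowSums(sweep(q, 2, centroid$p, "-")^2))
  names(d) <- keys[ok]
  d
}

#' Score compound wells and call transcriptional-mimetic hits
#'
#' Computes every compound-treated well's Euclidean distance `d` to the WT
#' centroid, the reference distance `d_ref` between the KO and WT control
#' centroids, and the relative score `d - d_ref` (the "KO at 0" axis:
#' untreated KO sits at 0 and negative values lie closer to WT than KO
#' does). A well is a hit iff `d < d_ref`, strictly. Wells are ranked by
#' ascending `d` with ties broken lexicographically by compound id.
#'
#' @param std a `"std_matrix"` whose wells include untreated controls of
#'   both genotypes (for the centroids) and compound-treated wells.
#' @return a `"score_table"` data.frame with columns plate_id, well_id,
#'   compound_id, distance, d_ref, relative_score, rank, is_hit; attributes
#'   `wt_centroid` and `ko_centroid` carry the centroids. Per-well KO
#'   control distances are attached as attribute `ko_well_distances` for
#'   diagnostics.
#' @export
call_hits <- function(std) {
  stopifnot(inherits(std, "std_matrix"))
  wt <- group_centroid(std, "WT")
  ko <- group_centroid(std, "KO")
  d_ref <- sqrt(sum((ko$p - wt$p)^2))
  d_all <- euclidean_score(std, wt)

  keys <- paste(std$wells$plate_id, std$wells$well_id, sep = ":")
  treated <- std$wells$treatment == "compound"
  tkeys <- keys[treated]
  scored <- tkeys[tkeys %in% names(d_all)]
  widx <- match(scored, keys)
  d <- unname(d_all[scored])

  tab <- data.frame(plate_id = std$wells$plate_id[widx],
                    well_id = std$wells$well_id[widx],
                    compound_id = std$wells$compound_id[widx],
                    distance = d,
                    d_ref = d_ref,
                    relative_score = d - d_ref,
                    stringsAsFactors = FALSE)
  ord <- order(tab$distance, tab$compound_id, method = "radix")
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  tab$is_hit <- tab$distance < d_ref
  rownames(tab) <- NULL
  class(tab) <- c("score_table", "data.frame")
  attr(tab, "wt_centroid") <- wt
  attr(tab, "ko_centroid") <- ko
  ko_ctrl <- std$wells$genotype == "KO" & std$wells$treatment == "untreated"
  attr(tab, "ko_well_distances") <- d_all[keys[ko_ctrl][keys[ko_ctrl] %in%
                                                          names(d_all)]]
  tab
}

#' Top-ranked compounds
#'
#' @param score_table a `"score_table"` from [call_hits()].
#' @param top_n how many compounds to return (ascending distance).
#' @return the first `top_n` rows; if `top_n` exceeds the table size, the
#'   whole table is returned with a warning.
#' @export
rank_compounds <- function(score_table, top_n) {
  stopifnot(is.data.frame(score_table), "rank" %in% names(score_table))
  if (top_n > nrow(score_table)) {
    warning("top_n = ", top_n, " exceeds the ", nrow(score_table),
            " scored wells; returning all", call. = FALSE)
    top_n <- nrow(score_table)
  }
  score_table[seq_len(top_n), , drop = FALSE]
}
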