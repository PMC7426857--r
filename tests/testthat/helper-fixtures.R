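# Hand-built fixtures, independent of the simulator, for exact-value tests.

# a minimal probe panel: nhk housekeeping probes, one target, the rest "other"
tiny_panel <- function(genes, hk, target = NULL) {
  data.frame(
    probe_id = genes,
    gene_symbol = genes,
    category = ifelse(genes %in% hk, "housekeeping",
                      ifelse(genes %in% (target %||% ""), "target", "other")),
    is_housekeeping = genes %in% hk,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_wells <- function(n, plate = "P1", genotype = "KO",
                       treatment = "compound", cell_count = 1) {
  ids <- as.vector(t(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0)))
  data.frame(plate_id = plate,
             well_id = ids[seq_len(n)],
             genotype = rep_len(genotype, n),
             treatment = rep_len(treatment, n),
             compound_id = ifelse(rep_len(treatment, n) == "compound",
                                  sprintf("C%03d", seq_len(n)), ""),
             cell_count = rep_len(cell_count, n),
             stringsAsFactors = FALSE)
}

tiny_screen <- function(counts, wells, panel, truth = NULL) {
  rownames(counts) <- paste(wells$plate_id, wells$well_id, sep = ":")
  structure(list(counts = counts, wells = wells, panel = panel,
                 truth = truth),
            class = "rasl_screen")
}

# a norm_screen built directly from a values matrix (bypasses normalization)
fake_norm <- function(values, wells, panel = NULL) {
  if (is.null(panel))
    panel <- tiny_panel(colnames(values), hk = character(0))
  rownames(values) <- paste(wells$plate_id, wells$well_id, sep = ":")
  structure(list(values = values, wells = wells, panel = panel,
                 housekeeping_sum = rep(1, nrow(values)),
                 provenance = unique(wells$plate_id),
                 removed_wells = data.frame(plate_id = character(0),
                                            well_id = character(0),
                                            reason = character(0))),
            class = "norm_screen")
}

fake_signature <- function(genes) {
  structure(list(table = NULL, genes = genes,
                 excluded_target = NA_character_,
                 n_dimensions = length(genes),
                 thresholds = list(fc_thresh = 1.5, p_thresh = 0.05),
                 eps = 1e-6, n_wt = NA, n_ko = NA),
            class = "signature_set")
}

fake_std <- function(values, wells) {
  structure(list(values = values, wells = wells,
                 constants = data.frame(gene_symbol = colnames(values),
                                        m = 0, s = 1),
                 fit_wells = wells[, c("plate_id", "well_id")]),
            class = "std_matrix")
}

# control-well layout: n_wt WT + n_ko KO untreated wells on one plate
control_wells <- function(n_wt, n_ko, plate = "P1") {
  w <- tiny_wells(n_wt + n_ko, plate = plate, treatment = "untreated")
  w$genotype <- c(rep("WT", n_wt), rep("KO", n_ko))
  w$compound_id <- ""
  w
}

# Welch two-sample t-test p-value by direct formula (independent oracle)
welch_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Mann-Whitney AUC: probability that a positive ranks closer (smaller d)
rank_auc <- function(d, positive) {
  r <- rank(d)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[!positive]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
}
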