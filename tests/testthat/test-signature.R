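# norm_screen with WT/KO controls whose values come from a programmed
# log-normal model: genes in `shifted` differ by `l2fc` (KO - WT)
control_norm <- function(n_wt = 16, n_ko = 16, genes = paste0("G", 1:8),
                         shifted = character(0), l2fc = 1, sd = 0.1,
                         seed = 1) {
  set.seed(seed)
  wells <- control_wells(n_wt, n_ko)
  base <- matrix(stats::rnorm(nrow(wells) * length(genes), 0, sd),
                 nrow(wells), length(genes), dimnames = list(NULL, genes))
  base[wells$genotype == "KO", genes %in% shifted] <-
    base[wells$genotype == "KO", genes %in% shifted] + l2fc
  fake_norm(2 ^ base, wells)
}

test_that("identical control groups select no genes", {
  wells <- control_wells(4, 4)
  v <- matrix(rep(c(1, 2, 3, 4), each = 8), 8, 4,
              dimnames = list(NULL, paste0("G", 1:4)))
  sig <- differential_signature(fake_norm(v, wells))
  expect_equal(sig$n_dimensions, 0)
  expect_true(all(sig$table$fc == 1))
})

test_that("fold changes and Welch p-values match a direct-formula oracle", {
  norm <- control_norm(shifted = c("G2", "G5"), seed = 3)
  sig <- differential_signature(norm)
  wt <- norm$wells$genotype == "WT"
  ko <- norm$wells$genotype == "KO"
  for (g in colnames(norm$values)) {
    expect_equal(sig$table$fc[sig$table$gene_symbol == g],
                 mean(norm$values[ko, g]) / mean(norm$values[wt, g]),
                 tolerance = 1e-12)
    lv <- log2(norm$values[, g] + sig$eps)
    expect_equal(sig$table$p_value[sig$table$gene_symbol == g],
                 welch_p(lv[ko], lv[wt]), tolerance = 1e-10)
  }
  expect_setequal(sig$genes, c("G2", "G5"))
  expect_equal(sig$table$direction[sig$table$gene_symbol == "G2"], "up_in_KO")
})

test_that("fold change inverts when the genotype labels swap", {
  norm <- control_norm(shifted = "G1", seed = 5)
  sig1 <- differential_signature(norm)
  swapped <- norm
  swapped$wells$genotype <- ifelse(norm$wells$genotype == "WT", "KO", "WT")
  sig2 <- differential_signature(swapped)
  expect_equal(sig1$table$fc, 1 / sig2$table$fc, tolerance = 1e-12)
})

test_that("selection is monotone in both thresholds", {
  norm <- control_norm(shifted = c("G1", "G4", "G7"), l2fc = 0.8, sd = 0.25,
                       seed = 7)
  strict <- differential_signature(norm, fc_thresh = 1.6, p_thresh = 0.01)
  relaxed <- differential_signature(norm, fc_thresh = 1.3, p_thresh = 0.10)
  expect_true(all(strict$genes %in% relaxed$genes))
})

test_that("the target probe is reported but never enters the signature", {
  norm <- control_norm(shifted = c("G3", "G6"), seed = 9)
  norm$panel$category[norm$panel$probe_id == "G3"] <- "target"
  sig <- differential_signature(norm)
  expect_true("G3" %in% sig$table$gene_symbol[sig$table$selected])
  expect_false("G3" %in% sig$genes)
  expect_equal(sig$excluded_target, "G3")
})

test_that("a zero WT mean yields an infinite-fc sentinel, not a selection", {
  wells <- control_wells(4, 4)
  v <- matrix(1, 8, 2, dimnames = list(NULL, c("G1", "G2")))
  v[wells$genotype == "WT", "G1"] <- 0
  v[wells$genotype == "KO", "G1"] <- 2
  sig <- differential_signature(fake_norm(v, wells))
  expect_equal(sig$table$fc[sig$table$gene_symbol == "G1"], Inf)
  expect_false("G1" %in% sig$genes)
})

test_that("too few control wells is a hard error", {
  norm <- control_norm(n_wt = 1, n_ko = 4)
  expect_error(differential_signature(norm), ">= 2 WT")
})

test_that("well-separated genotype groups produce no outlier flags", {
  norm <- control_norm(shifted = c("G1", "G2", "G3"), l2fc = 3, sd = 0.1,
                       seed = 11)
  sig <- fake_signature(c("G1", "G2", "G3"))
  out <- detect_outlier_controls(norm, sig)
  expect_equal(nrow(out$flagged), 0)
  expect_equal(out$linkage, "ward.D2")
})

test_that("a planted KO-profile well among WT controls is flagged", {
  norm <- control_norm(n_wt = 8, n_ko = 8, shifted = c("G1", "G2", "G3"),
                       l2fc = 3, sd = 0.1, seed = 13)
  # well 2 is labeled WT but carries the KO expression profile
  ko_rows <- which(norm$wells$genotype == "KO")
  norm$values[2, ] <- norm$values[ko_rows[1], ] * 1.01
  sig <- fake_signature(c("G1", "G2", "G3"))
  out <- detect_outlier_controls(norm, sig)
  expect_equal(out$flagged$well_id, norm$wells$well_id[2])
  expect_equal(out$flagged$genotype, "WT")
})

test_that("outlier flagging is invariant to well input order", {
  norm <- control_norm(n_wt = 8, n_ko = 8, shifted = c("G1", "G2"),
                       l2fc = 3, sd = 0.1, seed = 17)
  ko_rows <- which(norm$wells$genotype == "KO")
  norm$values[1, ] <- norm$values[ko_rows[2], ] * 0.99
  sig <- fake_signature(c("G1", "G2"))
  out1 <- detect_outlier_controls(norm, sig)
  perm <- sample(nrow(norm$values))
  shuffled <- norm
  shuffled$values <- norm$values[perm, , drop = FALSE]
  shuffled$wells <- norm$wells[perm, , drop = FALSE]
  out2 <- detect_outlier_controls(shuffled, sig)
  key <- function(d) sort(paste(d$plate_id, d$well_id))
  expect_equal(key(out2$flagged), key(out1$flagged))
})

test_that("derive_signature removes flagged outliers and recomputes once", {
  norm <- control_norm(n_wt = 8, n_ko = 8,
                       shifted = c("G1", "G2", "G3", "G4"),
                       l2fc = 1.2, sd = 0.15, seed = 19)
  ko_rows <- which(norm$wells$genotype == "KO")
  norm$values[3, ] <- norm$values[ko_rows[3], ]
  res <- derive_signature(norm)
  expect_equal(res$outliers$flagged$well_id, norm$wells$well_id[3])
  # recomputed signature excludes the planted well from the WT group
  manual <- differential_signature(norm, exclude_wells = res$outliers$flagged)
  expect_equal(res$signature$table, manual$table)
})

test_that("ward leaf ordering is deterministic and groups duplicates", {
  set.seed(23)
  m <- matrix(rnorm(40), 10, 4)
  m[7, ] <- m[2, ]                      # exact duplicate rows
  o1 <- ward_order(m)
  o2 <- ward_order(m)
  expect_identical(o1, o2)
  expect_true(sort(o1) |> identical(1:10))
  expect_equal(abs(diff(match(c(2, 7), o1))), 1)  # duplicates adjacent
  expect_identical(ward_order(m[1:2, ]), c(1L, 2L))
  # column ordering works on the transpose
  expect_setequal(ward_order(m, margin = 2), 1:4)
})

test_that("programmed signature genes are recovered from simulated screens", {
  # single-seed version of the multi-seed recovery experiment
  scr <- simulate_screen(sim_config(n_plates = 1, wells_per_plate = 96,
                                    n_compounds = 8,
                                    n_wt_controls_per_plate = 16,
                                    n_ko_controls_per_plate = 16,
                                    signature_log2fc = 1, nb_dispersion = 0.05,
                                    frac_toxic = 0, frac_lowread = 0,
                                    seed = 29))
  norm <- normalize_housekeeping(scr)
  sig <- differential_signature(norm)
  truth <- scr$truth$genes
  expect_setequal(sig$genes, truth$probe_id[truth$is_signature_true])
})
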