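# a norm_screen with controls + treated wells for scoring tests
scoring_norm <- function(n_wt = 6, n_ko = 6, n_treated = 20,
                         genes = paste0("G", 1:5), l2fc = 2, sd = 0.1,
                         seed = 1) {
  set.seed(seed)
  ctrl <- control_wells(n_wt, n_ko)
  trt <- tiny_wells(n_treated, treatment = "compound")
  trt$well_id <- sprintf("T%02d", seq_len(n_treated))
  wells <- rbind(ctrl, trt)
  base <- matrix(stats::rnorm(nrow(wells) * length(genes), 0, sd),
                 nrow(wells), length(genes), dimnames = list(NULL, genes))
  ko_like <- wells$genotype == "KO"
  base[ko_like, ] <- base[ko_like, ] + l2fc
  fake_norm(2 ^ base, wells)
}

test_that("standardization uses the sample (n-1) convention", {
  wells <- tiny_wells(2, treatment = "untreated", genotype = "WT")
  wells$compound_id <- ""
  v <- matrix(c(1, 3), 2, 1, dimnames = list(NULL, "G1"))
  std <- standardize(fake_norm(v, wells), fake_signature("G1"))
  expect_equal(unname(std$values[, 1]), c(-0.7071068, 0.7071068),
               tolerance = 1e-6)
})

test_that("fitted columns have mean 0 and sample sd 1 to numerical precision", {
  norm <- scoring_norm(seed = 2)
  std <- standardize(norm, fake_signature(colnames(norm$values)))
  expect_true(all(abs(colMeans(std$values)) < 1e-12))
  expect_true(all(abs(apply(std$values, 2, sd) - 1) < 1e-12))
})

test_that("standardization absorbs per-gene positive rescaling", {
  norm <- scoring_norm(seed = 3)
  sig <- fake_signature(colnames(norm$values))
  std1 <- standardize(norm, sig)
  set.seed(99)
  for (i in 1:5) {
    scaled <- norm
    k <- runif(ncol(norm$values), 0.1, 10)
    scaled$values <- sweep(norm$values, 2, k, "*")
    std2 <- standardize(scaled, sig)
    expect_equal(std2$values, std1$values, tolerance = 1e-9)
  }
})

test_that("zero-variance signature genes abort standardization by name", {
  wells <- control_wells(3, 3)
  v <- matrix(c(rep(2, 6), rnorm(6)), 6, 2,
              dimnames = list(NULL, c("Flat", "G2")))
  expect_error(standardize(fake_norm(v, wells),
                           fake_signature(c("Flat", "G2"))),
               "Flat")
})

test_that("distances obey the defining geometry", {
  wells <- tiny_wells(2, treatment = "compound")
  v <- matrix(c(0, 3, 0, 4), 2, 2, dimnames = list(NULL, c("G1", "G2")))
  std <- fake_std(v, wells)
  centroid <- structure(list(p = c(G1 = 0, G2 = 0), group = "WT",
                             n_wells = 2), class = "centroid")
  d <- euclidean_score(std, centroid)
  expect_equal(unname(d), c(0, 5))   # coincident well and a 3-4-5 triangle
})

test_that("vectorized distances equal a scalar double-loop oracle", {
  set.seed(7)
  q <- matrix(rnorm(50 * 11), 50, 11,
              dimnames = list(NULL, paste0("G", 1:11)))
  wells <- tiny_wells(50, treatment = "compound")
  p <- rnorm(11); names(p) <- colnames(q)
  d <- euclidean_score(fake_std(q, wells),
                       structure(list(p = p, group = "WT", n_wells = 5),
                                 class = "centroid"))
  oracle <- numeric(50)
  for (w in 1:50) {
    acc <- 0
    for (i in 1:11) acc <- acc + (q[w, i] - p[i])^2
    oracle[w] <- sqrt(acc)
  }
  expect_equal(unname(d), oracle, tolerance = 1e-12)
})

test_that("adding a per-gene constant before standardization leaves distances unchanged", {
  norm <- scoring_norm(seed = 5)
  sig <- fake_signature(colnames(norm$values))
  d1 <- call_hits(standardize(norm, sig))$distance
  shifted <- norm
  shifted$values <- sweep(norm$values, 2, runif(ncol(norm$values), 1, 5), "+")
  d2 <- call_hits(standardize(shifted, sig))$distance
  expect_equal(d2, d1, tolerance = 1e-9)
})

test_that("hit calling uses the strict KO-reference rule", {
  norm <- scoring_norm(seed = 6)
  tab <- call_hits(standardize(norm, fake_signature(colnames(norm$values))))
  expect_true(all(tab$distance >= 0))
  expect_equal(tab$is_hit, tab$relative_score < 0)
  expect_equal(tab$is_hit, tab$distance < tab$d_ref)
  expect_equal(sort(tab$rank), seq_len(nrow(tab)))
  # monotone: every well ranked above a hit is itself a hit
  if (any(tab$is_hit)) expect_true(all(tab$is_hit[1:max(which(tab$is_hit))]))
  # a well exactly at d_ref is not a hit
  expect_false(any(tab$is_hit[abs(tab$distance - tab$d_ref) < 1e-15]))
})

test_that("ties in distance rank deterministically by compound id", {
  wells <- rbind(control_wells(2, 2), {
    t <- tiny_wells(3, treatment = "compound")
    t$compound_id <- c("CB", "CA", "CC"); t$well_id <- c("T1", "T2", "T3"); t
  })
  v <- matrix(0, 7, 2, dimnames = list(NULL, c("G1", "G2")))
  v[wells$genotype == "KO", ] <- 2
  v[6:7, ] <- 1; v[5, ] <- 1           # three treated wells, identical d
  tab1 <- call_hits(fake_std(v, wells))
  expect_equal(tab1$compound_id, c("CA", "CB", "CC"))
  expect_equal(tab1$rank, 1:3)
  tab2 <- call_hits(fake_std(v[c(1:4, 7, 6, 5), ], wells[c(1:4, 7, 6, 5), ]))
  expect_equal(tab2$compound_id, tab1$compound_id)
})

test_that("rank_compounds returns the top of the ranking and warns past the end", {
  norm <- scoring_norm(n_treated = 10, seed = 8)
  tab <- call_hits(standardize(norm, fake_signature(colnames(norm$values))))
  top1 <- rank_compounds(tab, 1)
  expect_equal(top1$distance, min(tab$distance))
  topk <- rank_compounds(tab, 4)
  expect_equal(rbind(topk, tab[5:nrow(tab), ]), tab)
  expect_warning(all_back <- rank_compounds(tab, 99), "exceeds")
  expect_equal(nrow(all_back), nrow(tab))
})

test_that("excluding the target probe from the signature changes distances", {
  # the pseudo-target must carry signal that WOULD move scores if included
  scr <- simulate_screen(sim_config(n_plates = 1, wells_per_plate = 96,
                                    n_compounds = 20,
                                    frac_toxic = 0, frac_lowread = 0,
                                    frac_rescuers = 0.5, seed = 31))
  norm <- normalize_housekeeping(scr)
  sig <- derive_signature(norm)$signature
  target <- scr$panel$probe_id[scr$panel$category == "target"]
  expect_false(target %in% sig$genes)
  tab <- call_hits(standardize(norm, sig))
  with_target <- fake_signature(c(sig$genes, target))
  tab2 <- call_hits(standardize(norm, with_target))
  expect_gt(max(abs(tab2$distance[match(tab$compound_id, tab2$compound_id)] -
                      tab$distance)), 0.1)
})

test_that("missing signature values exclude a well from scoring with a warning", {
  norm <- scoring_norm(seed = 9)
  sig <- fake_signature(colnames(norm$values))
  std <- standardize(norm, sig)
  std$values[which(std$wells$treatment == "compound")[1], 2] <- NA
  expect_warning(tab <- call_hits(std), "excluded")
  expect_equal(nrow(tab), sum(std$wells$treatment == "compound") - 1)
})
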