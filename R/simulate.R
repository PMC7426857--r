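#' Configuration for a synthetic targeted-transcriptomic screen
#'
#' Builds and validates the parameter set for [simulate_screen()]. Defaults
#' emulate a four-plate, 384-well compound screen profiled on a 42-probe
#' panel with 6 housekeeping probes: 1,120 compounds (one per treated well),
#' untreated wild-type (WT) and knockout (KO) control wells on every plate,
#' per-well library-size variation, a programmed KO-vs-WT signature, and a
#' configurable fraction of "rescuer" compounds that move KO expression back
#' toward WT.
#'
#' @param n_plates number of plates.
#' @param wells_per_plate wells available per plate (at most 384, the
#'   standard 16 x 24 grid).
#' @param n_compounds total number of distinct compounds, one per treated
#'   well, split across plates.
#' @param n_probes total probes on the panel (includes housekeeping and the
#'   target-gene probe).
#' @param n_housekeeping number of housekeeping probes.
#' @param n_signature_true number of genes programmed to differ between KO
#'   and WT (the ground-truth signature; excludes the target probe).
#' @param signature_log2fc absolute programmed KO-vs-WT shift of signature
#'   genes, in log2 units. Directions alternate up/down in KO.
#' @param library_size_mean expected total reads per well.
#' @param library_size_cv coefficient of variation of library size across
#'   wells (log-normal; 0 gives a fixed library size).
#' @param nb_dispersion negative-binomial overdispersion of counts
#'   (variance = mu + dispersion * mu^2); 0 degenerates to Poisson.
#' @param n_wt_controls_per_plate,n_ko_controls_per_plate untreated control
#'   wells of each genotype on every plate.
#' @param frac_rescuers fraction of compounds given a nonzero rescue
#'   fraction rho (drawn among compounds not flagged toxic or low-read).
#' @param rescue_fraction_range length-2 numeric, range of rho for rescuer
#'   compounds; rho = 1 moves KO signature-gene means fully onto WT means.
#' @param frac_toxic fraction of compounds whose wells get a cell count
#'   drawn below the 40 percent QC threshold.
#' @param frac_lowread fraction of compounds whose wells get a library size
#'   below the read-depth QC threshold (disjoint from the toxic set).
#' @param lowread_library_range library-size range for low-read wells. Keep
#'   its upper end well below the QC read threshold you intend to use:
#'   dropout wells fail deeply in practice, and the margin keeps the
#'   low-read flag unambiguous against counting noise.
#' @param cell_count_sd standard deviation of the per-well cell count
#'   (Normal around 1.0, truncated at 0; only the ratio to the untreated
#'   mean matters downstream).
#' @param low_abundance_probes number of filler probes forced to a
#'   near-zero expected proportion (to exercise the per-plate probe filter).
#' @param noise_model `"nb"` for negative-binomial counts (default),
#'   `"poisson"` to force Poisson, or `"none"` for an idealized noiseless
#'   screen in which the emitted matrix holds the real-valued expected
#'   counts themselves.
#' @param seed integer seed controlling every random draw.
#'
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_screen()]
#' @export
sim_config <- function(n_plates = 4L,
                       wells_per_plate = 384L,
                       n_compounds = 1120L,
                       n_probes = 42L,
                       n_housekeeping = 6L,
                       n_signature_true = 11L,
                       signature_log2fc = 1.0,
                       library_size_mean = 3e5,
                       library_size_cv = 0.25,
                       nb_dispersion = 0.05,
                       n_wt_controls_per_plate = 16L,
                       n_ko_controls_per_plate = 16L,
                       frac_rescuers = 0.05,
                       rescue_fraction_range = c(0.7, 1.0),
                       frac_toxic = 0.08,
                       frac_lowread = 0.03,
                       lowread_library_range = c(1.5e4, 7e4),
                       cell_count_sd = 0.15,
                       low_abundance_probes = 0L,
                       noise_model = c("nb", "poisson", "none"),
                       seed = 1L) {
  cfg <- list(
    n_plates = as.integer(n_plates),
    wells_per_plate = as.integer(wells_per_plate),
    n_compounds = as.integer(n_compounds),
    n_probes = as.integer(n_probes),
    n_housekeeping = as.integer(n_housekeeping),
    n_signature_true = as.integer(n_signature_true),
    signature_log2fc = signature_log2fc,
    library_size_mean = library_size_mean,
    library_size_cv = library_size_cv,
    nb_dispersion = nb_dispersion,
    n_wt_controls_per_plate = as.integer(n_wt_controls_per_plate),
    n_ko_controls_per_plate = as.integer(n_ko_controls_per_plate),
    frac_rescuers = frac_rescuers,
    rescue_fraction_range = as.numeric(rescue_fraction_range),
    frac_toxic = frac_toxic,
    frac_lowread = frac_lowread,
    lowread_library_range = as.numeric(lowread_library_range),
    cell_count_sd = cell_count_sd,
    low_abundance_probes = as.integer(low_abundance_probes),
    noise_model = match.arg(noise_model),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  pos_int <- function(field, lo = 1L) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < lo)
      fail(field, sprintf("must be a single integer >= %d", lo))
  }
  frac <- function(field) {
    v <- cfg[[field]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      fail(field, "must lie in [0, 1]")
  }
  pos_int("n_plates"); pos_int("wells_per_plate"); pos_int("n_compounds")
  pos_int("n_probes", 2L); pos_int("n_housekeeping")
  pos_int("n_signature_true"); pos_int("seed", -.Machine$integer.max)
  pos_int("n_wt_controls_per_plate"); pos_int("n_ko_controls_per_plate")
  if (cfg$wells_per_plate > 384L)
    fail("wells_per_plate", "exceeds the 16 x 24 = 384-well grid")
  if (cfg$n_housekeeping >= cfg$n_probes)
    fail("n_housekeeping", "must be < n_probes")
  # one probe is reserved for the knocked-out target gene
  if (cfg$n_signature_true > cfg$n_probes - cfg$n_housekeeping - 1L)
    fail("n_signature_true", "must be <= n_probes - n_housekeeping - 1")
  for (f in c("frac_rescuers", "frac_toxic", "frac_lowread")) frac(f)
  if (cfg$frac_toxic + cfg$frac_lowread > 1)
    fail("frac_lowread", "frac_toxic + frac_lowread must be <= 1")
  rr <- cfg$rescue_fraction_range
  if (length(rr) != 2L || any(is.na(rr)) || rr[1] > rr[2] ||
      rr[1] < 0 || rr[2] > 1)
    fail("rescue_fraction_range", "must be (lo, hi) with 0 <= lo <= hi <= 1")
  if (cfg$library_size_mean <= 0)
    fail("library_size_mean", "must be positive")
  if (cfg$library_size_cv < 0) fail("library_size_cv", "must be >= 0")
  if (cfg$nb_dispersion < 0) fail("nb_dispersion", "must be >= 0")
  if (cfg$cell_count_sd < 0) fail("cell_count_sd", "must be >= 0")
  if (cfg$low_abundance_probes < 0 ||
      cfg$low_abundance_probes >
        cfg$n_probes - cfg$n_housekeeping - 1L - cfg$n_signature_true)
    fail("low_abundance_probes",
         "must leave at least the signature, housekeeping and target probes")
  per_plate <- ceiling(cfg$n_compounds / cfg$n_plates)
  need <- per_plate + cfg$n_wt_controls_per_plate + cfg$n_ko_controls_per_plate
  if (need > cfg$wells_per_plate)
    fail("wells_per_plate",
         sprintf("must hold %d control + %d compound wells (have %d)",
                 cfg$n_wt_controls_per_plate + cfg$n_ko_controls_per_plate,
                 per_plate, cfg$wells_per_plate))
  invisible(cfg)
}

# default gene names for generated panels; signature names follow the
# lysosomal / inflammatory / homeostatic panel design of the assay
.hk_pool <- c("Gapdh", "Actb", "B2m", "Hprt", "Rpl13a", "Tbp",
              "Pgk1", "Ppia", "Sdha", "Ywhaz")
.sig_pool <- c("Ctsd", "Ccl2", "Ccl3", "Ccl4", "Il1a", "Il16", "Il10ra",
               "Ifngr1", "Aif1", "Csf1r", "Tgfbr1")
.sig_cat <- c("lysosomal", "inflammatory", "inflammatory", "inflammatory",
              "inflammatory", "inflammatory", "inflammatory", "inflammatory",
              "microglial_homeostatic", "microglial_homeostatic",
              "microglial_homeostatic")

#' @keywords internal
well_grid <- function(n) {
  stopifnot(n <= 384L)
  ids <- as.vector(t(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0)))
  ids[seq_len(n)]
}

#' Simulate a multi-plate compound screen with ground truth
#'
#' Generates a wells x probes count matrix with the structure the analysis
#' pipeline assumes: untreated WT and KO control wells on every plate, one
#' compound per treated well (genotype KO), housekeeping probes whose
#' expected proportions are genotype-invariant, a programmed set of
#' signature genes shifted between genotypes, and a target-gene probe whose
#' expected count is zero in every KO-derived well. A compound with rescue
#' fraction `rho` has its expected signature-gene abundances shifted from
#' the KO baseline toward WT multiplicatively in log2 space:
#' `log2 mu = log2 mu_KO + rho * (log2 mu_WT - log2 mu_KO)`, so `rho = 1`
#' reproduces the WT expectations exactly. Counts are drawn negative-
#' binomially around per-well expected abundance x library size.
#'
#' All randomness is governed by `config$seed`; draws occur in a fixed
#' order (baseline abundances, compound flags, rescue fractions, cell
#' counts, library sizes, counts), so identical configs give byte-identical
#' output.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `"rasl_screen"` with elements
#'   \describe{
#'     \item{counts}{wells x probes matrix; integer counts unless
#'       `noise_model = "none"`, in which case real-valued expected counts.}
#'     \item{wells}{per-well metadata data.frame (`plate_id`, `well_id`,
#'       `genotype`, `treatment`, `compound_id`, `cell_count`).}
#'     \item{panel}{probe panel data.frame (`probe_id`, `gene_symbol`,
#'       `category`, `is_housekeeping`).}
#'     \item{truth}{ground truth: `$compounds` (compound_id,
#'       rescue_fraction, is_toxic, is_lowread) and `$genes` (probe_id,
#'       programmed_log2fc as KO minus WT, is_signature_true). The target
#'       probe's programmed log2 fold change is `NA` because its KO
#'       expectation is exactly zero.}
#'     \item{config}{the config used.}
#'   }
#' @examples
#' scr <- simulate_screen(sim_config(n_plates = 1, n_compounds = 20,
#'                                   wells_per_plate = 96, seed = 7))
#' dim(scr$counts)
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "sim_config"))
    config <- do.call(sim_config, as.list(config))
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)

  ## ---- panel -------------------------------------------------------------
  n_hk <- cfg$n_housekeeping
  n_sig <- cfg$n_signature_true
  n_fill <- cfg$n_probes - n_hk - n_sig - 1L
  hk_names <- if (n_hk <= length(.hk_pool)) .hk_pool[seq_len(n_hk)] else
    c(.hk_pool, sprintf("Hk%02d", seq_len(n_hk - length(.hk_pool))))
  if (n_sig <= length(.sig_pool)) {
    sig_names <- .sig_pool[seq_len(n_sig)]
    sig_cats <- .sig_cat[seq_len(n_sig)]
  } else {
    extra <- n_sig - length(.sig_pool)
    sig_names <- c(.sig_pool, sprintf("Sig%02d", seq_len(extra)))
    sig_cats <- c(.sig_cat, rep("other", extra))
  }
  fill_names <- if (n_fill > 0) sprintf("Gene%02d", seq_len(n_fill)) else
    character(0)
  fill_cats <- if (n_fill > 0)
    rep_len(c("lysosomal", "inflammatory", "microglial_homeostatic", "other"),
            n_fill) else character(0)
  panel <- data.frame(
    probe_id = c(hk_names, "Grn", sig_names, fill_names),
    gene_symbol = c(hk_names, "Grn", sig_names, fill_names),
    category = c(rep("housekeeping", n_hk), "target", sig_cats, fill_cats),
    is_housekeeping = c(rep(TRUE, n_hk), rep(FALSE, 1L + n_sig + n_fill)),
    stringsAsFactors = FALSE
  )

  ## ---- baseline expected abundances (WT sums to 1) -----------------------
  # housekeeping probes take a fixed large share; the rest is spread
  # log-normally over target + signature + filler probes
  hk_share <- 0.30
  target_share <- 0.02
  other_n <- n_sig + n_fill
  raw <- 2 ^ stats::rnorm(other_n, 0, 1)
  other_ab <- raw / sum(raw) * (1 - hk_share - target_share)
  ab_wt <- c(rep(hk_share / n_hk, n_hk), target_share, other_ab)
  names(ab_wt) <- panel$probe_id
  if (cfg$low_abundance_probes > 0L) {
    low_idx <- (n_hk + 1L + n_sig) + seq_len(cfg$low_abundance_probes)
    ab_wt[low_idx] <- 1e-7
  }

  sig_idx <- n_hk + 1L + seq_len(n_sig)
  # alternate direction: odd signature genes up in KO, even down
  sig_sign <- rep_len(c(1, -1), n_sig)
  log2fc <- rep(0, cfg$n_probes)
  log2fc[sig_idx] <- sig_sign * cfg$signature_log2fc
  ab_ko <- ab_wt * 2 ^ log2fc
  ab_ko[n_hk + 1L] <- 0   # target gene: expected count exactly 0 in KO

  truth_genes <- data.frame(
    probe_id = panel$probe_id,
    programmed_log2fc = ifelse(panel$category == "target", NA_real_, log2fc),
    is_signature_true = seq_len(cfg$n_probes) %in% sig_idx,
    stringsAsFactors = FALSE
  )

  ## ---- compound flags and rescue fractions -------------------------------
  comp_ids <- sprintf("C%04d", seq_len(cfg$n_compounds))
  n_toxic <- round(cfg$frac_toxic * cfg$n_compounds)
  n_lowread <- round(cfg$frac_lowread * cfg$n_compounds)
  flagged <- sample(cfg$n_compounds, n_toxic + n_lowread)
  toxic_set <- flagged[seq_len(n_toxic)]
  lowread_set <- setdiff(flagged, toxic_set)
  clean <- setdiff(seq_len(cfg$n_compounds), flagged)
  n_resc <- round(cfg$frac_rescuers * cfg$n_compounds)
  if (n_resc > length(clean))
    stop("frac_rescuers leaves no unflagged compounds to assign", call. = FALSE)
  resc_set <- if (n_resc > 0) sample(clean, n_resc) else integer(0)
  rho <- numeric(cfg$n_compounds)
  rho[resc_set] <- stats::runif(n_resc, cfg$rescue_fraction_range[1],
                                cfg$rescue_fraction_range[2])
  truth_compounds <- data.frame(
    compound_id = comp_ids,
    rescue_fraction = rho,
    is_toxic = seq_len(cfg$n_compounds) %in% toxic_set,
    is_lowread = seq_len(cfg$n_compounds) %in% lowread_set,
    stringsAsFactors = FALSE
  )

  ## ---- plate layout -------------------------------------------------------
  per_plate <- ceiling(cfg$n_compounds / cfg$n_plates)
  wt_n <- cfg$n_wt_controls_per_plate
  ko_n <- cfg$n_ko_controls_per_plate
  wells_list <- vector("list", cfg$n_plates)
  for (p in seq_len(cfg$n_plates)) {
    c_idx <- seq.int((p - 1L) * per_plate + 1L,
                     min(p * per_plate, cfg$n_compounds))
    c_idx <- c_idx[c_idx <= cfg$n_compounds]
    n_wells <- wt_n + ko_n + length(c_idx)
    wells_list[[p]] <- data.frame(
      plate_id = sprintf("P%d", p),
      well_id = well_grid(n_wells),
      genotype = c(rep("WT", wt_n), rep("KO", ko_n + length(c_idx))),
      treatment = c(rep("untreated", wt_n + ko_n),
                    rep("compound", length(c_idx))),
      compound_id = c(rep("", wt_n + ko_n), comp_ids[c_idx]),
      stringsAsFactors = FALSE
    )
  }
  wells <- do.call(rbind, wells_list)
  rownames(wells) <- NULL
  comp_row <- match(wells$compound_id, comp_ids)   # NA for controls

  ## ---- cell counts ---------------------------------------------------------
  n_w <- nrow(wells)
  cell <- pmax(stats::rnorm(n_w, 1, cfg$cell_count_sd), 0)
  # toxic wells: Uniform(0.05, 0.35) of the realized untreated mean of the
  # same plate, so they sit strictly below the 40% QC threshold
  untr <- wells$treatment == "untreated"
  plate_mean <- tapply(cell[untr], wells$plate_id[untr], mean)
  toxic_well <- !is.na(comp_row) & truth_compounds$is_toxic[comp_row]
  cell[toxic_well] <- stats::runif(sum(toxic_well), 0.05, 0.35) *
    plate_mean[wells$plate_id[toxic_well]]
  wells$cell_count <- unname(cell)

  ## ---- library sizes -------------------------------------------------------
  if (cfg$library_size_cv > 0) {
    sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
    lib <- stats::rlnorm(n_w, log(cfg$library_size_mean) - sdlog^2 / 2, sdlog)
  } else {
    lib <- rep(cfg$library_size_mean, n_w)
  }
  lowread_well <- !is.na(comp_row) & truth_compounds$is_lowread[comp_row]
  lib[lowread_well] <- stats::runif(sum(lowread_well),
                                    cfg$lowread_library_range[1],
                                    cfg$lowread_library_range[2])

  ## ---- expected counts and sampling ---------------------------------------
  l2wt <- log2(pmax(ab_wt, .Machine$double.xmin))
  l2ko <- log2(pmax(ab_ko, .Machine$double.xmin))
  mu <- matrix(0, n_w, cfg$n_probes,
               dimnames = list(paste(wells$plate_id, wells$well_id, sep = ":"),
                               panel$probe_id))
  for (w in seq_len(n_w)) {
    if (wells$genotype[w] == "WT") {
      ab <- ab_wt
    } else if (wells$treatment[w] == "untreated") {
      ab <- ab_ko
    } else {
      r <- rho[comp_row[w]]
      ab <- 2 ^ (l2ko + r * (l2wt - l2ko))
      ab[ab_ko == 0] <- 0     # target gene never rescued at the probe level
    }
    mu[w, ] <- lib[w] * ab
  }

  counts <- switch(cfg$noise_model,
    none = mu,
    poisson = matrix(stats::rpois(length(mu), mu), n_w,
                     dimnames = dimnames(mu)),
    nb = if (cfg$nb_dispersion == 0) {
      matrix(stats::rpois(length(mu), mu), n_w, dimnames = dimnames(mu))
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
             n_w, dimnames = dimnames(mu))
    })

  structure(list(counts = counts, wells = wells, panel = panel,
                 truth = list(compounds = truth_compounds,
                              genes = truth_genes),
                 config = cfg),
            class = "rasl_screen")
}

#' @export
print.rasl_screen <- function(x, ...) {
  cat(sprintf("rasl_screen: %d wells x %d probes on %d plate(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$wells$plate_id))))
  cat(sprintf("  controls: %d WT, %d KO untreated; compound wells: %d\n",
              sum(x$wells$genotype == "WT" & x$wells$treatment == "untreated"),
              sum(x$wells$genotype == "KO" & x$wells$treatment == "untreated"),
              sum(x$wells$treatment == "compound")))
  invisible(x)
}
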