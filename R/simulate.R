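# Synthetic-data generator emulating the study design: 11 HNSCC cell
# lines (3 HPV-positive) and 28 TME-conditioned media as attractants,
# two PBMC donors with duplicate test wells per medium, a 92-protein
# NPX panel with 4 planted stroma-only chemokines, and a 16-sample
# (3 MPR / 13 NPR) expression cohort with planted signature shifts.
#
# Generative model, in brief:
#   * latent secretion s[j, p] is log-normal; the planted chemokines
#     share a per-tumor stromal-activity factor (so they co-vary, as
#     chemokines from a common stromal compartment do) and are never
#     secreted by cell lines;
#   * NPX = protein baseline + log2(1 + s) + Gaussian assay noise; the
#     per-protein LOD sits at a configured quantile of the baseline
#     noise distribution;
#   * well counts are negative binomial with mean
#     baseline_subset * donor_effect * (1 + sum_p w[p, subset] * s[j, p]),
#     with chemokine weights nonzero only for cDC1/cDC2 (T cells do not
#     respond, the study's central negative finding);
#   * bead events are drawn so that bead arithmetic inverts the count
#     within acquisition noise.
#
# One seed governs everything: sub-generators use documented offsets
# (+1 secretome, +2 migration, +3 expression) so partial re-simulation
# is stable.

#' Simulation configuration
#'
#' Defaults mirror the emulated study design; invented parameters
#' (noise scales, dispersion, weights) are documented in the methods
#' vignette.
#'
#' @param seed integer master seed; sub-generators derive their RNG
#'   state as seed + 1 (secretome), + 2 (migration), + 3 (expression).
#' @param n_tme_samples number of TME-conditioned media (default 28).
#' @param n_cell_lines number of cell lines (default 11).
#' @param n_hpv_positive how many cell lines are HPV-positive
#'   (default 3).
#' @param n_donors PBMC donors per TME medium (default 2).
#' @param n_replicates test-well replicates per donor (default 2).
#' @param n_control_replicates control wells per donor (default 4).
#' @param panel_size NPX panel size (default 92).
#' @param planted_chemokines stroma-only proteins driving DC migration.
#' @param n_silent_proteins panel proteins never secreted (below LOD
#'   everywhere), default 24 so roughly 65-70 of 92 are detected.
#' @param subsets immune subsets measured per well.
#' @param baseline_negative_mean named per-subset mean migrated count
#'   toward medium only.
#' @param chemokine_weights named per-subset responsiveness to one unit
#'   of planted-chemokine secretion; zero for T cells.
#' @param positive_control_multiplier fold-increase of the chemokine
#'   mix over baseline (default 8).
#' @param count_dispersion negative-binomial dispersion (1/size) of
#'   well counts (default 0.02).
#' @param donor_sdlog log-SD of the multiplicative donor effect.
#' @param stromal_sdlog log-SD of the shared per-tumor stromal-activity
#'   factor scaling all planted chemokines.
#' @param chemokine_meanlog,chemokine_sdlog log-normal parameters of
#'   the idiosyncratic planted-chemokine secretion.
#' @param npx_noise_sd Gaussian assay noise on NPX (log2 units).
#' @param lod_quantile quantile of the baseline noise distribution at
#'   which the per-protein LOD is set; must lie in (0, 1).
#' @param beads_added counting beads spiked per well.
#' @param n_genes,n_expr_samples,n_mpr expression cohort dimensions
#'   (default 1200 genes, 16 samples of which 3 MPR).
#' @param signature_shift_sd planted shift (in per-gene SD units) added
#'   to "up"-signature genes in MPR samples (default 1).
#'
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_tme_samples = 28L,
                       n_cell_lines = 11L,
                       n_hpv_positive = 3L,
                       n_donors = 2L,
                       n_replicates = 2L,
                       n_control_replicates = 4L,
                       panel_size = 92L,
                       planted_chemokines = c("CCL7", "CCL8", "CCL13",
                                              "CXCL5"),
                       n_silent_proteins = 24L,
                       subsets = MIGRATION_SUBSETS,
                       baseline_negative_mean = c(cDC1 = 80, cDC2 = 300,
                                                  B_cell = 400,
                                                  CD4_T = 1500,
                                                  CD8_T = 900,
                                                  monocyte = 600,
                                                  pDC = 60),
                       chemokine_weights = c(cDC1 = 0.12, cDC2 = 0.18,
                                             B_cell = 0, CD4_T = 0,
                                             CD8_T = 0, monocyte = 0,
                                             pDC = 0),
                       positive_control_multiplier = 8,
                       count_dispersion = 0.02,
                       donor_sdlog = 0.25,
                       stromal_sdlog = 0.8,
                       chemokine_meanlog = log(8),
                       chemokine_sdlog = 0.4,
                       npx_noise_sd = 0.3,
                       lod_quantile = 0.9999,
                       beads_added = 20000L,
                       n_genes = 1200L,
                       n_expr_samples = 16L,
                       n_mpr = 3L,
                       signature_shift_sd = 1) {
  cfg <- as.list(environment())
  if (lod_quantile <= 0 || lod_quantile >= 1)
    stop("config error: lod_quantile must lie strictly in (0, 1)")
  if (n_hpv_positive > n_cell_lines)
    stop("config error: more HPV-positive lines than cell lines")
  if (length(planted_chemokines) > panel_size)
    stop("config error: planted chemokines exceed the panel size")
  if (n_expr_samples < 4)
    stop("config error: expression cohort needs at least 4 samples")
  if (positive_control_multiplier <= 0 || count_dispersion <= 0)
    stop("config error: multipliers and dispersion must be positive")
  if (!setequal(names(baseline_negative_mean), subsets) ||
      !setequal(names(chemokine_weights), subsets))
    stop("config error: per-subset parameters must cover the subsets")
  structure(cfg, class = "sim_config")
}

.panel_names <- function(config) {
  n_other <- config$panel_size - length(config$planted_chemokines)
  c(config$planted_chemokines, sprintf("PROT%03d", seq_len(n_other)))
}

#' Simulate a secretome profile set with ground truth
#'
#' @param config a [sim_config()].
#'
#' @return list with `secretome` (a `secretome_set`) and `truth`
#'   (latent secretion matrix, planted set, protein classes, LODs,
#'   stromal activity per TME sample).
#' @export
simulate_secretome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  panel <- .panel_names(config)
  planted <- config$planted_chemokines
  n_cl <- config$n_cell_lines
  n_tme <- config$n_tme_samples
  cl_ids <- sprintf("CL%02d", seq_len(n_cl))
  tme_ids <- sprintf("TME%02d", seq_len(n_tme))
  ids <- c(cl_ids, tme_ids)
  is_tme <- c(rep(FALSE, n_cl), rep(TRUE, n_tme))

  others <- setdiff(panel, planted)
  silent <- others[seq_len(min(config$n_silent_proteins, length(others)))]
  common <- setdiff(others, silent)
  class_of <- stats::setNames(rep("common", length(panel)), panel)
  class_of[planted] <- "planted"
  class_of[silent] <- "silent"

  baseline <- stats::setNames(stats::runif(length(panel), 1, 4), panel)
  mu_common <- stats::setNames(stats::runif(length(common), 0.5, 3), common)

  s <- matrix(0, length(ids), length(panel), dimnames = list(ids, panel))
  # common proteins: secreted by everyone, elevated in tumors (stromal
  # and immune compartments add to the cell-intrinsic secretion)
  for (p in common) {
    s[, p] <- stats::rlnorm(length(ids),
                            meanlog = mu_common[p] + ifelse(is_tme, 1, 0),
                            sdlog = 0.6)
  }
  # planted chemokines: stroma-only; a shared per-tumor stromal
  # activity factor makes them co-vary across TME samples
  stromal <- stats::setNames(stats::rlnorm(n_tme, 0, config$stromal_sdlog),
                             tme_ids)
  for (p in planted) {
    idio <- stats::rlnorm(n_tme, config$chemokine_meanlog,
                          config$chemokine_sdlog)
    s[tme_ids, p] <- stromal * idio
  }
  npx <- sweep(log2(1 + s), 2, baseline, "+") +
    matrix(stats::rnorm(length(s), 0, config$npx_noise_sd),
           nrow(s), ncol(s))
  lod <- baseline + stats::qnorm(config$lod_quantile) * config$npx_noise_sd

  site_pool <- c("OCSCC", "LSCC", "HSCC", "OPSCC_HPVneg", "OPSCC_HPVpos")
  meta <- data.frame(
    sample_id = ids,
    source = ifelse(is_tme, "tme", "cell_line"),
    site = c(rep("none", n_cl),
             sample(site_pool, n_tme, replace = TRUE)),
    stringsAsFactors = FALSE)
  set <- secretome_set(npx, meta, lod)
  truth <- list(secretion = s, planted = planted, classes = class_of,
                lod = lod, baseline = baseline, stromal_activity = stromal,
                sites = stats::setNames(meta$site, meta$sample_id))
  list(secretome = set, truth = truth)
}

#' Simulate migration wells for the generated secretome
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element from [simulate_secretome()] run
#'   with the same config.
#'
#' @return list with `wells` (one row per well, [read_wells()] schema)
#'   and `meta` (attractant metadata incl. HPV status and site).
#' @export
simulate_migration <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth$secretion))
    stop("missing secretome ground truth; run simulate_secretome first")
  set.seed(config$seed + 2L)
  subsets <- config$subsets
  s <- truth$secretion
  planted <- truth$planted
  size <- 1 / config$count_dispersion

  cl_ids <- grep("^CL", rownames(s), value = TRUE)
  tme_ids <- grep("^TME", rownames(s), value = TRUE)
  donors <- sprintf("D%02d", seq_len(config$n_donors))
  donor_eff <- matrix(
    stats::rlnorm(length(donors) * length(subsets), 0, config$donor_sdlog),
    length(donors), length(subsets), dimnames = list(donors, subsets))

  chemo_mult <- function(j, k) {
    1 + config$chemokine_weights[[k]] * sum(s[j, planted])
  }

  rows <- list()
  add_well <- function(attractant_id, a_class, donor, rep_i, mu_by_subset) {
    acq <- stats::runif(1, 0.3, 0.9)
    bead_events <- stats::rbinom(1, config$beads_added, acq)
    ev <- vapply(subsets, function(k) {
      count <- stats::rnbinom(1, mu = mu_by_subset[[k]], size = size)
      round(count * bead_events / config$beads_added)
    }, numeric(1))
    row <- data.frame(
      well_id = sprintf("W%05d", length(rows) + 1L),
      attractant_id = attractant_id, attractant_class = a_class,
      donor_id = donor, replicate = rep_i,
      bead_events = bead_events, beads_added = config$beads_added,
      stringsAsFactors = FALSE)
    for (k in subsets) row[[k]] <- ev[[k]]
    rows[[length(rows) + 1L]] <<- row
  }

  for (d in donors) {
    for (i in seq_len(config$n_control_replicates)) {
      mu_neg <- lapply(stats::setNames(subsets, subsets), function(k)
        config$baseline_negative_mean[[k]] * donor_eff[d, k])
      add_well("NEG", "negative_control", d, i, mu_neg)
      mu_pos <- lapply(stats::setNames(subsets, subsets), function(k)
        config$baseline_negative_mean[[k]] * donor_eff[d, k] *
          config$positive_control_multiplier)
      add_well("POS", "positive_control", d, i, mu_pos)
    }
    for (j in c(cl_ids, tme_ids)) {
      a_class <- if (grepl("^CL", j)) "cell_line" else "tme_medium"
      for (i in seq_len(config$n_replicates)) {
        mu <- lapply(stats::setNames(subsets, subsets), function(k)
          config$baseline_negative_mean[[k]] * donor_eff[d, k] *
            chemo_mult(j, k))
        add_well(j, a_class, d, i, mu)
      }
    }
  }
  wells <- do.call(rbind, rows)
  rownames(wells) <- NULL

  hpv <- c(rep("negative", config$n_cell_lines - config$n_hpv_positive),
           rep("positive", config$n_hpv_positive))
  tme_sites <- if (!is.null(truth$sites)) unname(truth$sites[tme_ids])
               else rep("OCSCC", length(tme_ids))
  meta <- data.frame(
    attractant_id = c("NEG", "POS", cl_ids, tme_ids),
    hpv_status = c("not_applicable", "not_applicable", hpv,
                   rep("not_applicable", length(tme_ids))),
    site = c("none", "none", rep("none", length(cl_ids)), tme_sites),
    fibroblast_depleted = FALSE,
    stringsAsFactors = FALSE)
  list(wells = wells, meta = meta)
}

# Default signature architecture of the simulated expression cohort.
# "up" signatures receive the planted MPR shift; "flat" do not.
.sim_signatures <- function(n_genes) {
  sizes <- c(chemokine = 25, DC_general = 20, cDC1_specific = 15,
             cDC2_specific = 15, myCAF = 25, iCAF = 25, eCAF = 25,
             pericyte = 25)
  if (sum(sizes) > n_genes)
    stop("config error: fewer genes than signature slots")
  bounds <- cumsum(c(0, sizes))
  sigs <- lapply(seq_along(sizes), function(i)
    sprintf("G%04d", (bounds[i] + 1):bounds[i + 1]))
  names(sigs) <- names(sizes)
  sigs
}

SIM_UP_SIGNATURES <- c("chemokine", "DC_general", "cDC1_specific",
                       "cDC2_specific", "myCAF", "iCAF")
SIM_FLAT_SIGNATURES <- c("eCAF", "pericyte")

SIM_COMPOSITES <- data.frame(
  composite = c("cDC1", "cDC1", "cDC2", "cDC2", "DC_overall", "DC_overall"),
  component = c("DC_general", "cDC1_specific", "DC_general",
                "cDC2_specific", "cDC1", "cDC2"),
  stringsAsFactors = FALSE)

#' Simulate an expression cohort with planted signature shifts
#'
#' Gene values are standard normal per gene; MPR samples receive a
#' `signature_shift_sd` SD upward shift on every gene of the "up"
#' signatures (chemokine, DC, myCAF, iCAF) and no shift on the "flat"
#' ones (eCAF, pericyte), mirroring the pattern of significant versus
#' non-significant signatures the analysis is meant to detect.
#'
#' @param config a [sim_config()].
#'
#' @return list: `values` (genes x samples matrix), `labels` (named
#'   MPR/NPR vector), `signatures` (atomic gene lists), `composites`
#'   (composite definition table), `truth` (shifted signatures and
#'   shift size).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n_s <- config$n_expr_samples
  sample_ids <- sprintf("PT%02d", seq_len(n_s))
  labels <- stats::setNames(
    c(rep("MPR", config$n_mpr), rep("NPR", n_s - config$n_mpr)),
    sample_ids)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  values <- matrix(stats::rnorm(config$n_genes * n_s), config$n_genes, n_s,
                   dimnames = list(genes, sample_ids))
  sigs <- .sim_signatures(config$n_genes)
  mpr <- labels == "MPR"
  up_genes <- unique(unlist(sigs[SIM_UP_SIGNATURES]))
  values[up_genes, mpr] <- values[up_genes, mpr] + config$signature_shift_sd
  list(values = values, labels = labels, signatures = sigs,
       composites = SIM_COMPOSITES,
       truth = list(shifted = SIM_UP_SIGNATURES,
                    flat = SIM_FLAT_SIGNATURES,
                    shift = config$signature_shift_sd))
}
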