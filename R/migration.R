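# Transwell migration quantification and induction calling.
#
# Wells arrive as one row per transwell lower compartment: flow-cytometry
# event counts per immune subset plus counting-bead events. Bead
# arithmetic converts events to absolute cell counts, donor QC removes
# unresponsive donors, counts are normalized to each donor's own positive
# control (chemokine mix = 100%), and induction is called per attractant
# x subset against the matched donor's negative-control mean + 2 SD.

MIGRATION_SUBSETS <- c("cDC1", "cDC2", "B_cell", "CD4_T", "CD8_T",
                       "monocyte", "pDC")

ATTRACTANT_CLASSES <- c("negative_control", "positive_control",
                        "cell_line", "tme_medium")

#' Convert subset events to an absolute cell count via counting beads
#'
#' A known quantity of beads is spiked into each sample before
#' acquisition; the cell:bead event ratio then scales events to absolute
#' counts: `subset_events * beads_added / bead_events`.
#'
#' @param subset_events nonnegative event count(s) for one immune subset.
#' @param bead_events bead events acquired; must be positive.
#' @param beads_added number of beads spiked in.
#'
#' @return Absolute migrated-cell count (real; not rounded).
#' @examples
#' beads_to_count(500, 10000, 20000)  # 1000
#' @export
beads_to_count <- function(subset_events, bead_events, beads_added) {
  if (any(bead_events <= 0))
    stop("unquantifiable well: bead_events must be positive")
  if (any(subset_events < 0) || any(beads_added <= 0))
    stop("subset_events must be >= 0 and beads_added > 0")
  subset_events * beads_added / bead_events
}

#' Donor inclusion rule
#'
#' A donor (per subset) is kept when migration toward the positive
#' control is at least `ratio_cutoff` times migration toward the
#' negative control; the boundary ratio itself is included since the
#' exclusion rule is "less than" the cutoff. A zero negative-control
#' mean with positive-control migration is the limit of the rule and is
#' included; a donor with both means zero is excluded with a warning.
#'
#' @param positive_mean,negative_mean nonnegative mean migrated counts.
#' @param ratio_cutoff exclusion boundary, default 2.5.
#'
#' @return `TRUE` to include the donor.
#' @export
donor_qc <- function(positive_mean, negative_mean, ratio_cutoff = 2.5) {
  if (positive_mean < 0 || negative_mean < 0)
    stop("means must be nonnegative")
  if (positive_mean == 0 && negative_mean == 0) {
    warning("degenerate donor: zero migration toward both controls; excluded")
    return(FALSE)
  }
  if (negative_mean == 0) return(TRUE)
  positive_mean / negative_mean >= ratio_cutoff
}

#' Call migration induction for one attractant x subset
#'
#' Induced when the attractant's mean migrated count strictly exceeds
#' the negative-control mean plus `sd_mult` sample standard deviations
#' of the negative-control replicates.
#'
#' @param attractant_counts numeric vector, >= 1 replicate.
#' @param negative_counts numeric vector, >= 2 replicates (a sample SD
#'   needs n >= 2).
#' @param sd_mult SD multiplier, default 2.
#'
#' @return list with `mean_count`, `threshold`, `induced`.
#' @examples
#' call_active(c(15, 15), c(8, 10, 12))  # threshold 14, induced
#' @export
call_active <- function(attractant_counts, negative_counts, sd_mult = 2) {
  if (length(attractant_counts) < 1)
    stop("need at least one attractant replicate")
  if (length(negative_counts) < 2)
    stop("insufficient negative-control replicates (need >= 2)")
  thr <- mean(negative_counts) + sd_mult * stats::sd(negative_counts)
  m <- mean(attractant_counts)
  list(mean_count = m, threshold = thr, induced = m > thr)
}

#' Normalize a migrated count to the positive control
#'
#' @param count migrated-cell count.
#' @param positive_mean mean count toward the positive control; must be
#'   positive (a donor with a nonpositive positive control should
#'   already have failed QC).
#'
#' @return `100 * count / positive_mean`.
#' @export
normalize_percent <- function(count, positive_mean) {
  if (any(positive_mean <= 0))
    stop("normalization error: positive-control mean must be positive")
  100 * count / positive_mean
}

.validate_wells <- function(wells, panel) {
  need <- c("well_id", "attractant_id", "attractant_class", "donor_id",
            "replicate", "bead_events", "beads_added")
  missing_cols <- setdiff(need, names(wells))
  if (length(missing_cols))
    stop("wells table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(wells$attractant_class), ATTRACTANT_CLASSES)
  if (length(bad))
    stop("unknown attractant_class: ", paste(bad, collapse = ", "))
  missing_sub <- setdiff(panel, names(wells))
  if (length(missing_sub))
    stop("wells table is missing subset column(s): ",
         paste(missing_sub, collapse = ", "))
  invisible(wells)
}

#' Summarize a migration experiment into induction calls
#'
#' Full per-experiment pipeline: bead-based quantification, per-donor QC
#' against each donor's own controls, within-donor normalization to the
#' positive control, pooling across donors, and induction calling per
#' attractant x subset.
#'
#' For `donor_pooling = "mean"` each donor contributes one mean per
#' attractant x subset and donor-level means, thresholds and normalized
#' percents are averaged; `"separate"` emits one row per donor. When
#' every donor is excluded for a subset, a row with `n_replicates = 0`
#' and `induced = NA` is still emitted so the absence is visible.
#'
#' @param wells data.frame, one row per well (see
#'   [read_wells()] for the schema).
#' @param meta optional attractant metadata data.frame
#'   (`attractant_id`, `hpv_status`, `site`, `fibroblast_depleted`);
#'   carried through onto the output when supplied.
#' @param panel character vector of subset column names present in
#'   `wells`; defaults to the built-in 7-subset panel intersected with
#'   the columns actually present.
#' @param ratio_cutoff donor-QC boundary (default 2.5).
#' @param sd_mult induction SD multiplier (default 2).
#' @param donor_pooling `"mean"` (default) or `"separate"`.
#'
#' @return data.frame of migration calls: `attractant_id`,
#'   `attractant_class`, `subset`, `mean_count`, `normalized_percent`,
#'   `threshold`, `induced`, `n_replicates` (and `donor_id` when
#'   `donor_pooling = "separate"`).
#' @export
summarize_experiment <- function(wells, meta = NULL,
                                 panel = intersect(MIGRATION_SUBSETS,
                                                   names(wells)),
                                 ratio_cutoff = 2.5, sd_mult = 2,
                                 donor_pooling = c("mean", "separate")) {
  donor_pooling <- match.arg(donor_pooling)
  .validate_wells(wells, panel)
  donors <- unique(wells$donor_id)

  # absolute counts per well x subset
  counts <- sapply(panel, function(s)
    beads_to_count(wells[[s]], wells$bead_events, wells$beads_added))
  counts <- matrix(counts, nrow = nrow(wells),
                   dimnames = list(NULL, panel))

  # per donor x subset: control summaries and QC
  donor_stats <- list()
  for (d in donors) {
    neg <- wells$donor_id == d & wells$attractant_class == "negative_control"
    pos <- wells$donor_id == d & wells$attractant_class == "positive_control"
    if (!any(neg) || !any(pos))
      stop("donor ", d, " lacks negative- or positive-control wells")
    if (sum(neg) < 2)
      stop("insufficient negative-control replicates for donor ", d)
    for (s in panel) {
      neg_counts <- counts[neg, s]
      pos_counts <- counts[pos, s]
      include <- withCallingHandlers(
        donor_qc(mean(pos_counts), mean(neg_counts), ratio_cutoff),
        warning = function(w) invokeRestart("muffleWarning"))
      donor_stats[[paste(d, s, sep = "\r")]] <- list(
        neg_mean = mean(neg_counts),
        threshold = mean(neg_counts) + sd_mult * stats::sd(neg_counts),
        pos_mean = mean(pos_counts),
        include = include)
    }
  }

  attract <- unique(wells$attractant_id)
  rows <- list()
  for (a in attract) {
    a_class <- wells$attractant_class[wells$attractant_id == a][1]
    for (s in panel) {
      per_donor <- list()
      for (d in donors) {
        sel <- wells$attractant_id == a & wells$donor_id == d
        if (!any(sel)) next
        st <- donor_stats[[paste(d, s, sep = "\r")]]
        if (!st$include) next
        dm <- mean(counts[sel, s])
        per_donor[[d]] <- data.frame(
          donor_id = d,
          mean_count = dm,
          normalized_percent = normalize_percent(dm, st$pos_mean),
          threshold = st$threshold,
          n_replicates = sum(sel),
          stringsAsFactors = FALSE)
      }
      if (length(per_donor) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          attractant_id = a, attractant_class = a_class, subset = s,
          mean_count = NA_real_, normalized_percent = NA_real_,
          threshold = NA_real_, induced = NA, n_replicates = 0L,
          stringsAsFactors = FALSE)
        next
      }
      dd <- do.call(rbind, per_donor)
      if (donor_pooling == "mean") {
        mc <- mean(dd$mean_count)
        thr <- mean(dd$threshold)
        rows[[length(rows) + 1]] <- data.frame(
          attractant_id = a, attractant_class = a_class, subset = s,
          mean_count = mc,
          normalized_percent = mean(dd$normalized_percent),
          threshold = thr, induced = mc > thr,
          n_replicates = sum(dd$n_replicates),
          stringsAsFactors = FALSE)
      } else {
        dd$induced <- dd$mean_count > dd$threshold
        dd2 <- data.frame(
          attractant_id = a, attractant_class = a_class, subset = s,
          donor_id = dd$donor_id, mean_count = dd$mean_count,
          normalized_percent = dd$normalized_percent,
          threshold = dd$threshold, induced = dd$induced,
          n_replicates = dd$n_replicates, stringsAsFactors = FALSE)
        rows[[length(rows) + 1]] <- dd2
      }
    }
  }
  calls <- do.call(rbind, rows)
  if (!is.null(meta)) {
    keep <- c("attractant_id",
              intersect(c("hpv_status", "site", "fibroblast_depleted"),
                        names(meta)))
    calls <- merge(calls, meta[, keep, drop = FALSE],
                   by = "attractant_id", all.x = TRUE, sort = FALSE)
  }
  # canonical row order, independent of input well order
  calls <- calls[order(calls$attractant_id, calls$subset), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' HPV-status contingency of induction calls for cell lines
#'
#' Cross-tabulates induced vs not-induced cell lines by HPV status for
#' one immune subset and tests the association with the exact Fisher
#' test.
#'
#' @param calls migration-call table (from [summarize_experiment()])
#'   carrying an `hpv_status` column, restricted internally to
#'   `attractant_class == "cell_line"`.
#' @param subset immune subset to tabulate, e.g. `"cDC2"`.
#'
#' @return list with the 2x2 `table` (rows = HPV status, columns =
#'   induced yes/no) and the Fisher `test` (`chemo_test`).
#' @export
hpv_contingency <- function(calls, subset) {
  cl <- calls[calls$attractant_class == "cell_line" &
                calls$subset == subset, , drop = FALSE]
  if (nrow(cl) == 0) stop("no cell-line calls for subset ", subset)
  if (!"hpv_status" %in% names(cl) || anyNA(cl$hpv_status) ||
      any(!cl$hpv_status %in% c("negative", "positive")))
    stop("every cell line must carry an HPV status")
  if (anyNA(cl$induced)) stop("cell line with missing induction call")
  tab <- matrix(
    c(sum(cl$hpv_status == "negative" & cl$induced),
      sum(cl$hpv_status == "negative" & !cl$induced),
      sum(cl$hpv_status == "positive" & cl$induced),
      sum(cl$hpv_status == "positive" & !cl$induced)),
    nrow = 2, byrow = TRUE,
    dimnames = list(hpv = c("negative", "positive"),
                    induced = c("yes", "no")))
  test <- fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
  list(table = tab, test = test)
}

#' Paired comparison of migration between two arms
#'
#' Wilcoxon signed-rank test on normalized migration percents measured
#' for the same tumor specimens under two conditions (e.g. total TME
#' versus fibroblast-depleted TME).
#'
#' @param calls_total,calls_depleted named numeric vectors of normalized
#'   percents; names are specimen identifiers and must coincide as sets.
#'
#' @return A `chemo_test`.
#' @export
compare_paired <- function(calls_total, calls_depleted) {
  if (is.null(names(calls_total)) || is.null(names(calls_depleted)))
    stop("both arms must be named by specimen")
  if (!setequal(names(calls_total), names(calls_depleted)))
    stop("pairing error: the two arms cover different specimens")
  ord <- names(calls_total)
  wilcoxon_signed_rank(calls_total[ord], calls_depleted[ord])
}
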