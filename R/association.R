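# Correlation screen linking secretome NPX to migration counts, and the
# combined candidate-chemokine selection rule: a candidate must (i)
# correlate positively and significantly (BH q < alpha) with migration
# of the anchor dendritic-cell subset and (ii) pass the cell-line-vs-TME
# presence contrast, marking it as stroma-derived.

#' Pivot migration calls to a per-sample count matrix
#'
#' Convenience reshaper from the long call table produced by
#' [summarize_experiment()] to the wide per-sample absolute-count layout
#' the screen consumes. Only TME-medium attractants are kept.
#'
#' @param calls migration-call data.frame.
#'
#' @return data.frame with `sample_id` and one column of mean absolute
#'   counts per subset.
#' @export
migration_count_matrix <- function(calls) {
  tme <- calls[calls$attractant_class == "tme_medium", , drop = FALSE]
  if (nrow(tme) == 0) stop("no TME-medium calls present")
  samples <- unique(tme$attractant_id)
  subsets <- unique(tme$subset)
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (s in subsets) {
    sub <- tme[tme$subset == s, , drop = FALSE]
    out[[s]] <- sub$mean_count[match(samples, sub$attractant_id)]
  }
  out
}

#' Screen secretome proteins for correlation with migration
#'
#' Pearson correlation between per-sample absolute migrated counts and
#' NPX, one record per (subset, protein), restricted to proteins
#' detected in the TME secretomes. Benjamini-Hochberg correction is
#' applied within each subset's protein family by default (`fdr_family
#' = "per_subset"`); `"global"` pools all records into one family.
#' Records with zero variance on either side are flagged degenerate and
#' excluded from the BH family. Significance is `q < alpha`
#' (`use_unadjusted = TRUE` switches to `p < alpha`).
#'
#' @param migration data.frame with `sample_id` plus one numeric column
#'   per subset of absolute counts (see [migration_count_matrix()]).
#' @param set a `secretome_set`; only its TME samples are used.
#' @param subsets subset columns to screen; default all count columns.
#' @param alpha significance threshold on q (default 0.05).
#' @param fdr_family `"per_subset"` (default) or `"global"`.
#' @param min_detected_samples passed to [detected_proteins()].
#' @param lod_policy below-LOD substitution policy for NPX.
#' @param use_unadjusted call significance on raw p instead of q.
#'
#' @return data.frame of association records: `subset`, `protein`, `r`,
#'   `p`, `q`, `n`, `significant`, `degenerate`.
#' @export
screen_associations <- function(migration, set,
                                subsets = setdiff(names(migration),
                                                  "sample_id"),
                                alpha = 0.05,
                                fdr_family = c("per_subset", "global"),
                                min_detected_samples = 1,
                                lod_policy = c("lod", "half_lod"),
                                use_unadjusted = FALSE) {
  fdr_family <- match.arg(fdr_family)
  lod_policy <- match.arg(lod_policy)
  stopifnot(inherits(set, "secretome_set"))
  if (!"sample_id" %in% names(migration))
    stop("migration table needs a sample_id column")
  tme_ids <- set$meta$sample_id[set$meta$source == "tme"]
  shared <- intersect(migration$sample_id, tme_ids)
  if (length(shared) < 3)
    stop("need at least 3 samples shared between migration and NPX")
  v <- npx_values(set, lod_policy)[shared, , drop = FALSE]
  proteins <- detected_proteins(set, min_detected_samples)
  mig <- migration[match(shared, migration$sample_id), , drop = FALSE]

  rows <- list()
  for (s in subsets) {
    counts <- as.numeric(mig[[s]])
    ok <- !is.na(counts)
    for (p in proteins) {
      xs <- counts[ok]; ys <- v[ok, p]
      n <- sum(ok)
      if (n < 3 || stats::sd(xs) == 0 || stats::sd(ys) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          subset = s, protein = p, r = NA_real_, p = NA_real_,
          n = n, degenerate = TRUE, stringsAsFactors = FALSE)
        next
      }
      ct <- pearson(xs, ys)
      rows[[length(rows) + 1]] <- data.frame(
        subset = s, protein = p, r = ct$statistic, p = ct$p_value,
        n = n, degenerate = FALSE, stringsAsFactors = FALSE)
    }
  }
  rec <- do.call(rbind, rows)
  rec$q <- NA_real_
  live <- !rec$degenerate
  if (fdr_family == "per_subset") {
    for (s in unique(rec$subset)) {
      idx <- which(live & rec$subset == s)
      if (length(idx)) rec$q[idx] <- bh_fdr(rec$p[idx])$q_values
    }
  } else {
    idx <- which(live)
    if (length(idx)) rec$q[idx] <- bh_fdr(rec$p[idx])$q_values
  }
  crit <- if (use_unadjusted) rec$p else rec$q
  rec$significant <- !rec$degenerate & !is.na(crit) & crit < alpha
  rec[, c("subset", "protein", "r", "p", "q", "n", "significant",
          "degenerate")]
}

#' Select candidate chemokines
#'
#' Intersects the correlation screen with the presence contrast:
#' `significant_positive` are proteins significantly and positively
#' correlated with migration of the anchor subset; `candidates` are
#' those that also pass the cell-line-vs-TME presence contrast.
#'
#' @param records association records from [screen_associations()].
#' @param contrasts presence-contrast table from [presence_contrast()].
#' @param anchor_subset subset anchoring the selection, default
#'   `"cDC1"`.
#'
#' @return list of class `candidate_selection`: `subset`,
#'   `significant_positive`, `candidates`.
#' @export
select_candidates <- function(records, contrasts, anchor_subset = "cDC1") {
  if (!anchor_subset %in% records$subset)
    stop("anchor subset ", anchor_subset, " absent from the records")
  anchor <- records[records$subset == anchor_subset, , drop = FALSE]
  sig_pos <- anchor$protein[anchor$significant & !is.na(anchor$r) &
                              anchor$r > 0]
  passing <- contrasts$protein[contrasts$passes]
  structure(
    list(subset = anchor_subset,
         significant_positive = sig_pos,
         candidates = intersect(sig_pos, passing)),
    class = "candidate_selection")
}

#' @export
print.candidate_selection <- function(x, ...) {
  cat("candidate selection anchored on", x$subset, "\n")
  cat("  significantly positively correlated:",
      length(x$significant_positive), "protein(s)\n")
  cat("  passing the presence contrast:",
      if (length(x$candidates)) paste(x$candidates, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
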