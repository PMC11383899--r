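# NPX secretome profiles with limit-of-detection semantics.
#
# NPX (Normalized Protein eXpression) is Olink's relative log2-scale
# abundance unit: comparable across samples for one protein, never
# across proteins. Values below the per-protein limit of detection (LOD)
# are stored as reported but flagged; analyses substitute the LOD value
# itself by default (half-LOD, i.e. LOD - 1 on the log2 scale, is
# available as an alternative policy).

#' Build a secretome profile set
#'
#' @param npx numeric matrix, samples x proteins, rownames = sample ids,
#'   colnames = panel proteins (no duplicates).
#' @param meta data.frame with columns `sample_id`, `source`
#'   (`"cell_line"` or `"tme"`) and optionally `site`; one row per NPX
#'   row, matched by `sample_id`.
#' @param lod named numeric vector of per-protein LODs covering the
#'   panel. `NULL` means no LOD information: every value is treated as
#'   detected, with a warning.
#'
#' @return An object of class `secretome_set` with elements `npx`,
#'   `meta`, `lod`, `below_lod` (logical matrix) and `panel`.
#' @export
secretome_set <- function(npx, meta, lod = NULL) {
  npx <- as.matrix(npx)
  if (is.null(colnames(npx)) || is.null(rownames(npx)))
    stop("npx must have sample rownames and protein colnames")
  if (anyDuplicated(colnames(npx)))
    stop("duplicate proteins in the panel")
  if (anyDuplicated(rownames(npx)))
    stop("duplicate sample ids")
  if (!all(c("sample_id", "source") %in% names(meta)))
    stop("meta must contain sample_id and source")
  if (!setequal(meta$sample_id, rownames(npx)))
    stop("meta sample_id set does not match the NPX rows")
  if (any(!meta$source %in% c("cell_line", "tme")))
    stop("source must be 'cell_line' or 'tme'")
  meta <- meta[match(rownames(npx), meta$sample_id), , drop = FALSE]
  panel <- colnames(npx)
  if (is.null(lod)) {
    warning("no LOD supplied: all NPX values treated as detected")
    below <- matrix(FALSE, nrow(npx), ncol(npx), dimnames = dimnames(npx))
    lod <- stats::setNames(rep(-Inf, length(panel)), panel)
  } else {
    if (!all(panel %in% names(lod)))
      stop("lod must cover every panel protein")
    lod <- lod[panel]
    below <- sweep(npx, 2, lod, "<")
  }
  structure(list(npx = npx, meta = meta, lod = lod,
                 below_lod = below, panel = panel),
            class = "secretome_set")
}

#' @export
print.secretome_set <- function(x, ...) {
  cat("secretome_set:", nrow(x$npx), "samples x", length(x$panel),
      "proteins\n")
  cat("  cell lines:", sum(x$meta$source == "cell_line"),
      " TME:", sum(x$meta$source == "tme"), "\n")
  cat("  values below LOD:", sum(x$below_lod), "\n")
  invisible(x)
}

# NPX with the below-LOD substitution policy applied.
npx_values <- function(set, lod_policy = c("lod", "half_lod")) {
  lod_policy <- match.arg(lod_policy)
  v <- set$npx
  sub <- matrix(rep(set$lod, each = nrow(v)), nrow(v), ncol(v),
                dimnames = dimnames(v))
  if (lod_policy == "half_lod") sub <- sub - 1  # half on the linear scale
  v[set$below_lod] <- sub[set$below_lod]
  v
}

#' Proteins detected in the TME-derived secretomes
#'
#' A protein counts as detected when it is above the LOD in at least
#' `min_detected_samples` TME samples (default 1, the liberal reading).
#'
#' @param set a `secretome_set` containing at least one TME profile.
#' @param min_detected_samples detection count threshold.
#'
#' @return Character vector of detected proteins (panel order).
#' @export
detected_proteins <- function(set, min_detected_samples = 1) {
  stopifnot(inherits(set, "secretome_set"))
  tme <- set$meta$source == "tme"
  if (!any(tme)) stop("no TME profiles in the set")
  n_det <- colSums(!set$below_lod[tme, , drop = FALSE])
  set$panel[n_det >= min_detected_samples]
}

#' Cell-line-versus-TME presence contrast
#'
#' The candidate-selection rule for stroma-derived chemokines: a protein
#' passes when it is below the LOD in every cell-line secretome and
#' above the LOD in a strict majority (fraction > `majority_threshold`)
#' of TME secretomes.
#'
#' @param set a `secretome_set` with both sources present.
#' @param proteins proteins to evaluate; default the whole panel.
#' @param majority_threshold default 0.5 (a 50% fraction does not pass).
#'
#' @return data.frame: `protein`, `all_cell_lines_below_lod`,
#'   `tme_detected_fraction`, `passes`.
#' @export
presence_contrast <- function(set, proteins = set$panel,
                              majority_threshold = 0.5) {
  stopifnot(inherits(set, "secretome_set"))
  unknown <- setdiff(proteins, set$panel)
  if (length(unknown))
    stop("unknown protein(s): ", paste(unknown, collapse = ", "))
  cl <- set$meta$source == "cell_line"
  tme <- set$meta$source == "tme"
  if (!any(cl) || !any(tme))
    stop("need both cell-line and TME profiles")
  all_below <- colSums(set$below_lod[cl, proteins, drop = FALSE]) == sum(cl)
  det_frac <- colMeans(!set$below_lod[tme, proteins, drop = FALSE])
  data.frame(
    protein = proteins,
    all_cell_lines_below_lod = unname(all_below),
    tme_detected_fraction = unname(det_frac),
    passes = unname(all_below & det_frac > majority_threshold),
    stringsAsFactors = FALSE)
}

#' Compare one protein's NPX between two sample groups
#'
#' Two-sided Mann-Whitney test on NPX values between two site groups
#' (e.g. HSCC vs LSCC). Below-LOD values participate at their
#' substituted value under `lod_policy`.
#'
#' @param set a `secretome_set` whose `meta` carries a `site` column.
#' @param protein single panel protein.
#' @param sites length-2 character vector of site labels; each group
#'   must have at least 2 samples.
#' @param lod_policy `"lod"` (default) or `"half_lod"`.
#'
#' @return A `chemo_test`.
#' @export
group_npx_compare <- function(set, protein, sites,
                              lod_policy = c("lod", "half_lod")) {
  stopifnot(inherits(set, "secretome_set"))
  if (!protein %in% set$panel) stop("unknown protein: ", protein)
  if (length(sites) != 2) stop("sites must name exactly two groups")
  if (!"site" %in% names(set$meta)) stop("meta carries no site column")
  v <- npx_values(set, lod_policy)[, protein]
  g1 <- v[set$meta$site == sites[1]]
  g2 <- v[set$meta$site == sites[2]]
  if (length(g1) < 2 || length(g2) < 2)
    stop("each site group needs at least 2 samples")
  mann_whitney(g1, g2)
}
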