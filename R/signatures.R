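# Gene-set signature Z-scoring of bulk expression and comparison of
# scores between immunotherapy responders (MPR) and non-responders
# (NPR).
#
# Scoring: each gene is z-scored across the cohort (sample SD), the
# per-sample signature score is the mean z over signature genes present
# in the matrix. Zero-variance genes contribute z = 0; genes absent
# from the matrix are dropped and the number actually used is reported.
# By construction one signature's scores average to zero over the
# cohort.

#' Resolve composite signatures into gene lists
#'
#' Composite signatures (e.g. cDC1 = general DC + cDC1-specific;
#' overall DC = cDC1 + cDC2) resolve to the duplicate-free union of
#' their components' gene lists. Components may themselves be
#' composites; cycles are rejected.
#'
#' @param sigs named list of character gene vectors (atomic
#'   signatures).
#' @param composites data.frame with columns `composite`, `component`,
#'   one row per membership; or `NULL` for no composites.
#'
#' @return Named list of gene vectors covering atomic and composite
#'   signatures.
#' @export
resolve_signatures <- function(sigs, composites = NULL) {
  if (is.null(composites)) return(sigs)
  if (!all(c("composite", "component") %in% names(composites)))
    stop("composites must have columns 'composite' and 'component'")
  out <- sigs
  resolving <- character(0)
  resolve1 <- function(name) {
    if (name %in% names(out)) return(out[[name]])
    if (name %in% resolving) stop("cycle in composite definitions: ", name)
    comp <- composites$component[composites$composite == name]
    if (length(comp) == 0) stop("unknown signature: ", name)
    resolving <<- c(resolving, name)
    genes <- unique(unlist(lapply(comp, resolve1)))
    resolving <<- setdiff(resolving, name)
    out[[name]] <<- genes
    genes
  }
  for (nm in unique(composites$composite)) resolve1(nm)
  out
}

#' Score samples against a gene signature
#'
#' @param values numeric matrix, genes x samples, with rownames and
#'   colnames; assumed log-scale and library-normalized upstream.
#' @param genes character vector of signature genes.
#' @param signature label carried onto the output.
#'
#' @return data.frame: `sample_id`, `signature`, `z` (mean gene
#'   z-score), `n_genes_used`.
#' @export
score_signature <- function(values, genes, signature = "signature") {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need at least 2 samples to z-score")
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers")
  present <- intersect(genes, rownames(values))
  if (length(present) == 0)
    stop("empty signature: no gene of '", signature, "' is in the matrix")
  sub <- values[present, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  z <- (sub - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  data.frame(
    sample_id = colnames(values),
    signature = signature,
    z = unname(colMeans(z)),
    n_genes_used = length(present),
    stringsAsFactors = FALSE)
}

#' Score samples against many signatures
#'
#' @param values genes x samples matrix (see [score_signature()]).
#' @param sigs named list of gene vectors, e.g. from [read_gmt()] after
#'   [resolve_signatures()].
#'
#' @return Long data.frame of per-sample, per-signature scores.
#' @export
score_signatures <- function(values, sigs) {
  do.call(rbind, lapply(names(sigs), function(nm)
    score_signature(values, sigs[[nm]], nm)))
}

#' Compare signature scores between response groups
#'
#' Two-sided Mann-Whitney (rank-sum) test of per-sample signature
#' scores between labeled groups (MPR vs NPR), exact for cohort sizes
#' like 3 vs 13.
#'
#' @param scores data.frame from [score_signatures()].
#' @param labels named character vector mapping `sample_id` to `"MPR"`,
#'   `"NPR"` or `"unlabeled"`; unlabeled samples are dropped.
#'
#' @return data.frame with one row per signature: `signature`,
#'   `statistic`, `p`, `exact`, `n_mpr`, `n_npr`.
#' @export
compare_response <- function(scores, labels) {
  lab <- labels[scores$sample_id]
  rows <- lapply(split(seq_len(nrow(scores)), scores$signature),
                 function(idx) {
    s <- scores[idx, ]
    l <- lab[idx]
    x <- s$z[!is.na(l) & l == "MPR"]
    y <- s$z[!is.na(l) & l == "NPR"]
    if (length(x) == 0 || length(y) == 0)
      stop("both response groups must be nonempty")
    mt <- mann_whitney(x, y, exact_threshold = max(length(x), length(y)))
    data.frame(signature = s$signature[1], statistic = mt$statistic,
               p = mt$p_value, exact = mt$exact,
               n_mpr = length(x), n_npr = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
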