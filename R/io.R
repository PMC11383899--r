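# Readers and writers for the pipeline's file formats.
#
# Conventions: CSV (comma, header row, "." decimal, UTF-8) for input
# matrices, TSV for result tables, GMT for gene sets, YAML for
# configuration. Floats are serialized with 17 significant digits so a
# write-read round trip reproduces values bit-exactly. Empty cells are
# missing values, never zero.

.read_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, sep = sep, header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "")
}

.write_table <- function(x, path, sep = ",") {
  # 17 significant digits: lossless for doubles
  num <- vapply(x, is.numeric, logical(1)) &
    !vapply(x, is.integer, logical(1))
  x[num] <- lapply(x[num], function(v) format(v, digits = 17,
                                              scientific = FALSE,
                                              trim = TRUE))
  utils::write.table(x, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  invisible(df)
}

.check_numeric <- function(df, cols, path) {
  for (cc in cols) {
    v <- df[[cc]]
    if (is.character(v)) {
      suppress <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(suppress))
      if (length(bad))
        stop("parse error in ", path, ", line ", bad[1] + 1,
             ", column '", cc, "': non-numeric value '", v[bad[1]], "'")
      df[[cc]] <- suppress
    }
  }
  df
}

#' Read a migration wells table
#'
#' Schema: `well_id, attractant_id, attractant_class, donor_id,
#' replicate, bead_events, beads_added`, then one column per subset
#' event count.
#'
#' @param path CSV path.
#' @return data.frame of wells.
#' @export
read_wells <- function(path) {
  w <- .read_table(path)
  .require_columns(w, c("well_id", "attractant_id", "attractant_class",
                        "donor_id", "replicate", "bead_events",
                        "beads_added"), path)
  if (anyDuplicated(w$well_id)) {
    dup <- w$well_id[duplicated(w$well_id)][1]
    stop("parse error in ", path, ", line ",
         which(w$well_id == dup)[2] + 1, ": duplicate well_id '", dup, "'")
  }
  subset_cols <- setdiff(names(w),
                         c("well_id", "attractant_id", "attractant_class",
                           "donor_id", "replicate", "bead_events",
                           "beads_added"))
  .check_numeric(w, c("replicate", "bead_events", "beads_added",
                      subset_cols), path)
}

#' Read attractant metadata
#'
#' Schema: `attractant_id, hpv_status, site, fibroblast_depleted`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_attractant_meta <- function(path) {
  m <- .read_table(path)
  .require_columns(m, c("attractant_id", "hpv_status", "site",
                        "fibroblast_depleted"), path)
  if (anyDuplicated(m$attractant_id))
    stop("parse error in ", path, ": duplicate attractant_id")
  m$fibroblast_depleted <- as.logical(m$fibroblast_depleted)
  m
}

#' Read an NPX matrix plus LOD table into a secretome set
#'
#' NPX schema: `sample_id, source, site`, then one numeric column per
#' panel protein. LOD schema: `protein, lod`.
#'
#' @param path NPX CSV path.
#' @param lod_path companion LOD CSV path, or `NULL` (all values
#'   treated as detected, with a warning).
#' @return A `secretome_set`.
#' @export
read_npx <- function(path, lod_path = NULL) {
  d <- .read_table(path)
  .require_columns(d, c("sample_id", "source"), path)
  if (anyDuplicated(d$sample_id)) {
    dup <- d$sample_id[duplicated(d$sample_id)][1]
    stop("parse error in ", path, ", line ",
         which(d$sample_id == dup)[2] + 1,
         ": duplicate sample_id '", dup, "'")
  }
  meta_cols <- intersect(c("sample_id", "source", "site"), names(d))
  prot_cols <- setdiff(names(d), meta_cols)
  if (length(prot_cols) == 0)
    stop("parse error in ", path, ": no protein columns")
  d <- .check_numeric(d, prot_cols, path)
  npx <- as.matrix(d[, prot_cols, drop = FALSE])
  rownames(npx) <- d$sample_id
  lod <- NULL
  if (!is.null(lod_path)) {
    l <- .read_table(lod_path)
    .require_columns(l, c("protein", "lod"), lod_path)
    l <- .check_numeric(l, "lod", lod_path)
    lod <- stats::setNames(l$lod, l$protein)
  }
  secretome_set(npx, d[, meta_cols, drop = FALSE], lod)
}

#' Write a secretome set back to NPX + LOD CSVs
#'
#' @param set a `secretome_set`.
#' @param path NPX CSV path.
#' @param lod_path LOD CSV path.
#' @return `path`, invisibly.
#' @export
write_npx <- function(set, path, lod_path) {
  df <- cbind(set$meta,
              as.data.frame(set$npx, check.names = FALSE))
  .write_table(df, path)
  .write_table(data.frame(protein = names(set$lod), lod = unname(set$lod),
                          stringsAsFactors = FALSE), lod_path)
  invisible(path)
}

#' Read an expression matrix (genes x samples)
#'
#' First column is the gene identifier, remaining columns one per
#' sample.
#'
#' @param path CSV path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  d <- .read_table(path)
  if (ncol(d) < 2) stop("parse error in ", path, ": need gene + samples")
  gene_col <- names(d)[1]
  if (anyDuplicated(d[[gene_col]]))
    stop("parse error in ", path, ": duplicate gene identifiers")
  d <- .check_numeric(d, names(d)[-1], path)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[gene_col]]
  m
}

#' Write an expression matrix
#' @param values genes x samples matrix.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(values, path) {
  df <- data.frame(gene = rownames(values),
                   as.data.frame(values, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_table(df, path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated;
#' fewer than 3 fields is a parse error.
#'
#' @param path GMT path.
#' @return named list of character gene vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("parse error in ", path, ", line ", i,
           ": GMT lines need name, description and at least one gene")
    if (f[1] %in% names(out))
      stop("parse error in ", path, ", line ", i,
           ": duplicate set name '", f[1], "'")
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' Write gene sets in GMT format
#' @param sigs named list of gene vectors.
#' @param path GMT path.
#' @param descriptions optional named descriptions (default "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sigs, path, descriptions = NULL) {
  lines <- vapply(names(sigs), function(nm) {
    desc <- if (!is.null(descriptions) && nm %in% names(descriptions))
      descriptions[[nm]] else "na"
    paste(c(nm, desc, sigs[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample response labels
#'
#' Schema: `sample_id, label` with labels MPR / NPR / unlabeled.
#'
#' @param path CSV path.
#' @return named character vector.
#' @export
read_labels <- function(path) {
  d <- .read_table(path)
  .require_columns(d, c("sample_id", "label"), path)
  bad <- setdiff(unique(d$label), c("MPR", "NPR", "unlabeled"))
  if (length(bad))
    stop("parse error in ", path, ": unknown label(s) ",
         paste(bad, collapse = ", "))
  stats::setNames(d$label, d$sample_id)
}

#' Write a result table as TSV
#' @param x data.frame.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) .write_table(x, path, sep = "\t")

#' Read a result table written by [write_tsv()]
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv <- function(path) .read_table(path, sep = "\t")
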