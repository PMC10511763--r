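# Core data container: a gene x sample matrix of log2 expression values with
# a dataset role tag.  Kept as a plain numeric matrix with dimnames plus two
# attributes so that all of base R's matrix algebra applies directly.

#' Construct an ExpressionMatrix
#'
#' A gene-by-sample numeric matrix of expression values on log2 scale (or raw
#' counts, see \code{scale_flag}), tagged with the role the dataset plays in
#' the harmonization pipeline: the raw dataset (R), the calibration dataset
#' (P) and its transformed versions (Pprime, Pdoubleprime), the reference
#' definitive dataset (Q), or the harmonized output (H).
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must have
#'   unique, non-empty rownames (gene ids) and colnames (sample ids).
#' @param role Dataset role, one of "R", "P", "Pprime", "Pdoubleprime",
#'   "Q", "H".
#' @param scale_flag Either "log2" (default) or "counts".
#' @return An \code{ExpressionMatrix}: a numeric matrix with attributes
#'   \code{role} and \code{scale_flag}.
#' @export
expression_matrix <- function(values, role = "R", scale_flag = "log2") {
  role <- match.arg(role, c("R", "P", "Pprime", "Pdoubleprime", "Q", "H"))
  scale_flag <- match.arg(scale_flag, c("log2", "counts"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(colnames(values)) || (nrow(values) > 0 &&
                                    is.null(rownames(values))))
    stop("'values' must carry gene rownames and sample colnames")
  if (nrow(values) == 0 && is.null(rownames(values)))
    rownames(values) <- character(0)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite expression values are not allowed")
  structure(values, role = role, scale_flag = scale_flag,
            class = c("ExpressionMatrix", class(matrix())))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [role %s, %s]: %d genes x %d samples\n",
              attr(x, "role"), attr(x, "scale_flag"), nrow(x), ncol(x)))
  invisible(x)
}

# Re-wrap a plain matrix that was derived from an ExpressionMatrix.
as_em <- function(values, role, scale_flag = "log2") {
  expression_matrix(as.matrix(values), role = role, scale_flag = scale_flag)
}

em_role <- function(x) attr(x, "role")

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row \code{gene<TAB>sample1<TAB>...} and one gene per row.
#' Duplicate gene rows are collapsed by the per-sample maximum (with a logged
#' warning); when \code{scale_flag = "counts"} values are transformed to
#' \code{log2(x + 1)} and the result is stored on log2 scale.
#'
#' @param path Path to a tab-separated file.
#' @param scale_flag "log2" (values stored as-is) or "counts"
#'   (log2(x+1)-transformed on load).
#' @param role Dataset role passed to \code{\link{expression_matrix}}.
#' @param impute_missing If TRUE, missing cells are replaced by the gene's
#'   mean over observed samples; the default (FALSE) rejects files with
#'   missing values.
#' @return An \code{ExpressionMatrix} (always on log2 scale).
#' @export
read_expression_tsv <- function(path, scale_flag = c("log2", "counts"),
                                role = "R", impute_missing = FALSE) {
  scale_flag <- match.arg(scale_flag)
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header in ", path,
         ": expected 'gene<TAB>sample...' with at least one sample column")
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample column name(s) in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  gene_ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(vals) == 0) {
    empty <- matrix(numeric(0), 0, length(sample_ids),
                    dimnames = list(character(0), sample_ids))
    return(expression_matrix(empty, role = role, scale_flag = "log2"))
  }
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 ncol = ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals) & !(vals %in% c("NA", "", "NaN")),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric cell at data row %d, column '%s' in %s: '%s'",
                 bad[1, 1], sample_ids[bad[1, 2]], path,
                 vals[bad[1, 1], bad[1, 2]]))
  dimnames(num) <- list(gene_ids, sample_ids)
  if (anyDuplicated(gene_ids)) {
    dups <- unique(gene_ids[duplicated(gene_ids)])
    shmb_log(sprintf("collapsing %d duplicated gene id(s) by per-sample max",
                     length(dups)), "warn")
    keep <- rownames(num)
    num <- do.call(rbind, lapply(unique(keep), function(g) {
      suppressWarnings(apply(num[keep == g, , drop = FALSE], 2, max,
                             na.rm = TRUE))
    }))
    rownames(num) <- unique(keep)
    num[!is.finite(num)] <- NA_real_
  }
  if (anyNA(num)) {
    if (!impute_missing) {
      i <- which(is.na(num), arr.ind = TRUE)[1, ]
      stop(sprintf("missing value at gene '%s', sample '%s' in %s %s",
                   rownames(num)[i[1]], colnames(num)[i[2]], path,
                   "(use impute_missing = TRUE to mean-impute)"))
    }
    for (r in which(rowSums(is.na(num)) > 0)) {
      m <- mean(num[r, ], na.rm = TRUE)
      if (!is.finite(m))
        stop("gene '", rownames(num)[r], "' has no observed values")
      num[r, is.na(num[r, ])] <- m
    }
    shmb_log("missing values mean-imputed per gene", "warn")
  }
  if (scale_flag == "counts") {
    if (any(num < 0))
      stop("negative values are not valid counts")
    num <- log2(num + 1)
  }
  expression_matrix(num, role = role, scale_flag = "log2")
}

#' Write an ExpressionMatrix to TSV
#'
#' Values are written with 12 significant digits so that a read/write
#' round trip reproduces the matrix to within 1e-9.
#'
#' @param matrix An \code{ExpressionMatrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(matrix)), collapse = "\t"), con)
  if (nrow(matrix) > 0) {
    body <- apply(unclass(matrix), 1, function(v)
      paste(format(v, digits = 12, scientific = TRUE, trim = TRUE),
            collapse = "\t"))
    writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a GCT 1.2 expression file
#'
#' Skips the two GCT header lines and ignores the Description column.
#'
#' @inheritParams read_expression_tsv
#' @return An \code{ExpressionMatrix}.
#' @export
read_expression_gct <- function(path, scale_flag = c("log2", "counts"),
                                role = "R") {
  scale_flag <- match.arg(scale_flag)
  lines <- readLines(path)
  if (length(lines) < 3 || !grepl("^#1\\.2", lines[1]))
    stop("not a GCT 1.2 file: ", path)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  # drop the Description column (position 2)
  body <- vapply(lines[-(1:3)], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    paste(f[-2], collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  writeLines(c(paste(c("gene", header[-(1:2)]), collapse = "\t"), body), tmp)
  read_expression_tsv(tmp, scale_flag = scale_flag, role = role)
}

#' Read a sample annotation table
#'
#' TSV with columns \code{sample_id}, \code{tissue_type}, \code{platform}
#' and an optional \code{group} ("case"/"control"); extra columns are kept.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with one row per sample.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param df A data.frame to validate as a sample table.
#' @export
validate_sample_table <- function(df) {
  need <- c("sample_id", "tissue_type", "platform")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if ("group" %in% names(df)) {
    bad <- setdiff(unique(stats::na.omit(df$group)), c("case", "control"))
    if (length(bad))
      stop("invalid group value(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Per-gene mean and standard deviation summaries
#'
#' Computes, for every gene of a dataset, the mean and the sample (n-1
#' denominator) standard deviation of its log-expression values.  These are
#' the per-gene location/scale summaries the rescaling modes consume
#' (e.g. mu_gQ / sigma_gQ for the reference definitive dataset).
#'
#' @param matrix An \code{ExpressionMatrix} with at least 2 samples.
#' @return A \code{GeneSummary}: data.frame with columns \code{gene},
#'   \code{mu}, \code{sigma} and attribute \code{source_role}.
#' @export
gene_summaries <- function(matrix) {
  if (ncol(matrix) < 2)
    stop("gene_summaries: need >= 2 samples (sigma undefined for ",
         ncol(matrix), " sample)")
  x <- unclass(matrix)
  out <- data.frame(gene = rownames(x), mu = rowMeans(x), sigma = row_sds(x),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, source_role = attr(matrix, "role"),
            class = c("GeneSummary", "data.frame"))
}
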