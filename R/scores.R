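# Case-vs-control derivative scores.  Per-gene log fold change (LFC) feeds
# role-weighted pathway activation levels (PAL), which combine with target
# gene LFCs into a balanced drug efficiency score (BES) whose positive sign
# predicts potential drug benefit.  The PAL/BES aggregation formulas are
# documented package defaults behind this module's interface; the sign
# conventions and the pathway-plus-targets structure are fixed.

#' Read a pathway database (extended GMT)
#'
#' Format: \code{pathway<TAB>description<TAB>gene:role<TAB>...} with role
#' +1 (activator) or -1 (repressor).  Plain GMT (\code{gene} without
#' \code{:role}) is accepted, with role defaulting to +1.
#'
#' @param path Path to the GMT file.
#' @return List of class \code{PathwayDB}: per pathway a data.frame with
#'   columns \code{gene}, \code{role}.
#' @export
read_pathway_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty pathway database: ", path)
  pws <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line (need pathway, description, >=1 member): ", l)
    members <- f[-(1:2)]
    has_role <- grepl(":", members, fixed = TRUE)
    gene <- ifelse(has_role, sub(":[^:]*$", "", members), members)
    role <- ifelse(has_role, as.numeric(sub("^.*:", "", members)), 1)
    if (any(!is.finite(role) | role == 0))
      stop("invalid role weight in pathway '", f[1], "'")
    data.frame(gene = gene, role = role, stringsAsFactors = FALSE)
  })
  names(pws) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(pws)))
    stop("duplicated pathway id(s) in ", path)
  structure(pws, class = "PathwayDB")
}

#' Write a pathway database in the extended GMT dialect
#' @param db A \code{PathwayDB}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_pathway_gmt <- function(db, path) {
  lines <- vapply(names(db), function(p) {
    paste(c(p, "synthetic pathway",
            sprintf("%s:%+d", db[[p]]$gene, as.integer(db[[p]]$role))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug-target database
#'
#' TSV with columns \code{drug}, \code{targets} (comma-separated gene ids)
#' and \code{pathways} (comma-separated pathway ids, may be empty).
#'
#' @param path Path to the TSV.
#' @return List of class \code{DrugTargetDB}: per drug a list with
#'   \code{targets} and \code{pathways}.
#' @export
read_drug_db <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = NULL)
  need <- c("drug", "targets", "pathways")
  if (!all(need %in% names(df)))
    stop("drug database needs columns: ", paste(need, collapse = ", "))
  split_field <- function(s) {
    out <- strsplit(s, ",", fixed = TRUE)[[1]]
    out[nzchar(out)]
  }
  drugs <- lapply(seq_len(nrow(df)), function(i) {
    tg <- split_field(df$targets[i])
    if (!length(tg)) stop("drug '", df$drug[i], "' has no target genes")
    list(targets = tg, pathways = split_field(df$pathways[i]))
  })
  names(drugs) <- df$drug
  if (anyDuplicated(names(drugs))) stop("duplicated drug id(s) in ", path)
  structure(drugs, class = "DrugTargetDB")
}

#' Write a drug-target database
#' @param db A \code{DrugTargetDB}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_drug_db <- function(db, path) {
  lines <- c("drug\ttargets\tpathways",
             vapply(names(db), function(d) {
               paste(d, paste(db[[d]]$targets, collapse = ","),
                     paste(db[[d]]$pathways, collapse = ","), sep = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

score_vector <- function(ids, values, level) {
  if (anyDuplicated(ids)) stop("duplicated score ids")
  if (any(!is.finite(values))) stop("non-finite score values")
  structure(list(level = level, ids = ids, values = stats::setNames(values,
                                                                    ids)),
            class = "ScoreVector")
}

#' Case-to-control log fold change per gene
#'
#' \code{LFC_g = case log2 value - aggregated control log2 value}, with the
#' control aggregate being the per-gene median (default) or mean.
#'
#' @param case Named numeric vector (one sample's log2 profile) or a
#'   single-column \code{ExpressionMatrix}.
#' @param controls \code{ExpressionMatrix} of control samples over the same
#'   gene list.
#' @param aggregate "median" or "mean".
#' @return \code{ScoreVector} with level "gene_LFC".
#' @export
log_fold_change <- function(case, controls, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.matrix(case)) {
    if (ncol(case) != 1) stop("'case' must be a single profile")
    case <- stats::setNames(as.numeric(case), rownames(case))
  }
  if (!identical(names(case), rownames(controls)))
    stop("case and controls must share an identical gene list")
  ref <- if (aggregate == "median") {
    apply(unclass(controls), 1, stats::median)
  } else rowMeans(unclass(controls))
  score_vector(names(case), as.numeric(case) - ref, "gene_LFC")
}

#' Pathway activation levels from gene LFCs
#'
#' For every pathway p, \code{PAL_p = sum(role_g * LFC_g) / sum(|role_g|)}
#' over the pathway members present in the LFC vector (the "surviving"
#' genes).  Pathways with no surviving member are dropped with a warning.
#'
#' @param lfc \code{ScoreVector} of level "gene_LFC".
#' @param db \code{PathwayDB}.
#' @return \code{ScoreVector} with level "pathway_PAL".
#' @export
pathway_activation <- function(lfc, db) {
  if (!length(db)) stop("empty pathway database")
  vals <- vapply(db, function(pw) {
    keep <- pw$gene %in% lfc$ids
    if (!any(keep)) return(NA_real_)
    w <- pw$role[keep]
    sum(w * lfc$values[pw$gene[keep]]) / sum(abs(w))
  }, numeric(1))
  if (anyNA(vals)) {
    shmb_log(sprintf("pathway_activation: dropping %d pathway(s) with no %s",
                     sum(is.na(vals)), "surviving member"), "warn")
    vals <- vals[!is.na(vals)]
  }
  if (!length(vals)) stop("no pathway has surviving members")
  score_vector(names(vals), unname(vals), "pathway_PAL")
}

#' Balanced drug efficiency scores
#'
#' \code{BES_d = 1/2 * mean(PAL of linked pathways) + 1/2 * mean(LFC of
#' target genes)}.  Positive BES predicts a potentially beneficial drug,
#' negative a harmful one.  Drugs with no surviving target gene are not
#' scored (reported in the \code{unscored} attribute); drugs whose linked
#' pathways all dropped out fall back to the target-gene term alone.
#'
#' @param pal \code{ScoreVector} of level "pathway_PAL".
#' @param lfc \code{ScoreVector} of level "gene_LFC".
#' @param db \code{DrugTargetDB}.
#' @return \code{ScoreVector} with level "drug_BES" (attribute
#'   \code{unscored} lists drugs with no surviving targets).
#' @export
drug_efficiency <- function(pal, lfc, db) {
  res <- lapply(names(db), function(d) {
    tg <- intersect(db[[d]]$targets, lfc$ids)
    if (!length(tg)) return(NULL)
    gene_term <- mean(lfc$values[tg])
    pw <- intersect(db[[d]]$pathways, pal$ids)
    if (!length(pw)) {
      shmb_log(sprintf("drug '%s': no linked pathways, target term only", d),
               "debug")
      return(gene_term)
    }
    0.5 * mean(pal$values[pw]) + 0.5 * gene_term
  })
  names(res) <- names(db)
  unscored <- names(res)[vapply(res, is.null, logical(1))]
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(unscored))
    shmb_log(sprintf("drug_efficiency: %d drug(s) without surviving targets",
                     length(unscored)), "warn")
  if (!length(res)) stop("no drug has surviving target genes")
  out <- score_vector(names(res), unlist(res), "drug_BES")
  attr(out, "unscored") <- unscored
  out
}

#' Database coverage after gene filtering
#'
#' Reports, for every drug, whether all target genes survived harmonization
#' and the surviving fraction; and for every pathway, the surviving fraction
#' and whether it is strictly above 75%.
#'
#' @param db A \code{DrugTargetDB} or \code{PathwayDB}.
#' @param surviving_genes Character vector of surviving gene ids.
#' @return List with a per-entry data.frame \code{table} and global
#'   percentages (\code{pct_genes_survived}, \code{pct_entries_ok}).
#' @export
target_survival_report <- function(db, surviving_genes) {
  if (inherits(db, "DrugTargetDB")) {
    tab <- do.call(rbind, lapply(names(db), function(d) {
      tg <- db[[d]]$targets
      frac <- mean(tg %in% surviving_genes)
      data.frame(id = d, n_genes = length(tg), fraction = frac,
                 all_survived = frac == 1, stringsAsFactors = FALSE)
    }))
    ok <- tab$all_survived
  } else if (inherits(db, "PathwayDB")) {
    tab <- do.call(rbind, lapply(names(db), function(p) {
      g <- db[[p]]$gene
      frac <- mean(g %in% surviving_genes)
      data.frame(id = p, n_genes = length(g), fraction = frac,
                 over_75 = frac > 0.75, stringsAsFactors = FALSE)
    }))
    ok <- tab$over_75
  } else stop("db must be a DrugTargetDB or a PathwayDB")
  all_genes <- unique(unlist(lapply(db, function(e)
    if (!is.null(e$targets)) e$targets else e$gene)))
  list(table = tab,
       pct_genes_survived = 100 * mean(all_genes %in% surviving_genes),
       pct_entries_ok = 100 * mean(ok))
}

#' Rank drugs by BES
#'
#' @param bes \code{ScoreVector} of level "drug_BES".
#' @param top_n Number of drugs to return (clamped to the available count).
#' @return Character vector of drug ids, BES descending, ties broken
#'   lexicographically.
#' @export
rank_drugs <- function(bes, top_n = 10) {
  if (top_n < 1) stop("top_n must be >= 1")
  ord <- order(-bes$values, bes$ids)
  bes$ids[ord][seq_len(min(top_n, length(ord)))]
}
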