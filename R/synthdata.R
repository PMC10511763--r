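# Seeded generator of multi-platform, multi-tissue bulk expression data.
# The generator emulates the statistical structure the harmonizer and its
# metrics assume: a shared tissue signal across platforms, a monotone
# nonlinear platform distortion (cubic in the per-gene z-score, preserving
# within-sample ranks), per-gene platform bias, a low-expression gene tail,
# Poisson count rendering for sequencing-like platforms, and planted
# case-vs-control pathway shifts whose signs are knowable in advance.

#' Synthetic benchmark configuration
#'
#' @param n_tissues Number of tissue types.
#' @param genes Number of genes (>= 100).
#' @param n Control samples per tissue per platform (>= 3).
#' @param tau Tissue-effect sd in log2 units, applied to the
#'   tissue-informative genes.
#' @param tissue_frac Fraction of genes carrying tissue signal (tissue
#'   signatures are sparse; the rest of the transcriptome is
#'   tissue-invariant).
#' @param sigma_b Per-sample biological noise sd in log2 units
#'   (within-tissue heterogeneity between donors).
#' @param platforms Named list; each platform is a list with monotone cubic
#'   response-curve coefficients \code{a}, \code{b} (value u on the
#'   standardized measurement scale maps to a u^3 + b u), per-gene platform
#'   bias sd \code{lambda}, and a \code{counts} flag (render through
#'   Poisson counts).
#' @param sigma_e Measurement noise sd (log2 units).
#' @param low_fraction Fraction of genes in the low-expression tail.
#' @param p_top_fraction Fraction of genes (top by baseline mean) retained
#'   in the calibration dataset P.
#' @param n_aux Samples in each auxiliary dataset (P and Q).
#' @param n_cases Case samples (with planted shifts) per platform, drawn
#'   from the first tissue; matched controls are that tissue's samples.
#' @param n_pathways,pathway_size Pathway fixture dimensions.
#' @param n_shifted Number of pathways receiving a planted case shift.
#' @param delta Planted shift magnitude in log2 units.
#' @param n_drugs Drug fixture count.
#' @param seed Master integer seed.
#' @return Validated list of class \code{SyntheticConfig}.
#' @export
synthetic_config <- function(n_tissues = 4, genes = 3000, n = 14,
                             tau = 0.75, tissue_frac = 0.08, sigma_b = 1.1,
                             platforms = list(
                               rnaseq = list(a = 0, b = 1, lambda = 0.1,
                                             counts = TRUE),
                               microarray = list(a = 0.6, b = 0.4,
                                                 lambda = 0.1,
                                                 counts = FALSE)),
                             sigma_e = 0.3, low_fraction = 0.3,
                             p_top_fraction = 0.7, n_aux = 24, n_cases = 10,
                             n_pathways = 20, pathway_size = c(5, 12),
                             n_shifted = 6, delta = 2, n_drugs = 15,
                             seed = 1L) {
  cfg <- mget(names(formals()))
  stopifnot(genes >= 100, n >= 3, tau >= 0, sigma_e >= 0, sigma_b >= 0,
            tissue_frac > 0, tissue_frac <= 1,
            low_fraction >= 0, low_fraction < 1, n_tissues >= 2,
            length(platforms) >= 1, p_top_fraction > 0, p_top_fraction <= 1,
            n_shifted <= n_pathways)
  for (p in platforms)
    stopifnot(is.numeric(p$a), is.numeric(p$b), p$lambda >= 0,
              is.logical(p$counts))
  structure(cfg, class = "SyntheticConfig")
}

# Deterministic shared structure: baselines, tissue offsets, pathway and
# drug memberships, planted-shift ledger.  Every generate_* call rebuilds
# the same blueprint from the config seed so fixtures stay consistent.
synth_blueprint <- function(config) {
  with_seed(sample_seed(config$seed, "blueprint"), {
    G <- config$genes
    gene_ids <- sprintf("G%04d", seq_len(G))
    n_low <- round(config$low_fraction * G)
    low <- seq_len(G) <= n_low          # deterministic tail membership
    baseline <- ifelse(low, stats::rnorm(G, 3, 1), stats::rnorm(G, 8, 2))
    names(baseline) <- gene_ids
    tissues <- sprintf("tissue%d", seq_len(config$n_tissues))
    # sparse tissue signatures: only a fraction of genes vary by tissue
    informative <- sample(G, round(config$tissue_frac * G))
    offsets <- matrix(0, G, config$n_tissues,
                      dimnames = list(gene_ids, tissues))
    offsets[informative, ] <- stats::rnorm(
      length(informative) * config$n_tissues, 0, config$tau)
    # pathways: disjoint member sets drawn from genes that are both in the
    # high-expression component and inside the calibration dataset's
    # top-fraction gene list, so every member survives harmonization
    p_keep <- names(sort(baseline, decreasing = TRUE))[
      seq_len(round(config$p_top_fraction * G))]
    pool <- sample(intersect(gene_ids[!low], p_keep))
    sizes <- sample(seq(config$pathway_size[1], config$pathway_size[2]),
                    config$n_pathways, replace = TRUE)
    if (sum(sizes) > length(pool))
      stop("not enough strongly expressed genes for the pathway fixtures")
    stops <- cumsum(sizes)
    pdb <- lapply(seq_len(config$n_pathways), function(i) {
      g <- pool[(stops[i] - sizes[i] + 1):stops[i]]
      data.frame(gene = g,
                 role = sample(c(1, -1), length(g), replace = TRUE,
                               prob = c(0.7, 0.3)),
                 stringsAsFactors = FALSE)
    })
    names(pdb) <- sprintf("PW%02d", seq_len(config$n_pathways))
    class(pdb) <- "PathwayDB"
    shifted <- names(pdb)[seq_len(config$n_shifted)]
    shift_sign <- stats::setNames(rep(c(1, -1),
                                      length.out = config$n_shifted),
                                  shifted)
    # per-gene case shift: delta * pathway sign * member role
    gene_shift <- stats::setNames(numeric(G), gene_ids)
    for (p in shifted) {
      gene_shift[pdb[[p]]$gene] <- config$delta * shift_sign[[p]] *
        pdb[[p]]$role
    }
    ddb <- lapply(seq_len(config$n_drugs), function(i) {
      pw <- sample(names(pdb), sample(1:2, 1))
      tg <- unique(unlist(lapply(pdb[pw], function(x)
        sample(x$gene, min(2, nrow(x))))))
      list(targets = tg[seq_len(min(3, length(tg)))], pathways = pw)
    })
    names(ddb) <- sprintf("DR%02d", seq_len(config$n_drugs))
    class(ddb) <- "DrugTargetDB"
    list(gene_ids = gene_ids, baseline = baseline, offsets = offsets,
         tissues = tissues, low = low, pathways = pdb, drugs = ddb,
         shifted = shifted, shift_sign = shift_sign,
         gene_shift = gene_shift)
  })
}

# Render a matrix of per-tissue mean signals through one platform's
# measurement model: add per-sample biological noise (each platform's
# samples are distinct donors), pass the values through the platform's
# monotone cubic response curve (a global warp of the measurement scale,
# emulating e.g. microarray saturation versus linear sequencing response —
# the kind of distortion a per-sample quantile-based harmonizer is designed
# to remove), add per-gene platform bias (probe-affinity-like, deliberately
# NOT removable one sample at a time) and measurement noise, and optionally
# render through Poisson counts.
render_platform <- function(signal, pl, sigma_b, sigma_e, seed) {
  G <- nrow(signal)
  with_seed(seed, {
    signal <- signal + matrix(stats::rnorm(length(signal), 0, sigma_b), G)
    m <- mean(signal)
    v <- stats::sd(signal)
    if (!is.finite(v) || v == 0) v <- 1
    u <- (signal - m) / v
    bias <- stats::rnorm(G, 0, pl$lambda)
    y <- m + v * (pl$a * u^3 + pl$b * u) + bias +
      matrix(stats::rnorm(length(signal), 0, sigma_e), G)
    if (isTRUE(pl$counts)) {
      lam <- 2^pmin(y, 30)
      y <- log2(matrix(stats::rpois(length(lam), pmax(lam, 0)), G) + 1)
    }
    dimnames(y) <- dimnames(signal)
    y
  })
}

#' Generate multi-platform, multi-tissue expression matrices
#'
#' Per-gene baselines come from a two-component (high/low expression)
#' mixture; tissue offsets are shared across platforms; each platform
#' renders the per-gene standardized signal through its own monotone cubic
#' distortion plus per-gene bias and noise (Poisson counts for
#' sequencing-like platforms).  Case samples of the first tissue carry the
#' planted pathway shifts.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return List with \code{matrices} (one \code{ExpressionMatrix} per
#'   platform), and \code{truth} (annotations data.frame, per-gene
#'   baselines, planted-shift ledger).
#' @export
generate_multiplatform <- function(config = synthetic_config()) {
  bp <- synth_blueprint(config)
  mats <- list()
  anns <- list()
  for (pn in names(config$platforms)) {
    pl <- config$platforms[[pn]]
    ids <- c(); tis <- c(); grp <- c()
    for (t in seq_along(bp$tissues)) {
      ids <- c(ids, sprintf("%s_%s_c%02d", pn, bp$tissues[t],
                            seq_len(config$n)))
      tis <- c(tis, rep(bp$tissues[t], config$n))
      grp <- c(grp, rep("control", config$n))
    }
    if (config$n_cases > 0) {
      ids <- c(ids, sprintf("%s_%s_case%02d", pn, bp$tissues[1],
                            seq_len(config$n_cases)))
      tis <- c(tis, rep(bp$tissues[1], config$n_cases))
      grp <- c(grp, rep("case", config$n_cases))
    }
    signal <- bp$baseline + bp$offsets[, tis, drop = FALSE]
    signal <- signal + outer(bp$gene_shift, as.numeric(grp == "case"))
    colnames(signal) <- ids
    y <- render_platform(signal, pl, config$sigma_b, config$sigma_e,
                         sample_seed(config$seed, paste0("platform:", pn)))
    mats[[pn]] <- expression_matrix(y, role = "R")
    anns[[pn]] <- data.frame(sample_id = ids, tissue_type = tis,
                             platform = pn, group = grp,
                             stringsAsFactors = FALSE)
  }
  truth <- list(annotations = do.call(rbind, anns),
                baseline = bp$baseline,
                ledger = list(shifted_pathways = bp$shifted,
                              shift_sign = bp$shift_sign,
                              delta = config$delta,
                              gene_shift = bp$gene_shift[bp$gene_shift != 0]))
  rownames(truth$annotations) <- NULL
  list(matrices = mats, truth = truth)
}

#' Generate the auxiliary calibration (P) and reference definitive (Q)
#' datasets
#'
#' P emulates a microarray-like platform with a compressed dynamic range
#' and a restricted gene list (top fraction of genes by baseline mean,
#' mirroring a calibration set of the most strongly expressed genes); Q is
#' count-rendered over the full gene list.  Both span all tissues with
#' control samples only.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return List with \code{P} and \code{Q} \code{ExpressionMatrix} objects.
#' @export
generate_auxiliary <- function(config = synthetic_config()) {
  bp <- synth_blueprint(config)
  per_tissue <- ceiling(config$n_aux / config$n_tissues)
  tis <- rep(bp$tissues, each = per_tissue)[seq_len(
    max(config$n_aux, config$n_tissues))]
  make <- function(tag, pl, genes) {
    ids <- sprintf("%s_%s_a%02d", tag, tis, seq_along(tis))
    signal <- (bp$baseline + bp$offsets[, tis, drop = FALSE])[genes, ,
                                                              drop = FALSE]
    colnames(signal) <- ids
    render_platform(signal, pl, config$sigma_b, config$sigma_e,
                    sample_seed(config$seed, paste0("aux:", tag)))
  }
  n_keep <- round(config$p_top_fraction * config$genes)
  p_genes <- names(sort(bp$baseline, decreasing = TRUE))[seq_len(n_keep)]
  p_genes <- p_genes[order(match(p_genes, bp$gene_ids))]
  P <- make("P", list(a = 0.05, b = 0.7, lambda = 0.3, counts = FALSE),
            p_genes)
  Q <- make("Q", list(a = 0, b = 1, lambda = 0.15, counts = TRUE),
            bp$gene_ids)
  list(P = expression_matrix(P, role = "P"),
       Q = expression_matrix(Q, role = "Q"))
}

#' Generate pathway and drug fixtures consistent with the planted shifts
#'
#' The returned databases use the synthetic gene ids and are
#' ledger-consistent with \code{\link{generate_multiplatform}}: a pathway
#' listed in the truth ledger with planted sign s is expected to show
#' \code{sign(PAL) == s} in case-vs-control scoring.
#'
#' @param config A \code{\link{synthetic_config}}.
#' @return List with \code{pathways} (\code{PathwayDB}), \code{drugs}
#'   (\code{DrugTargetDB}), \code{shifted}, \code{shift_sign}.
#' @export
generate_pathway_fixtures <- function(config = synthetic_config()) {
  bp <- synth_blueprint(config)
  list(pathways = bp$pathways, drugs = bp$drugs, shifted = bp$shifted,
       shift_sign = bp$shift_sign)
}
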