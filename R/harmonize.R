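# The uniformly shaped harmonization pipeline.  Each raw profile is (1)
# quantile-normalized together with the calibration dataset P, (2) mapped
# into the shape of the reference definitive dataset Q by a block transform
# (block-linear for method "shambhala1", piecewise-cubic for "shambhala2"),
# and (3) rescaled per gene by one of three modes (PBR/QBR/RBR).

#' Harmonization configuration
#'
#' @param method "shambhala1" (block-linear XPN-style transform) or
#'   "shambhala2" (piecewise-cubic CuBlock-style transform).
#' @param rescale_mode "PBR", "QBR" or "RBR"; see \code{\link{rescale}}.
#' @param xpn_params List with elements \code{K} (gene clusters, >= 2),
#'   \code{L} (sample clusters, >= 2), \code{n_repeats}, \code{max_iter},
#'   \code{tol}.
#' @param cublock_params List with elements \code{B} (number of gene blocks,
#'   >= 1), \code{poly_degree} (fixed at 3) and \code{clamp} (enforce a
#'   monotone fitted map).
#' @param seed Master integer seed; all stochastic steps derive from it.
#' @param sigma_floor Smallest admissible per-gene sd; genes below it map to
#'   the target mean during rescaling.
#' @return A validated list of class \code{HarmonizationConfig}.
#' @export
harmonization_config <- function(method = c("shambhala2", "shambhala1"),
                                 rescale_mode = c("PBR", "QBR", "RBR"),
                                 xpn_params = list(K = 25, L = 5,
                                                   n_repeats = 30,
                                                   max_iter = 50, tol = 1e-6),
                                 cublock_params = list(B = 8, poly_degree = 3,
                                                       clamp = TRUE),
                                 seed = 1L, sigma_floor = 1e-8) {
  method <- match.arg(method)
  rescale_mode <- match.arg(rescale_mode)
  xd <- list(K = 25, L = 5, n_repeats = 30, max_iter = 50, tol = 1e-6)
  xd[names(xpn_params)] <- xpn_params
  cd <- list(B = 8, poly_degree = 3, clamp = TRUE)
  cd[names(cublock_params)] <- cublock_params
  stopifnot(xd$K >= 2, xd$L >= 2, xd$n_repeats >= 1, cd$B >= 1,
            cd$poly_degree == 3, sigma_floor > 0)
  structure(list(method = method, rescale_mode = rescale_mode,
                 xpn_params = xd, cublock_params = cd,
                 seed = as.integer(seed), sigma_floor = sigma_floor),
            class = "HarmonizationConfig")
}

#' Intersect gene lists of the raw, calibration and reference datasets
#'
#' The harmonized output only contains genes present in all three datasets;
#' because the calibration dataset is restricted to strongly expressed genes,
#' this intersection acts as an implicit expression filter.  An optional
#' explicit top-N filter (by median expression in P) is available.
#'
#' @param R,P,Q \code{ExpressionMatrix} objects.
#' @param top_n Optional integer: keep only the top-N genes of the
#'   intersection ranked by median expression in P.
#' @return Sorted character vector of shared gene ids.
#' @export
intersect_and_filter_genes <- function(R, P, Q, top_n = NULL) {
  genes <- sort(intersect(intersect(rownames(R), rownames(P)), rownames(Q)))
  if (length(genes) == 0)
    stop("empty gene intersection between R, P and Q; check that all three ",
         "datasets use the same gene identifier namespace")
  if (!is.null(top_n) && top_n < length(genes)) {
    med <- apply(unclass(P)[genes, , drop = FALSE], 1, stats::median)
    genes <- sort(names(sort(med, decreasing = TRUE))[seq_len(top_n)])
  }
  genes
}

#' Quantile normalization
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the across-sample mean of sorted value vectors.  Within-sample ranks are
#' preserved; ties receive the mean of the tied reference values.
#' Delegates to \code{limma::normalizeQuantiles}.
#'
#' @param matrix An \code{ExpressionMatrix} with >= 2 samples (a single
#'   sample is returned unchanged with a warning).
#' @return The quantile-normalized \code{ExpressionMatrix}.
#' @export
quantile_normalize <- function(matrix) {
  if (ncol(matrix) < 2) {
    warning("quantile_normalize: single sample, returning input unchanged")
    return(matrix)
  }
  out <- limma::normalizeQuantiles(unclass(matrix), ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  as_em(out, role = attr(matrix, "role"))
}

# XPN-style block-linear transform ---------------------------------------

# Fit x_gi ~ A[alpha(g), beta(i)] * b_g + c_g + sigma_g * eps by iterated
# least squares on a per-gene standardized matrix.  Gauge: b has unit mean
# square within each gene cluster, with mean(b) >= 0.
xpn_fit <- function(x, alpha, beta, K, L, max_iter, tol) {
  G <- nrow(x); n <- ncol(x)
  b <- rep(1, G); c0 <- rowMeans(x)
  A <- matrix(0, K, L)
  n_l <- tabulate(beta, L)
  for (it in seq_len(max_iter)) {
    A_old <- A
    # A given b, c
    resid <- x - c0
    for (k in seq_len(K)) {
      gk <- which(alpha == k)
      if (!length(gk)) next
      bk2 <- sum(b[gk]^2)
      for (l in seq_len(L)) {
        il <- which(beta == l)
        if (!length(il) || bk2 == 0) { A[k, l] <- 0; next }
        A[k, l] <- sum(resid[gk, il, drop = FALSE] * b[gk]) / (bk2 * n_l[l])
      }
    }
    # b, c given A: per gene simple regression of x_g. on a_i = A[alpha(g), beta(.)]
    a_rows <- A[alpha, beta, drop = FALSE]      # G x n matrix of regressors
    am <- rowMeans(a_rows)
    av <- rowSums((a_rows - am)^2)
    xm <- rowMeans(x)
    cov_xa <- rowSums((a_rows - am) * (x - xm))
    b <- ifelse(av > 1e-12, cov_xa / av, 0)
    c0 <- xm - b * am
    # gauge fix per gene cluster
    for (k in seq_len(K)) {
      gk <- which(alpha == k)
      if (!length(gk)) next
      s <- sqrt(mean(b[gk]^2))
      if (s > 1e-12) {
        sg <- if (mean(b[gk]) < 0) -1 else 1
        b[gk] <- b[gk] / (s * sg)
        A[k, ] <- A[k, ] * s * sg
      }
    }
    if (max(abs(A - A_old)) < tol) break
  }
  fit <- A[alpha, beta, drop = FALSE] * b + c0
  res <- x - fit
  sigma <- sqrt(pmax(rowSums(res^2) / max(n - 1, 1), 0))
  list(A = A, b = b, c = c0, sigma = sigma, resid = res)
}

#' Block-linear (XPN-style) transform of P' toward the shape of Q
#'
#' Genes are clustered into K groups and samples into L groups by k-means on
#' per-gene standardized data of the combined set.  A block-linear model
#' \code{x_gi ~ A[gene block, sample block] * b_g + c_g + sigma_g * eps} is
#' fitted to each dataset's standardized values by iterated least squares;
#' the dataset-specific parameters are replaced by their cross-dataset
#' weighted averages (weights = sample counts) and P' is reconstructed under
#' the shared parameters, then restored to Q's per-gene scale so that the
#' output is expressed in the format of the reference definitive dataset.
#' Results are averaged over \code{n_repeats} random clustering restarts.
#'
#' @param Pprime,Q \code{ExpressionMatrix} objects over an identical gene
#'   list.
#' @param params List as \code{xpn_params} of
#'   \code{\link{harmonization_config}}.
#' @param seed Integer seed for the clustering restarts.
#' @param sigma_floor Guard for near-zero residual scale.
#' @return \code{ExpressionMatrix} (role Pdoubleprime) with the columns of
#'   \code{Pprime} transformed; dimensions equal \code{dim(Pprime)}.
#' @export
xpn_transform <- function(Pprime, Q, params = list(), seed = 1L,
                          sigma_floor = 1e-8) {
  pd <- list(K = 25, L = 5, n_repeats = 30, max_iter = 50, tol = 1e-6)
  pd[names(params)] <- params
  if (!identical(rownames(Pprime), rownames(Q)))
    stop("Pprime and Q must share an identical gene list")
  G <- nrow(Pprime); n1 <- ncol(Pprime); n2 <- ncol(Q)
  K <- pd$K; L <- pd$L
  if (K > G) stop("K = ", K, " gene clusters exceed ", G, " genes")
  if (L > n1 + n2) stop("L exceeds the number of available samples")
  if (min(n1, n2) < max(L, 3))
    stop("each dataset needs at least max(L, 3) samples")
  std <- function(x) {
    m <- rowMeans(x); s <- pmax(row_sds(x), sigma_floor)
    list(z = (x - m) / s, mu = m, sigma = s)
  }
  s1 <- std(unclass(Pprime)); s2 <- std(unclass(Q))
  z <- cbind(s1$z, s2$z)
  is_p <- c(rep(TRUE, n1), rep(FALSE, n2))
  acc <- matrix(0, G, n1)
  with_seed(seed, {
    for (rep_i in seq_len(pd$n_repeats)) {
      alpha <- stats::kmeans(z, centers = K, nstart = 1,
                             iter.max = 30)$cluster
      beta <- stats::kmeans(t(z), centers = L, nstart = 1,
                            iter.max = 30)$cluster
      f1 <- xpn_fit(s1$z, alpha, beta[is_p], K, L, pd$max_iter, pd$tol)
      f2 <- xpn_fit(s2$z, alpha, beta[!is_p], K, L, pd$max_iter, pd$tol)
      w1 <- n1 / (n1 + n2); w2 <- n2 / (n1 + n2)
      # blocks with no samples on one side fall back to the other side
      A1 <- f1$A; A2 <- f2$A
      seen1 <- outer(tabulate(alpha, K) > 0, tabulate(beta[is_p], L) > 0)
      seen2 <- outer(tabulate(alpha, K) > 0, tabulate(beta[!is_p], L) > 0)
      Ast <- ifelse(seen1 & seen2, w1 * A1 + w2 * A2,
                    ifelse(seen1, A1, A2))
      bst <- w1 * f1$b + w2 * f2$b
      cst <- w1 * f1$c + w2 * f2$c
      sst <- sqrt(w1 * f1$sigma^2 + w2 * f2$sigma^2)
      eps <- f1$resid / pmax(f1$sigma, sigma_floor)
      acc <- acc + Ast[alpha, beta[is_p], drop = FALSE] * bst + cst +
        sst * eps
    }
  })
  zstar <- acc / pd$n_repeats
  out <- s2$mu + s2$sigma * zstar      # restore to Q's per-gene scale
  dimnames(out) <- dimnames(Pprime)
  as_em(out, role = "Pdoubleprime")
}

# CuBlock-style piecewise-cubic transform ---------------------------------

# Fit y ~ poly(x, 3) on matched quantile grids; degrade to linear when the
# block is too small; optionally clamp to the monotone envelope.
cublock_block_map <- function(xvals, yvals, degree = 3, clamp = TRUE,
                              n_grid = 500) {
  m <- min(n_grid, length(xvals), length(yvals))
  p <- (seq_len(m) - 0.5) / m
  xq <- stats::quantile(xvals, p, names = FALSE, type = 7)
  yq <- stats::quantile(yvals, p, names = FALSE, type = 7)
  deg <- if (length(xvals) < 8 || length(unique(xq)) < 4) 1L else degree
  if (deg < degree)
    shmb_log("cublock: small block, falling back to linear fit", "warn")
  co <- stats::coef(stats::lm(yq ~ stats::poly(xq, degree = deg, raw = TRUE)))
  co[is.na(co)] <- 0
  f <- function(v) {
    out <- co[1]
    for (d in seq_len(deg)) out <- out + co[d + 1] * v^d
    out
  }
  fitted <- f(xvals)
  if (clamp && deg == 3) {
    o <- order(xvals)
    fo <- fitted[o]
    if (any(diff(fo) < 0)) {
      fitted[o] <- cummax(fo)   # monotone envelope over the observed range
    }
  }
  fitted
}

#' Piecewise-cubic (CuBlock-style) transform of P' toward the shape of Q
#'
#' Both datasets are per-gene z-scored; genes of the combined standardized
#' data are clustered into B blocks by k-means.  Within each block a cubic
#' polynomial mapping the empirical quantiles of P' onto those of Q is
#' fitted by least squares and applied to P' values; Q is the fixed
#' reference and is never modified.  The transformed standardized values are
#' restored to Q's per-gene scale.
#'
#' @param Pprime,Q \code{ExpressionMatrix} objects over an identical gene
#'   list.
#' @param params List as \code{cublock_params} of
#'   \code{\link{harmonization_config}}.
#' @param seed Integer seed (k-means block assignment).
#' @param sigma_floor Guard for zero-variance genes.
#' @return \code{ExpressionMatrix} (role Pdoubleprime), same shape as
#'   \code{Pprime}.
#' @export
cublock_transform <- function(Pprime, Q, params = list(), seed = 1L,
                              sigma_floor = 1e-8) {
  pd <- list(B = 8, poly_degree = 3, clamp = TRUE)
  pd[names(params)] <- params
  if (!identical(rownames(Pprime), rownames(Q)))
    stop("Pprime and Q must share an identical gene list")
  if (min(ncol(Pprime), ncol(Q)) < 3)
    stop("each dataset needs at least 3 samples")
  G <- nrow(Pprime)
  m1 <- rowMeans(unclass(Pprime)); s1 <- pmax(row_sds(unclass(Pprime)),
                                              sigma_floor)
  m2 <- rowMeans(unclass(Q)); s2 <- pmax(row_sds(unclass(Q)), sigma_floor)
  z1 <- (unclass(Pprime) - m1) / s1
  z2 <- (unclass(Q) - m2) / s2
  B <- min(pd$B, G)
  blocks <- if (B == 1) rep(1L, G) else
    with_seed(seed, stats::kmeans(cbind(z1, z2), centers = B, nstart = 1,
                                  iter.max = 30)$cluster)
  zstar <- z1
  for (bl in seq_len(B)) {
    gb <- which(blocks == bl)
    if (!length(gb)) next
    xv <- as.vector(z1[gb, , drop = FALSE])
    yv <- as.vector(z2[gb, , drop = FALSE])
    fit <- cublock_block_map(xv, yv, degree = pd$poly_degree,
                             clamp = pd$clamp)
    zstar[gb, ] <- matrix(fit, nrow = length(gb))
  }
  out <- m2 + s2 * zstar               # restore to Q's per-gene scale
  dimnames(out) <- dimnames(Pprime)
  as_em(out, role = "Pdoubleprime")
}

# Rescaling ---------------------------------------------------------------

#' Per-gene rescaling of the standardized harmonized profile
#'
#' Applies one of three modes to the double-transformed log-expression value
#' LE'' of every gene g:
#' \itemize{
#'   \item PBR ("P-based"): \code{LE = mu_gQ + LE'' * sigma_gQ} — a simple
#'     per-gene translation and multiplication by the reference summaries;
#'     depends on Q only, so each sample is rescaled independently.
#'   \item QBR ("Q-based"): \code{LE = mu_gQ + (LE'' - mu_gH) * sigma_gQ /
#'     sigma_gH} — sets the per-gene mean/sd of the harmonized batch exactly
#'     to Q's.
#'   \item RBR ("R-based"): \code{LE = mu_gR + (LE'' - mu_gH) * sigma_gR /
#'     sigma_gH} — as QBR but targeting the raw dataset's summaries.
#' }
#' Genes whose batch sd \code{sigma_gH} falls below \code{sigma_floor} map
#' every value to the target mean, with a logged warning.
#'
#' @param Hraw \code{ExpressionMatrix} of LE'' values (standardized domain).
#' @param mode "PBR", "QBR" or "RBR".
#' @param sumQ,sumH,sumR \code{GeneSummary} objects aligned to
#'   \code{rownames(Hraw)}; \code{sumH} is required for QBR/RBR and
#'   \code{sumR} for RBR.
#' @param sigma_floor Smallest admissible sigma_gH.
#' @return Rescaled \code{ExpressionMatrix} with role "H".
#' @export
rescale <- function(Hraw, mode = c("PBR", "QBR", "RBR"), sumQ, sumH = NULL,
                    sumR = NULL, sigma_floor = 1e-8) {
  mode <- match.arg(mode)
  align <- function(s, what) {
    if (is.null(s)) stop("rescale: summary '", what, "' required for ", mode)
    if (!identical(s$gene, rownames(Hraw)))
      stop("rescale: summary '", what, "' is not aligned to Hraw's gene list")
    s
  }
  sumQ <- align(sumQ, "Q")
  x <- unclass(Hraw)
  if (mode == "PBR") {
    out <- sumQ$mu + x * sumQ$sigma
  } else {
    sumH <- align(sumH, "H")
    tgt <- if (mode == "QBR") sumQ else align(sumR, "R")
    low <- sumH$sigma < sigma_floor
    ratio <- ifelse(low, 0, tgt$sigma / pmax(sumH$sigma, sigma_floor))
    if (any(low))
      shmb_log(sprintf(
        "rescale: %d gene(s) with sigma_H below floor mapped to target mean",
        sum(low)), "warn")
    out <- tgt$mu + (x - sumH$mu) * ratio
  }
  dimnames(out) <- dimnames(x)
  as_em(out, role = "H")
}

# Full pipeline ------------------------------------------------------------

harmonize_one_sample <- function(r_col, sample_id, P, Q, config,
                                 qn_projection = FALSE) {
  merged <- cbind(unclass(P), r_col)
  colnames(merged) <- c(colnames(P), sample_id)
  Pp <- if (qn_projection) {
    # project the raw profile onto P's fixed quantiles (P columns untouched)
    ref <- rowMeans(apply(unclass(P), 2, sort))
    proj <- merged
    proj[, ncol(proj)] <- ref[rank(r_col, ties.method = "average")]
    as_em(proj, role = "Pprime")
  } else {
    quantile_normalize(as_em(merged, role = "Pprime"))
  }
  sd_i <- sample_seed(config$seed, sample_id)
  Ppp <- if (config$method == "shambhala1") {
    xpn_transform(Pp, Q, config$xpn_params, seed = sd_i,
                  sigma_floor = config$sigma_floor)
  } else {
    cublock_transform(Pp, Q, config$cublock_params, seed = sd_i,
                      sigma_floor = config$sigma_floor)
  }
  unclass(Ppp)[, ncol(Ppp)]
}

#' Harmonize a raw dataset into the universal shape
#'
#' Runs the whole pipeline on every sample of R independently: merge the
#' sample with the calibration dataset P, quantile-normalize (P'), transform
#' toward the reference definitive dataset Q (P''), extract the sample's
#' column, and finally rescale the assembled output by the configured mode.
#' Gene scope is \code{\link{intersect_and_filter_genes}(R, P, Q)}.
#'
#' @param R Raw \code{ExpressionMatrix} to harmonize.
#' @param P Calibration \code{ExpressionMatrix} (>= 10 samples).
#' @param Q Reference definitive \code{ExpressionMatrix} (>= 10 samples).
#' @param config A \code{\link{harmonization_config}}.
#' @param qn_projection If TRUE, the raw profile is projected onto P's fixed
#'   quantiles instead of being merged with weight 1 into the quantile
#'   normalization (the default).
#' @return Harmonized \code{ExpressionMatrix} (role "H") over the shared
#'   gene list, samples in R's order.
#' @export
shambhalize <- function(R, P, Q, config = harmonization_config(),
                        qn_projection = FALSE) {
  if (ncol(P) < 10 || ncol(Q) < 10)
    stop("P and Q must each have >= 10 samples")
  genes <- intersect_and_filter_genes(R, P, Q)
  shmb_log(sprintf("harmonizing %d sample(s); genes: R=%d P=%d Q=%d -> %d",
                   ncol(R), nrow(R), nrow(P), nrow(Q), length(genes)))
  Pg <- as_em(unclass(P)[genes, , drop = FALSE], "P")
  Qg <- as_em(unclass(Q)[genes, , drop = FALSE], "Q")
  Rg <- unclass(R)[genes, , drop = FALSE]
  sumQ <- gene_summaries(Qg)
  cols <- lapply(colnames(Rg), function(sid) {
    out <- tryCatch(
      harmonize_one_sample(Rg[, sid], sid, Pg, Qg, config, qn_projection),
      error = function(e) stop("harmonization failed for sample '", sid,
                               "': ", conditionMessage(e), call. = FALSE))
    out
  })
  Hq <- do.call(cbind, cols)            # on Q's per-gene scale
  dimnames(Hq) <- list(genes, colnames(Rg))
  # LE'' of the rescaling formulas is the standardized double-transformed
  # value; recover it from the Q-scale output of the block transform.
  Hdp <- (Hq - sumQ$mu) / pmax(sumQ$sigma, config$sigma_floor)
  Hdp <- as_em(Hdp, role = "H")
  sumH <- if (ncol(Hdp) >= 2) gene_summaries(Hdp) else NULL
  sumR <- if (config$rescale_mode == "RBR") {
    s <- gene_summaries(as_em(Rg, "R")); s
  } else NULL
  if (config$rescale_mode != "PBR" && is.null(sumH))
    stop("QBR/RBR need >= 2 samples in R to define the batch summaries")
  rescale(Hdp, mode = config$rescale_mode, sumQ = sumQ, sumH = sumH,
          sumR = sumR, sigma_floor = config$sigma_floor)
}
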