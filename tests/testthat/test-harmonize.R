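test_that("gene intersection is sorted, filtered and validated", {
  mk <- function(genes, role) em(matrix(seq_along(genes), ncol = 1),
                                 role = role, genes = genes,
                                 samples = paste0(role, "1"))
  R <- mk(c("a", "b", "c"), "R"); P <- mk(c("b", "c", "d"), "P")
  Q <- mk(c("c", "b"), "Q")
  expect_identical(intersect_and_filter_genes(R, P, Q), c("b", "c"))
  g100 <- sprintf("g%03d", 1:100)
  expect_length(intersect_and_filter_genes(mk(g100, "R"), mk(g100, "P"),
                                           mk(g100, "Q")), 100)
  expect_error(intersect_and_filter_genes(mk(c("x"), "R"), mk(c("y"), "P"),
                                          mk(c("z"), "Q")), "namespace")
})

test_that("top-N filter keeps the most expressed calibration genes", {
  genes <- c("a", "b", "c", "d")
  R <- em(matrix(1, 4, 2), genes = genes)
  P <- em(matrix(c(1, 9, 5, 2), 4, 2), role = "P", genes = genes)
  Q <- em(matrix(1, 4, 2), role = "Q", genes = genes)
  expect_identical(intersect_and_filter_genes(R, P, Q, top_n = 2),
                   c("b", "c"))
})

test_that("quantile normalization matches the hand example and contract", {
  m <- em(cbind(c(2, 4, 6), c(1, 3, 5)))
  qn <- quantile_normalize(m)
  expect_equal(as.numeric(unclass(qn)), rep(c(1.5, 3.5, 5.5), 2))
  # fixed point on identical samples
  id <- em(cbind(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(unclass(quantile_normalize(id)), unclass(id))
  # idempotence and rank preservation on random data
  r <- rand_em(G = 50, n = 5, seed = 2)
  q1 <- quantile_normalize(r)
  q2 <- quantile_normalize(q1)
  expect_lt(max(abs(unclass(q1) - unclass(q2))), 1e-12)
  for (j in seq_len(ncol(r)))
    expect_identical(order(unclass(r)[, j]), order(unclass(q1)[, j]))
  expect_warning(quantile_normalize(em(matrix(1:3, 3, 1))), "single sample")
})

test_that("rescale implements the three per-gene formulas", {
  le <- em(rbind(c(1, 2, 3)))
  gsum <- function(mu, sigma, role) structure(
    data.frame(gene = "g001", mu = mu, sigma = sigma), source_role = role,
    class = c("GeneSummary", "data.frame"))
  qbr <- rescale(le, "QBR", sumQ = gsum(10, 2, "Q"), sumH = gsum(2, 1, "H"))
  expect_equal(unname(unclass(qbr)[1, ]), c(8, 10, 12))
  expect_equal(mean(unclass(qbr)[1, ]), 10)
  expect_equal(stats::sd(unclass(qbr)[1, ]), 2)
  pbr <- rescale(em(rbind(c(-1, 0, 1))), "PBR", sumQ = gsum(5, 2, "Q"))
  expect_equal(unname(unclass(pbr)[1, ]), c(3, 5, 7))
  rbr <- rescale(em(rbind(c(0, 2))), "RBR", sumQ = gsum(0, 1, "Q"),
                 sumH = gsum(1, sqrt(2), "H"),
                 sumR = gsum(4, 2 * sqrt(2), "R"))
  expect_equal(unname(unclass(rbr)[1, ]), c(2, 6))
})

test_that("rescale maps zero-variance genes to the target mean", {
  le <- em(rbind(c(2, 2, 2)))
  gsum <- function(mu, sigma) structure(
    data.frame(gene = "g001", mu = mu, sigma = sigma), source_role = "Q",
    class = c("GeneSummary", "data.frame"))
  out <- rescale(le, "QBR", sumQ = gsum(7, 3), sumH = gsum(2, 0))
  expect_equal(unname(unclass(out)[1, ]), c(7, 7, 7))
  # misaligned summary is refused
  bad <- structure(data.frame(gene = "other", mu = 1, sigma = 1),
                   class = c("GeneSummary", "data.frame"))
  expect_error(rescale(le, "PBR", sumQ = bad), "aligned")
})

test_that("block transforms are reference-faithful and seeded", {
  cfg <- small_config(seed = 3)
  aux <- generate_auxiliary(cfg)
  Q <- aux$Q
  # cublock: exact identity when Pprime equals Q
  idem <- cublock_transform(
    expression_matrix(unclass(Q), role = "Pprime"), Q,
    list(B = 4), seed = 9)
  expect_lt(max(abs(unclass(idem) - unclass(Q))), 1e-6)
  # xpn: affine bias (+3 on every gene) is absorbed by the block model
  Pp3 <- expression_matrix(unclass(Q) + 3, role = "Pprime")
  out3 <- xpn_transform(Pp3, Q, list(K = 8, L = 3, n_repeats = 2), seed = 5)
  expect_lt(max(abs(rowMeans(out3) - rowMeans(Q))), 0.1)
  # xpn: near-null distortion leaves profiles near the reference
  set.seed(11)
  Ppn <- expression_matrix(unclass(Q) +
                             matrix(rnorm(length(Q), 0, 0.01), nrow(Q)),
                           role = "Pprime")
  outn <- xpn_transform(Ppn, Q, list(K = 8, L = 3, n_repeats = 2), seed = 5)
  expect_lt(max(abs(rowMeans(outn) - rowMeans(Q))), 0.05)
  # seeded determinism for both transforms
  expect_identical(
    unclass(xpn_transform(Pp3, Q, list(K = 8, L = 3, n_repeats = 2), 5)),
    unclass(xpn_transform(Pp3, Q, list(K = 8, L = 3, n_repeats = 2), 5)))
  expect_identical(
    unclass(cublock_transform(Pp3, Q, list(B = 4), 5)),
    unclass(cublock_transform(Pp3, Q, list(B = 4), 5)))
  expect_error(xpn_transform(Pp3, Q, list(K = 10000, L = 3), 1), "exceed")
})

test_that("cublock corrects a representable monotone distortion", {
  set.seed(4)
  G <- 150; n <- 16
  z <- matrix(rnorm(G * n), G)
  Q <- em(5 + 2 * z, role = "Q")
  zq <- (unclass(Q) - rowMeans(unclass(Q))) / apply(unclass(Q), 1, sd)
  warp <- sign(zq) * abs(zq)^(1 / 3)     # correction map is cubic
  Pp <- em(rowMeans(unclass(Q)) + apply(unclass(Q), 1, sd) * warp,
           role = "Pprime", genes = rownames(Q), samples = colnames(Q))
  out <- cublock_transform(Pp, Q, list(B = 1), seed = 2)
  zo <- (unclass(out) - rowMeans(unclass(Q))) / apply(unclass(Q), 1, sd)
  p <- (1:99) / 100
  rmse <- sqrt(mean((quantile(zo, p) - quantile(zq, p))^2))
  expect_lt(rmse, 0.1)
  # the non-representable (cubed) direction is still improved
  Pp2 <- em(rowMeans(unclass(Q)) + apply(unclass(Q), 1, sd) * zq^3,
            role = "Pprime", genes = rownames(Q), samples = colnames(Q))
  out2 <- cublock_transform(Pp2, Q, list(B = 1), seed = 2)
  zo2 <- (unclass(out2) - rowMeans(unclass(Q))) / apply(unclass(Q), 1, sd)
  before <- sqrt(mean((quantile((unclass(Pp2) - rowMeans(unclass(Q))) /
                                  apply(unclass(Q), 1, sd), p) -
                         quantile(zq, p))^2))
  after <- sqrt(mean((quantile(zo2, p) - quantile(zq, p))^2))
  expect_lt(after, before)
})

test_that("tiny blocks fall back to a linear quantile map", {
  set.seed(6)
  # 2 genes x 3 samples in the block: fewer than 8 pooled values
  Q <- em(matrix(rnorm(6, 5), 2, 3), role = "Q")
  Pp <- em(unclass(Q) * 2 - 5, role = "Pprime", genes = rownames(Q),
           samples = colnames(Q))
  expect_no_error(out <- cublock_transform(Pp, Q, list(B = 1), seed = 1))
  expect_true(all(is.finite(unclass(out))))
})

test_that("shambhalize honors the pipeline contract", {
  cfg <- small_config(seed = 2)
  sim <- generate_multiplatform(cfg)
  aux <- generate_auxiliary(cfg)
  R <- expression_matrix(unclass(sim$matrices$microarray)[, 1:3], role = "R")
  config <- fast_sh2(seed = 4)
  H <- shambhalize(R, aux$P, aux$Q, config)
  genes <- intersect_and_filter_genes(R, aux$P, aux$Q)
  expect_identical(rownames(H), genes)
  expect_identical(colnames(H), colnames(R))
  expect_identical(attr(H, "role"), "H")
  # seeded determinism of the whole pipeline
  H2 <- shambhalize(R, aux$P, aux$Q, config)
  expect_identical(unclass(H), unclass(H2))
})

test_that("PBR harmonization is independent of batch composition", {
  cfg <- small_config(seed = 5)
  sim <- generate_multiplatform(cfg)
  aux <- generate_auxiliary(cfg)
  Rall <- unclass(sim$matrices$rnaseq)
  config <- fast_sh2(seed = 7, rescale_mode = "PBR")
  H_batch <- shambhalize(expression_matrix(Rall[, 1:3], role = "R"),
                         aux$P, aux$Q, config)
  H_alone <- shambhalize(expression_matrix(Rall[, 1, drop = FALSE],
                                           role = "R"),
                         aux$P, aux$Q, config)
  expect_identical(unclass(H_alone)[, 1], unclass(H_batch)[, 1])
  # QBR, by contrast, depends on the batch through the H summaries
  configq <- fast_sh2(seed = 7, rescale_mode = "QBR")
  Hq_batch <- shambhalize(expression_matrix(Rall[, 1:3], role = "R"),
                          aux$P, aux$Q, configq)
  Hq_pair <- shambhalize(expression_matrix(Rall[, c(1, 3)], role = "R"),
                         aux$P, aux$Q, configq)
  expect_gt(max(abs(unclass(Hq_pair)[, 1] - unclass(Hq_batch)[, 1])), 1e-6)
})

test_that("QBR output matches the reference moments exactly", {
  cfg <- small_config(seed = 6)
  sim <- generate_multiplatform(cfg)
  aux <- generate_auxiliary(cfg)
  R <- expression_matrix(unclass(sim$matrices$microarray)[, 1:5], role = "R")
  H <- shambhalize(R, aux$P, aux$Q, fast_sh2(seed = 2, "QBR"))
  sq <- gene_summaries(expression_matrix(
    unclass(aux$Q)[rownames(H), , drop = FALSE], role = "Q"))
  expect_lt(max(abs(rowMeans(H) - sq$mu)), 1e-9)
  expect_lt(max(abs(apply(unclass(H), 1, stats::sd) - sq$sigma)), 1e-9)
})

test_that("harmonization failures name the offending sample", {
  cfg <- small_config(seed = 2)
  aux <- generate_auxiliary(cfg)
  bad <- expression_matrix(
    matrix(1, 2, 1, dimnames = list(c("zzz1", "zzz2"), "weird")), role = "R")
  expect_error(shambhalize(bad, aux$P, aux$Q, fast_sh2()), "namespace")
})
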