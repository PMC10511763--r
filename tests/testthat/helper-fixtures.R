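# Shared fixtures: all test data is generated in code.

suppressMessages(shmb_log_level("quiet"))

# a small named ExpressionMatrix from a plain numeric matrix
em <- function(values, role = "R", genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, role = role)
}

rand_em <- function(G = 20, n = 6, role = "R", seed = 1, mu = 5, sd = 2) {
  set.seed(seed)
  em(matrix(stats::rnorm(G * n, mu, sd), G, n), role = role)
}

# small-but-complete synthetic benchmark configuration for module tests
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(genes = 400, n = 4, n_aux = 12, n_cases = 4, n_pathways = 6,
         pathway_size = c(4, 6), n_shifted = 3, n_drugs = 5, seed = seed),
    list(...))
  do.call(synthetic_config, args)
}

# reduced-size harmonization config for fast tests
fast_sh1 <- function(seed = 1, rescale_mode = "PBR") {
  harmonization_config(method = "shambhala1", rescale_mode = rescale_mode,
                       xpn_params = list(K = 8, L = 3, n_repeats = 3),
                       seed = seed)
}

fast_sh2 <- function(seed = 1, rescale_mode = "PBR") {
  harmonization_config(method = "shambhala2", rescale_mode = rescale_mode,
                       cublock_params = list(B = 4), seed = seed)
}

# hand-built hclust object (merge rows follow increasing height)
manual_hclust <- function(merge, height, labels) {
  structure(list(merge = merge, height = height,
                 order = seq_along(labels), labels = labels,
                 method = "manual", call = match.call(),
                 dist.method = "manual"),
            class = "hclust")
}
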