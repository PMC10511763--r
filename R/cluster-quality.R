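# Entropy-based dendrogram quality: how quickly do the splits of a
# hierarchical clustering tree separate known sample classes?  The
# Watermelon Multisection (WM) metric compares the observed information-gain
# trajectory with the theoretically fastest one and with a permutation null.

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of the columns of an expression matrix.  The
#' default distance is 1 - Pearson correlation across genes (scale-robust
#' for expression profiles); the default linkage is average.
#'
#' @param matrix \code{ExpressionMatrix} with >= 3 samples.
#' @param distance "correlation" (1 - Pearson) or "euclidean".
#' @param linkage Any method accepted by \code{\link[stats]{hclust}}.
#' @return An \code{\link[stats]{hclust}} tree over the samples.
#' @export
hierarchical_cluster <- function(matrix, distance = c("correlation",
                                                      "euclidean"),
                                 linkage = "average") {
  distance <- match.arg(distance)
  if (ncol(matrix) < 3) stop("need >= 3 samples to cluster")
  x <- unclass(matrix)
  if (distance == "correlation") {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
      stop("constant sample vector(s) incompatible with correlation ",
           "distance: ", paste(colnames(x)[sds == 0], collapse = ", "))
    d <- stats::as.dist(1 - stats::cor(x))
  } else {
    d <- stats::dist(t(x))
  }
  stats::hclust(d, method = linkage)
}

#' Export a dendrogram as a newick string
#'
#' @param dendrogram An \code{hclust} object.
#' @param path Optional file to write to.
#' @return The newick string, invisibly if written to file.
#' @export
newick_export <- function(dendrogram, path = NULL) {
  phy <- dend_to_newick(dendrogram)
  if (is.null(path)) return(phy)
  writeLines(phy, path)
  invisible(phy)
}

dend_to_newick <- function(hc) {
  rec <- function(node, parent_h) {
    if (node < 0)
      return(sprintf("%s:%g", hc$labels[-node], parent_h))
    ch <- hc$merge[node, ]
    h <- hc$height[node]
    sprintf("(%s,%s):%g", rec(ch[1], h), rec(ch[2], h), parent_h - h)
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  sprintf("(%s,%s);", rec(hc$merge[root, 1], h), rec(hc$merge[root, 2], h))
}

# leaf sets and label counts per tree node, bottom-up
node_label_counts <- function(hc, lab_int, m) {
  n <- length(hc$order)
  nm <- nrow(hc$merge)
  counts <- matrix(0L, nm, m)
  for (r in seq_len(nm)) {
    for (ch in hc$merge[r, ]) {
      if (ch < 0) {
        counts[r, lab_int[-ch]] <- counts[r, lab_int[-ch]] + 1L
      } else {
        counts[r, ] <- counts[r, ] + counts[ch, ]
      }
    }
  }
  counts
}

# cumulative normalized information gain after j = 0..n-1 splits, splits
# applied in order of decreasing merge height (= reverse merge order for
# monotone linkages; ties broken by internal node index)
ig_observed <- function(hc, lab_int, m) {
  n <- length(hc$order)
  counts <- node_label_counts(hc, lab_int, m)
  ent <- function(cnt) {
    tot <- sum(cnt)
    if (tot == 0) return(0)
    p <- cnt[cnt > 0] / tot
    -sum(p * log(p))
  }
  node_ent <- apply(counts, 1, ent)
  node_size <- rowSums(counts)
  H <- ent(tabulate(lab_int, m))
  cond <- numeric(n)                       # weighted conditional entropy
  cond[1] <- H
  cur <- H
  for (j in seq_len(n - 1)) {
    r <- nrow(hc$merge) - j + 1            # undo merges from the root down
    term <- function(ch) {
      if (ch < 0) 0 else node_size[ch] / n * node_ent[ch]
    }
    parent <- if (r == nrow(hc$merge)) H else {
      node_size[r] / n * node_ent[r]
    }
    cur <- cur - parent + term(hc$merge[r, 1]) + term(hc$merge[r, 2])
    cond[j + 1] <- cur
  }
  (H - cond) / H
}

# greedy fastest-separation trajectory: isolate, one at a time, the class
# whose removal from the remaining lump maximizes information gain
ig_maximal <- function(lab_int, m, n_splits) {
  n <- length(lab_int)
  cnt <- tabulate(lab_int, m)
  H <- entropy(lab_int)
  ent_cnt <- function(cn) {
    tot <- sum(cn)
    if (tot == 0) return(0)
    p <- cn[cn > 0] / tot
    -sum(p * log(p))
  }
  remaining <- which(cnt > 0)
  traj <- numeric(n_splits + 1)            # traj[1] = 0 splits -> IG 0
  for (j in seq_len(n_splits)) {
    if (length(remaining) <= 1) { traj[j + 1] <- 1; next }
    best <- -Inf; best_c <- remaining[1]
    for (cl in remaining) {
      rest <- setdiff(remaining, cl)
      cond <- sum(cnt[rest]) / n * ent_cnt(cnt[rest])
      ig <- (H - cond) / H
      if (ig > best) { best <- ig; best_c <- cl }
    }
    remaining <- setdiff(remaining, best_c)
    traj[j + 1] <- best
  }
  traj
}

#' Information-gain trajectory of a labeled dendrogram
#'
#' Splits are applied from the root down in order of decreasing merge
#' height; after j splits the leaves form j+1 clusters and the cumulative
#' information gain about the class labels, normalized by the total label
#' entropy, is recorded.  The maximal trajectory is the theoretically
#' fastest separation of the classes (1 for every j >= number of classes -
#' 1; greedy class isolation below that).
#'
#' @param dendrogram An \code{hclust} object.
#' @param labels Class label per leaf, in \code{dendrogram$labels} order.
#' @return List of class \code{IGTrajectory} with elements \code{observed}
#'   and \code{maximal} (numeric vectors of length n).
#' @export
ig_trajectory <- function(dendrogram, labels) {
  labels <- as.factor(labels)
  if (length(labels) != length(dendrogram$labels))
    stop("labels length must equal the number of leaves")
  m <- nlevels(labels)
  if (m < 2) stop("WM undefined for single-class labels (zero entropy)")
  lab_int <- as.integer(labels)
  n <- length(lab_int)
  structure(list(observed = ig_observed(dendrogram, lab_int, m),
                 maximal = ig_maximal(lab_int, m, n - 1)),
            class = "IGTrajectory")
}

#' Watermelon Multisection metric
#'
#' WM scores how quickly a dendrogram's splits separate known classes:
#' \code{wm = (A_obs - A_null) / (A_max - A_null)} where A is the mean of an
#' information-gain trajectory over splits 1..n-1, "obs" is the observed
#' tree/label trajectory, "max" the fastest possible separation, and "null"
#' the mean trajectory over random label permutations on the same tree.
#' wm is clipped to [0, 1]; a perfectly class-separating tree scores 1 and
#' random labels score ~0 (before clipping).
#'
#' @param dendrogram An \code{hclust} object.
#' @param labels Class per leaf.
#' @param n_perm Number of label permutations for the null (>= 20).
#' @param seed Integer seed for the permutations.
#' @return \code{IGTrajectory} list with elements \code{observed},
#'   \code{maximal}, \code{null}, \code{wm} (clipped) and \code{wm_raw}.
#' @export
wm_metric <- function(dendrogram, labels, n_perm = 100, seed = 1L) {
  if (n_perm < 20) stop("n_perm must be >= 20")
  tr <- ig_trajectory(dendrogram, labels)
  labels <- as.factor(labels)
  lab_int <- as.integer(labels)
  m <- nlevels(labels)
  n <- length(lab_int)
  null_acc <- numeric(n)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      null_acc <- null_acc + ig_observed(dendrogram, sample(lab_int), m)
    }
  })
  tr$null <- null_acc / n_perm
  idx <- 2:n                               # splits j = 1 .. n-1
  a_obs <- mean(tr$observed[idx])
  a_max <- mean(tr$maximal[idx])
  a_null <- mean(tr$null[idx])
  if (a_max <= a_null)
    stop("degenerate tree: maximal trajectory does not exceed the null")
  tr$wm_raw <- (a_obs - a_null) / (a_max - a_null)
  tr$wm <- min(max(tr$wm_raw, 0), 1)
  tr
}

#' Harmonization-quality ratio from subsampled dendrograms
#'
#' For each repeat, draws \code{n_per_cell} samples from every tissue-by-
#' platform cell, clusters them, and computes the WM metric twice: against
#' tissue labels (wm_s) and against platform labels (wm_p).  The ratio
#' \code{R = wm_s / wm_p} measures whether clustering is driven by biology
#' (R > 1) or by platform bias (R < 1); the reported value is the median
#' over repeats.
#'
#' @param matrix \code{ExpressionMatrix} of the samples to assess.
#' @param samples Sample table (see \code{\link{read_sample_table}})
#'   covering every column of \code{matrix}.
#' @param n_per_cell Samples drawn per tissue-by-platform cell.
#' @param n_repeats Number of random subsamples.
#' @param seed Integer seed.
#' @param n_perm Permutations for each WM null.
#' @param distance,linkage Passed to \code{\link{hierarchical_cluster}}.
#' @return List of class \code{QualityRatio}: \code{replicates} (data.frame
#'   with wm_s, wm_p, ratio per repeat), \code{median_ratio},
#'   \code{median_wm_s}, \code{median_wm_p}.
#' @export
quality_ratio <- function(matrix, samples, n_per_cell = 5, n_repeats = 25,
                          seed = 1L, n_perm = 100,
                          distance = "correlation", linkage = "average") {
  samples <- validate_sample_table(samples)
  idx <- match(colnames(matrix), samples$sample_id)
  if (anyNA(idx))
    stop("samples missing from the annotation table: ",
         paste(colnames(matrix)[is.na(idx)], collapse = ", "))
  ann <- samples[idx, ]
  cell <- interaction(ann$tissue_type, ann$platform, drop = TRUE)
  sizes <- table(cell)
  keep_cells <- names(sizes)[sizes >= n_per_cell]
  if (length(keep_cells) < length(sizes))
    shmb_log(sprintf("quality_ratio: dropping %d cell(s) below n_per_cell",
                     length(sizes) - length(keep_cells)), "warn")
  in_scope <- cell %in% keep_cells
  if (length(unique(ann$tissue_type[in_scope])) < 2 ||
      length(unique(ann$platform[in_scope])) < 2)
    stop("need >= 2 tissues and >= 2 platforms after cell filtering")
  reps <- with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      pick <- unlist(lapply(keep_cells, function(cl) {
        sample(which(cell == cl & in_scope), n_per_cell)
      }))
      sub <- as_em(unclass(matrix)[, pick, drop = FALSE], "H")
      hc <- hierarchical_cluster(sub, distance = distance, linkage = linkage)
      wseed <- sample.int(2147483647, 1)
      ws <- wm_metric(hc, ann$tissue_type[pick], n_perm = n_perm,
                      seed = wseed)$wm
      wp <- wm_metric(hc, ann$platform[pick], n_perm = n_perm,
                      seed = wseed + 1)$wm
      # wm values are clipped to [0, 1]; floor both at a small epsilon so
      # the ratio stays finite and positive in degenerate subsamples
      c(wm_s = ws, wm_p = wp, ratio = max(ws, 1e-6) / max(wp, 1e-6))
    })
  })
  df <- as.data.frame(do.call(rbind, reps))
  structure(list(replicates = df,
                 median_ratio = stats::median(df$ratio),
                 median_wm_s = stats::median(df$wm_s),
                 median_wm_p = stats::median(df$wm_p)),
            class = "QualityRatio")
}
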