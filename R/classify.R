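#' Total connectivity of each node
#'
#' Sum of all outgoing plus incoming interactions of every node:
#' `TC_i = sum_{j != i} C_ij + sum_{j != i} C_ji`.
#'
#' @param C square coupling matrix.
#' @return Numeric vector of length M.
#' @export
total_connectivity <- function(C) {
  assert_square(C)
  rowSums(C) + colSums(C) - 2 * diag(C)
}

#' Compare per-node statistics between two conditions
#'
#' Two-sided Wilcoxon rank-sum test per node with Benjamini-Hochberg FDR
#' correction across the M nodes.
#'
#' @param tc_a,tc_b samples x M matrices (e.g. total connectivity of each
#'   model in each condition); at least 3 samples per side.
#' @param alpha FDR level (default 0.05).
#' @param alternative test sidedness (default "two.sided").
#' @return Data frame with columns `node`, `statistic`, `p`, `p_adj`,
#'   `significant`.
#' @export
compare_conditions <- function(tc_a, tc_b, alpha = 0.05,
                               alternative = "two.sided") {
  tc_a <- as.matrix(tc_a); tc_b <- as.matrix(tc_b)
  if (ncol(tc_a) != ncol(tc_b))
    stop("both samples must cover the same nodes", call. = FALSE)
  if (nrow(tc_a) < 3L || nrow(tc_b) < 3L)
    stop("need at least 3 samples per condition", call. = FALSE)
  M <- ncol(tc_a)
  stat <- p <- rep(NA_real_, M)
  for (j in seq_len(M)) {
    if (length(unique(c(tc_a[, j], tc_b[, j]))) == 1L) {
      warning(sprintf("node %d: all samples tied; p set to 1", j))
      stat[j] <- NA_real_
      p[j] <- 1
    } else {
      wt <- suppressWarnings(
        wilcox.test(tc_a[, j], tc_b[, j], alternative = alternative))
      stat[j] <- unname(wt$statistic)
      p[j] <- wt$p.value
    }
  }
  p_adj <- p.adjust(p, method = "BH")
  data.frame(node = seq_len(M), statistic = stat, p = p, p_adj = p_adj,
             significant = p_adj <= alpha)
}

#' Directed graph of supra-threshold interactions
#'
#' Lists every entry with `C[i, j] > thr` (strictly) as a directed edge
#' i -> j, excluding the diagonal, together with per-node edge views.
#'
#' @param C square coupling matrix.
#' @param thr threshold (default 0.1).
#' @return A list of class `coupling_graph`: `edges` (data frame `from`,
#'   `to`, `weight`), `out_edges` and `in_edges` (edge lists split by node).
#' @export
threshold_graph <- function(C, thr = 0.1) {
  assert_square(C)
  M <- nrow(C)
  sel <- which(C > thr & row(C) != col(C), arr.ind = TRUE)
  edges <- data.frame(from = sel[, 1L], to = sel[, 2L],
                      weight = C[sel])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 out_edges = split(edges, factor(edges$from,
                                                 levels = seq_len(M))),
                 in_edges = split(edges, factor(edges$to,
                                                levels = seq_len(M))),
                 thr = thr, n_nodes = M),
            class = "coupling_graph")
}

#' Classifier configuration
#'
#' @param kernel_scale Gaussian kernel scale s in
#'   `K(x, y) = exp(-||x - y||^2 / s^2)`; `NULL` (default) uses the
#'   `sqrt(D)` heuristic on standardized features.
#' @param box box constraint of each binary SVM (default 1).
#' @param train_frac training fraction of each stratified split (default 0.9).
#' @param n_repeats shuffled-split repetitions (default 100).
#' @param smo_max_iter iteration cap of the SMO solver per binary machine
#'   (default 8000; solutions on non-separable label noise plateau long
#'   before this).
#' @param seed integer master seed.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(kernel_scale = NULL, box = 1,
                              train_frac = 0.9, n_repeats = 100L,
                              smo_max_iter = 8000L, seed = NULL) {
  stopifnot(train_frac > 0, train_frac < 1, n_repeats >= 1L, box > 0,
            smo_max_iter >= 1L)
  structure(list(kernel_scale = kernel_scale, box = box,
                 train_frac = train_frac, n_repeats = as.integer(n_repeats),
                 smo_max_iter = as.integer(smo_max_iter), seed = seed),
            class = "classifier_config")
}

#' Flatten coupling / connectivity matrices into feature vectors
#'
#' For asymmetric coupling matrices the feature vector is all off-diagonal
#' entries (M(M-1) features); for symmetric FC matrices use the upper
#' triangle only.
#'
#' @param C square matrix.
#' @return Numeric feature vector.
#' @export
lgec_features <- function(C) {
  assert_square(C)
  C[row(C) != col(C)]
}

#' @rdname lgec_features
#' @export
fc_features <- function(C) {
  assert_square(C)
  C[upper.tri(C)]
}

#' Train and evaluate the condition-fingerprint classifier
#'
#' Gaussian-kernel one-versus-one multiclass SVM (K(K-1)/2 binary machines,
#' vote decoding): for each of `n_repeats` repetitions, draws a stratified
#' shuffled train/validation split, standardizes features on the training
#' part, fits, and scores the validation part. Reports mean and SD accuracy
#' and the pooled row-normalized confusion matrix.
#'
#' @param features samples x D numeric matrix (e.g. rows of
#'   [lgec_features()] vectors).
#' @param labels class label per sample (coerced to factor).
#' @param cfg a [classifier_config()].
#' @return An object of class `classifier_report` with `accuracy_mean`,
#'   `accuracy_sd`, `per_repeat`, `confusion` (true x predicted,
#'   row-normalized) and `classes`.
#' @export
train_task_classifier <- function(features, labels,
                                  cfg = classifier_config()) {
  features <- assert_matrix(features)
  labels <- factor(labels)
  stopifnot(nrow(features) == length(labels), nlevels(labels) >= 2L)
  K <- nlevels(labels)
  D <- ncol(features)
  y <- as.integer(labels)
  scale_s <- if (is.null(cfg$kernel_scale)) sqrt(D) else cfg$kernel_scale
  gamma <- 1 / scale_s^2

  set_seed_if(cfg$seed)
  acc <- rep(NA_real_, cfg$n_repeats)
  confusion <- matrix(0, K, K, dimnames = list(levels(labels),
                                               levels(labels)))
  for (rep_i in seq_len(cfg$n_repeats)) {
    test_idx <- unlist(lapply(seq_len(K), function(cl) {
      idx <- which(y == cl)
      n_te <- max(1L, round((1 - cfg$train_frac) * length(idx)))
      if (n_te >= length(idx))
        stop("a class has too few samples for the requested split",
             call. = FALSE)
      sample(idx, n_te)
    }))
    tr <- setdiff(seq_len(nrow(features)), test_idx)
    mu <- colMeans(features[tr, , drop = FALSE])
    sdv <- apply(features[tr, , drop = FALSE], 2L, sd)
    sdv[sdv == 0] <- 1
    std <- function(x) sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
    pred <- svm_ovo_cpp(std(features[tr, , drop = FALSE]), y[tr],
                        std(features[test_idx, , drop = FALSE]),
                        K, cfg$box, gamma, 1e-3, cfg$smo_max_iter)
    truth <- y[test_idx]
    acc[rep_i] <- mean(pred == truth)
    for (t in seq_along(truth))
      confusion[truth[t], pred[t]] <- confusion[truth[t], pred[t]] + 1
  }
  rs <- rowSums(confusion)
  rs[rs == 0] <- 1
  structure(list(accuracy_mean = mean(acc), accuracy_sd = sd(acc),
                 per_repeat = acc, confusion = confusion / rs,
                 classes = levels(labels)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> accuracy %.3f +/- %.3f over %d repeats (%d classes)\n",
              x$accuracy_mean, x$accuracy_sd, length(x$per_repeat),
              length(x$classes)))
  invisible(x)
}

#' Randomly permute a label vector
#'
#' Seeded uniform permutation preserving the label multiset; the chance-level
#' control for the fingerprint classifier.
#'
#' @param labels label vector.
#' @param seed integer seed.
#' @return Permuted labels.
#' @export
scramble_labels <- function(labels, seed = NULL) {
  stopifnot(length(labels) >= 1L)
  set_seed_if(seed)
  labels[sample.int(length(labels))]
}
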