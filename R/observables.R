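#' Zero-lag functional connectivity (FC)
#'
#' Pairwise Pearson correlation between the columns of a time-by-mode (or
#' time-by-region) matrix.
#'
#' @param x T x M numeric matrix, T >= 3, no constant column.
#' @return M x M symmetric correlation matrix with unit diagonal.
#' @export
compute_fc <- function(x) {
  x <- assert_matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 time frames", call. = FALSE)
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    stop(sprintf("column %d is constant; correlation undefined",
                 which(sds == 0)[1L]), call. = FALSE)
  fc <- cor(x)
  diag(fc) <- 1
  fc
}

#' Forward-shifted functional connectivity FCf(tau)
#'
#' `FCf[i, j]` is the Pearson correlation between mode i and mode j shifted
#' forward in time by `tau` frames: `cor(x_i[1..T-tau], x_j[(1+tau)..T])`.
#' The row index is the earlier signal. Generally asymmetric; its asymmetry
#' reflects temporal irreversibility (broken detailed balance).
#'
#' @param x T x M numeric matrix with `T > tau + 2`.
#' @param tau forward shift in observation frames (default 3).
#' @return M x M matrix with attribute `tau`.
#' @export
compute_fcf <- function(x, tau = 3L) {
  x <- assert_matrix(x)
  tau <- as.integer(tau)
  stopifnot(tau >= 0L)
  T <- nrow(x)
  if (T <= tau + 2L)
    stop("need T > tau + 2 frames", call. = FALSE)
  early <- x[seq_len(T - tau), , drop = FALSE]
  late <- x[(1L + tau):T, , drop = FALSE]
  sds_e <- apply(early, 2L, sd)
  sds_l <- apply(late, 2L, sd)
  if (any(sds_e == 0) || any(sds_l == 0))
    stop(sprintf("column %d is constant; correlation undefined",
                 which(sds_e == 0 | sds_l == 0)[1L]), call. = FALSE)
  fcf <- cor(early, late)
  attr(fcf, "tau") <- tau
  fcf
}

#' Similarity between two connectivity matrices
#'
#' Pearson correlation over the off-diagonal entries (the constant unit
#' diagonal of correlation matrices would otherwise inflate the similarity).
#'
#' @param A,B square matrices of equal size.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
matrix_similarity <- function(A, B) {
  assert_square(A); assert_square(B)
  if (!all(dim(A) == dim(B)))
    stop("'A' and 'B' must have the same shape", call. = FALSE)
  off <- row(A) != col(A)
  a <- A[off]; b <- B[off]
  if (sd(a) == 0 || sd(b) == 0)
    stop("off-diagonal entries are constant; similarity undefined",
         call. = FALSE)
  cor(a, b)
}

#' Average connectivity matrices over random disjoint subgroups
#'
#' Shuffles the subject order (seeded), partitions into disjoint groups of
#' `group_size` (dropping any remainder), and returns the entrywise mean of
#' each group — the subgroup-averaged observables that each model is fitted
#' to.
#'
#' @param mats list of equally-sized matrices (one per subject).
#' @param group_size subjects per group (e.g. 10 for rest, 9 for rest+tasks).
#' @param seed integer seed for the shuffle; `NULL` uses the current stream.
#' @return List of `floor(length(mats)/group_size)` averaged matrices.
#' @export
group_average <- function(mats, group_size, seed = NULL) {
  stopifnot(is.list(mats), length(mats) >= 1L, group_size >= 1L,
            length(mats) >= group_size)
  set_seed_if(seed)
  ord <- sample.int(length(mats))
  n_groups <- length(mats) %/% group_size
  lapply(seq_len(n_groups), function(g) {
    idx <- ord[((g - 1L) * group_size + 1L):(g * group_size)]
    Reduce(`+`, mats[idx]) / group_size
  })
}

#' Coupling-asymmetry index
#'
#' `||C - t(C)||_F / (||C + t(C)||_F + 1e-12)`: zero for symmetric coupling,
#' large for strongly directed coupling. Asymmetric coupling breaks detailed
#' balance and produces temporally irreversible dynamics.
#'
#' @param C square matrix.
#' @return Nonnegative scalar.
#' @export
asymmetry_index <- function(C) {
  assert_square(C)
  norm(C - t(C), "F") / (norm(C + t(C), "F") + 1e-12)
}

#' Subject-averaged empirical observables
#'
#' Convenience wrapper: computes FC and FCf(tau) for each trajectory and
#' returns their entrywise means, the "empirical" pair that
#' [infer_gec()] fits.
#'
#' @param latents list of T x M latent-trajectory matrices.
#' @param tau forward shift in frames (default 3).
#' @return List with elements `fc` and `fcf`.
#' @export
average_observables <- function(latents, tau = 3L) {
  if (is.matrix(latents)) latents <- list(latents)
  stopifnot(length(latents) >= 1L)
  fcs <- lapply(latents, compute_fc)
  fcfs <- lapply(latents, compute_fcf, tau = tau)
  fcf <- Reduce(`+`, fcfs) / length(fcfs)
  attr(fcf, "tau") <- as.integer(tau)
  list(fc = Reduce(`+`, fcs) / length(fcs), fcf = fcf)
}
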