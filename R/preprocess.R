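#' Construct a regional BOLD time-series object
#'
#' Container for one subject/condition recording: a numeric matrix with one
#' row per time frame and one column per region, plus the sampling period
#' (repetition time, TR) in seconds.
#'
#' @param data numeric matrix, rows = time frames (T >= 2), columns = regions
#'   (N >= 2); all values must be finite.
#' @param tr_seconds positive sampling period in seconds.
#' @param region_labels optional character vector of N region names.
#' @param subject_id,condition free-text labels carried through the pipeline.
#' @return An object of class `bold_ts`.
#' @export
bold_timeseries <- function(data, tr_seconds, region_labels = NULL,
                            subject_id = "", condition = "") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L)
    stop("time series must have at least 2 time frames", call. = FALSE)
  if (ncol(data) < 2L)
    stop("time series must have at least 2 regions", call. = FALSE)
  bad <- which(!is.finite(data), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-finite value at row %d, column %d", bad[1, 1], bad[1, 2]),
         call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0)
    stop("'tr_seconds' must be a positive number", call. = FALSE)
  if (is.null(region_labels))
    region_labels <- colnames(data)
  if (is.null(region_labels))
    region_labels <- sprintf("R%03d", seq_len(ncol(data)))
  if (length(region_labels) != ncol(data))
    stop("'region_labels' length must equal the number of regions",
         call. = FALSE)
  colnames(data) <- region_labels
  structure(
    list(data = data, tr_seconds = tr_seconds,
         region_labels = as.character(region_labels),
         subject_id = as.character(subject_id),
         condition = as.character(condition)),
    class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf("<bold_ts> %d frames x %d regions, TR = %g s",
              nrow(x$data), ncol(x$data), x$tr_seconds))
  if (nzchar(x$subject_id)) cat(sprintf(", subject %s", x$subject_id))
  if (nzchar(x$condition)) cat(sprintf(", condition %s", x$condition))
  cat("\n")
  invisible(x)
}

#' Read a regional time-series matrix from a delimited text file
#'
#' Expects a numeric CSV/TSV matrix with rows = time frames and columns =
#' regions; an optional header row provides region labels. If the file holds
#' more columns than rows the matrix is transposed when `allow_transpose` is
#' set (with a warning), since region count normally is far below frame count.
#'
#' @param path file to read.
#' @param tr_seconds sampling period in seconds.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab.
#' @param allow_transpose permit transposing a wide matrix (default FALSE).
#' @param subject_id,condition labels stored in the result.
#' @return A [bold_timeseries()] object.
#' @export
load_timeseries <- function(path, tr_seconds, sep = NULL,
                            allow_transpose = FALSE,
                            subject_id = "", condition = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  first <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (grepl("\t", first)) "\t" else ","
  header <- {
    cells <- strsplit(first, sep, fixed = TRUE)[[1]]
    any(is.na(suppressWarnings(as.numeric(cells))))
  }
  df <- read.table(path, sep = sep, header = header,
                   stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric cell at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2], path), call. = FALSE)
  }
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    stop(sprintf("non-finite cell at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2], path), call. = FALSE)
  }
  if (ncol(m) > nrow(m)) {
    if (allow_transpose) {
      warning(sprintf("%s has more columns than rows; transposing", path))
      m <- t(m)
    }
  }
  if (nrow(m) < 2L)
    stop(sprintf("%s has fewer than 2 time frames", path), call. = FALSE)
  bold_timeseries(m, tr_seconds,
                  region_labels = colnames(m),
                  subject_id = subject_id, condition = condition)
}

#' Write a regional time-series matrix to a delimited text file
#'
#' @param ts a [bold_timeseries()] object.
#' @param path output file; extension `.tsv` selects tab separation, anything
#'   else comma.
#' @param header write the region labels as a header row (default TRUE).
#' @export
write_timeseries <- function(ts, path, header = TRUE) {
  stopifnot(inherits(ts, "bold_ts"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  write.table(ts$data, path, sep = sep, row.names = FALSE,
              col.names = header, quote = FALSE)
  invisible(path)
}

#' Band-pass filter specification
#'
#' Defaults follow the standard fMRI band: a second-order Butterworth
#' band-pass between 0.008 and 0.08 Hz.
#'
#' @param order filter order of the Butterworth prototype (default 2).
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr_seconds)` for the series being filtered.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(order = 2L, low_hz = 0.008, high_hz = 0.08) {
  order <- as.integer(order)
  stopifnot(order >= 1L, low_hz > 0, high_hz > low_hz)
  structure(list(order = order, low_hz = low_hz, high_hz = high_hz),
            class = "filter_spec")
}

# Digital Butterworth band-pass design via the bilinear transform.
# Returns transfer-function coefficients b, a of length 2*order + 1.
# No signal-processing package ships in this R stack, so the design is done
# here: analog low-pass prototype poles -> low-pass-to-band-pass
# transformation -> bilinear map with frequency pre-warping.
butter_bandpass <- function(order, low_hz, high_hz, fs) {
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf(
      "infeasible band [%g, %g] Hz for sampling rate %g Hz (Nyquist %g Hz)",
      low_hz, high_hz, fs, nyq), call. = FALSE)
  fs2 <- 2 * fs
  # pre-warped analog edge frequencies
  w1 <- fs2 * tan(pi * low_hz / fs)
  w2 <- fs2 * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # analog Butterworth low-pass prototype poles (unit cutoff)
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # low-pass -> band-pass: each pole splits into two
  sp <- p_lp * bw / 2
  p_bp <- c(sp + sqrt(sp^2 - w0^2), sp - sqrt(sp^2 - w0^2))
  z_bp <- rep(0 + 0i, order)        # 'order' zeros at s = 0
  k_bp <- bw^order                   # prototype gain 1
  # bilinear transform s -> 2 fs (z-1)/(z+1)
  zd <- (fs2 + z_bp) / (fs2 - z_bp)
  pd <- (fs2 + p_bp) / (fs2 - p_bp)
  kd <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  # degree difference adds zeros at z = -1
  zd <- c(zd, rep(-1 + 0i, length(p_bp) - length(z_bp)))
  poly_from_roots <- function(r) {
    p <- 1 + 0i
    for (ri in r) p <- c(p, 0) - c(0, p * ri)
    p
  }
  b <- Re(kd * poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))
  list(b = b, a = a)
}

# Steady-state initial conditions for a unit step input (the standard
# lfilter_zi construction: solve (I - A^T) zi = B with A the companion
# matrix of the denominator).
lfilter_zi <- function(b, a) {
  n <- length(a)
  comp <- rbind(-a[-1] / a[1],
                cbind(diag(1, n - 2L), rep(0, n - 2L)))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - t(comp), B)
}

# Zero-phase (forward-backward) filtering of one signal with odd-symmetric
# edge extension and step-matched initial conditions, mirroring the
# conventional filtfilt procedure.
filtfilt_one <- function(b, a, x) {
  T <- length(x)
  padlen <- min(3L * max(length(a), length(b)), T - 1L)
  ext <- c(2 * x[1] - x[(padlen + 1L):2L],
           x,
           2 * x[T] - x[(T - 1L):(T - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter_cpp(b, a, ext, zi * ext[1])
  y <- rev(lfilter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + T)]
}

# Analytic squared magnitude response of the digital design at frequency
# f (Hz): Butterworth band-pass evaluated at the pre-warped frequency.
# Exposed internally as the oracle used by the test-suite.
butter_bandpass_gain <- function(spec, f, fs) {
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * spec$low_hz / fs)
  w2 <- fs2 * tan(pi * spec$high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  w <- fs2 * tan(pi * f / fs)
  sqrt(1 / (1 + ((w^2 - w0^2) / (bw * w))^(2 * spec$order)))
}

#' Apply a zero-phase Butterworth band-pass filter to each region
#'
#' Each column is filtered independently with a Butterworth band-pass applied
#' forward and backward (zero phase), so the lag structure needed by the
#' forward-shifted connectivity is not distorted by group delay.
#'
#' @param ts a [bold_timeseries()] object.
#' @param spec a [filter_spec()]; the band must lie below the Nyquist
#'   frequency `1/(2 tr_seconds)`.
#' @return A filtered `bold_ts` of the same shape.
#' @export
bandpass_filter <- function(ts, spec = filter_spec()) {
  stopifnot(inherits(ts, "bold_ts"), inherits(spec, "filter_spec"))
  fs <- 1 / ts$tr_seconds
  ba <- butter_bandpass(spec$order, spec$low_hz, spec$high_hz, fs)
  out <- apply(ts$data, 2L, function(x) filtfilt_one(ba$b, ba$a, x))
  bold_timeseries(out, ts$tr_seconds, ts$region_labels,
                  ts$subject_id, ts$condition)
}

#' Trim a fraction of frames from both ends of a recording
#'
#' Discards `floor(fraction * T)` frames at the start and the same number at
#' the end, the usual guard against band-pass border effects.
#'
#' @param ts a [bold_timeseries()] object.
#' @param fraction fraction of frames removed per end, in `[0, 0.5)`
#'   (default 0.05).
#' @return A shortened `bold_ts`.
#' @export
trim_edges <- function(ts, fraction = 0.05) {
  stopifnot(inherits(ts, "bold_ts"), fraction >= 0, fraction < 0.5)
  T <- nrow(ts$data)
  k <- floor(fraction * T)
  if (T - 2 * k < 2L)
    stop("trimming would leave fewer than 2 frames", call. = FALSE)
  if (k == 0L) return(ts)
  bold_timeseries(ts$data[(k + 1L):(T - k), , drop = FALSE],
                  ts$tr_seconds, ts$region_labels,
                  ts$subject_id, ts$condition)
}

#' Build the time-by-time spatial-pattern training set
#'
#' Concatenates frames across recordings into one K x N pattern matrix
#' (each row is one time frame's spatial pattern), optionally z-scores each
#' region using training-set statistics, and splits train/test at the subject
#' level: all frames of a held-out subject go to the test set.
#'
#' @param series list of [bold_timeseries()] objects sharing N regions.
#' @param train_frac fraction of subjects assigned to training (default 0.9).
#' @param normalize z-score each region on training-frame statistics
#'   (default TRUE); the per-region mean/SD are stored so the transform is
#'   invertible.
#' @param seed integer seed for the subject shuffle; `NULL` uses the current
#'   RNG stream.
#' @return An object of class `pattern_set` with elements `patterns` (K x N),
#'   `train_mask`, `subject`, `condition`, `normalization`.
#' @export
build_pattern_set <- function(series, train_frac = 0.9, normalize = TRUE,
                              seed = NULL) {
  stopifnot(is.list(series), length(series) >= 1L,
            train_frac > 0, train_frac < 1)
  if (!all(vapply(series, inherits, TRUE, "bold_ts")))
    stop("'series' must be a list of bold_ts objects", call. = FALSE)
  ns <- vapply(series, function(s) ncol(s$data), 1L)
  if (length(unique(ns)) != 1L)
    stop("all series must share the same number of regions", call. = FALSE)
  subj <- vapply(series, function(s) s$subject_id, "")
  if (any(!nzchar(subj)))
    subj[!nzchar(subj)] <- sprintf("S%03d", which(!nzchar(subj)))
  patterns <- do.call(rbind, lapply(series, function(s) s$data))
  frame_subj <- rep(subj, vapply(series, function(s) nrow(s$data), 1L))
  frame_cond <- rep(vapply(series, function(s) s$condition, ""),
                    vapply(series, function(s) nrow(s$data), 1L))

  set_seed_if(seed)
  subjects <- unique(subj)
  n_test <- max(1L, round((1 - train_frac) * length(subjects)))
  if (n_test >= length(subjects))
    stop("train_frac leaves no training subjects", call. = FALSE)
  test_subjects <- sample(subjects, n_test)
  train_mask <- !(frame_subj %in% test_subjects)

  normalization <- NULL
  if (normalize) {
    mu <- colMeans(patterns[train_mask, , drop = FALSE])
    sdv <- apply(patterns[train_mask, , drop = FALSE], 2L, sd)
    sdv[sdv == 0] <- 1
    patterns <- sweep(sweep(patterns, 2L, mu, "-"), 2L, sdv, "/")
    normalization <- list(center = mu, scale = sdv)
  }
  structure(
    list(patterns = patterns, train_mask = train_mask,
         subject = frame_subj, condition = frame_cond,
         normalization = normalization, test_subjects = test_subjects),
    class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> %d frames x %d regions (%d train / %d test), %s\n",
              nrow(x$patterns), ncol(x$patterns), sum(x$train_mask),
              sum(!x$train_mask),
              if (is.null(x$normalization)) "raw" else "z-scored"))
  invisible(x)
}

# Apply / invert a stored per-region normalization.
apply_normalization <- function(x, normalization) {
  if (is.null(normalization)) return(x)
  sweep(sweep(x, 2L, normalization$center, "-"), 2L, normalization$scale, "/")
}

invert_normalization <- function(x, normalization) {
  if (is.null(normalization)) return(x)
  sweep(sweep(x, 2L, normalization$scale, "*"), 2L, normalization$center, "+")
}
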