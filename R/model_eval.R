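#' Learning curves
#'
#' A `learning_curve` is a data-frame-like object with a 1-based reporting
#' index `x`, a value `y` (proportion correct in [0, 1], or episode length),
#' and optionally a per-point standard error of the mean `sem` and the
#' number of runs `n_runs` that were averaged.
#'
#' @param x index vector (1-based for reporting).
#' @param y value vector, same length as `x`.
#' @param sem optional SEM vector.
#' @param n_runs number of runs averaged into `y`.
#' @return a `learning_curve` object.
#' @export
learning_curve <- function(x, y, sem = NULL, n_runs = 1L) {
  stopifnot(length(x) == length(y),
            is.null(sem) || length(sem) == length(y))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 sem = if (is.null(sem)) rep(NA_real_, length(y)) else sem,
                 n_runs = as.integer(n_runs)),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("<learning_curve> ", length(x$y), " points, n_runs=", x$n_runs,
      ", range [", round(min(x$y), 3), ", ", round(max(x$y), 3), "]\n",
      sep = "")
  invisible(x)
}

#' Sliding-window proportion correct
#'
#' Convolves a binary correctness sequence with a flat kernel that averages
#' `window` trials at a time. Default edge handling is "valid": the first
#' output point corresponds to trial `window` (curves start once a full
#' window is available). `"trailing"` mode instead averages over
#' `min(t, window)` trials so the curve has one point per trial.
#'
#' @param correctness numeric/logical vector of 0/1 outcomes.
#' @param window kernel width in trials (default 10).
#' @param mode `"valid"` or `"trailing"`.
#' @return a `learning_curve`; for `"valid"` mode `x` runs from `window` to
#'   `length(correctness)`.
#' @export
sliding_proportion_correct <- function(correctness, window = 10L,
                                       mode = c("valid", "trailing")) {
  mode <- match.arg(mode)
  correctness <- as.numeric(correctness)
  n <- length(correctness)
  stopifnot(window >= 1L)
  if (n < window) stop("sequence shorter than the averaging window")
  cs <- cumsum(c(0, correctness))
  if (mode == "valid") {
    y <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
    learning_curve(x = window:n, y = y)
  } else {
    w <- pmin(seq_len(n), window)
    lo <- seq_len(n) - w
    y <- (cs[seq_len(n) + 1L] - cs[lo + 1L]) / w
    learning_curve(x = seq_len(n), y = y)
  }
}

#' Average several runs' curves into a mean curve with SEM
#'
#' @param ys a list of equal-length numeric vectors (one per run) or a
#'   matrix with one row per run.
#' @param x optional index; defaults to 1..ncol.
#' @return a `learning_curve` with per-point mean and SEM.
#' @export
average_curves <- function(ys, x = NULL) {
  mat <- if (is.matrix(ys)) ys else do.call(rbind, ys)
  if (is.null(x)) x <- seq_len(ncol(mat))
  m <- colMeans(mat)
  sem <- apply(mat, 2L, stats::sd) / sqrt(nrow(mat))
  learning_curve(x, m, sem, n_runs = nrow(mat))
}

#' Episode-length learning curve
#'
#' @param lengths integer vector of per-episode action counts.
#' @param truncated optional logical vector marking truncated episodes.
#' @return a `learning_curve` (x = episode number, 1-based) carrying a
#'   `truncated` attribute.
#' @export
episode_length_curve <- function(lengths, truncated = NULL) {
  cv <- learning_curve(seq_along(lengths), lengths)
  attr(cv, "truncated") <- if (is.null(truncated)) {
    rep(FALSE, length(lengths))
  } else {
    truncated
  }
  cv
}

#' Residual sum of squares between two curves
#'
#' Curves of unequal length are compared on their common support (the
#' shorter length); a message notes the truncation.
#'
#' @param curve_a,curve_b `learning_curve` objects or plain numeric vectors.
#' @return `sum((a - b)^2)` over the common support.
#' @export
rss <- function(curve_a, curve_b) {
  a <- if (inherits(curve_a, "learning_curve")) curve_a$y else as.numeric(curve_a)
  b <- if (inherits(curve_b, "learning_curve")) curve_b$y else as.numeric(curve_b)
  n <- min(length(a), length(b))
  if (n == 0L) stop("curves have empty overlap")
  if (length(a) != length(b)) {
    message("rss: curves truncated to common support of ", n, " points")
  }
  sum((a[seq_len(n)] - b[seq_len(n)])^2)
}

#' Corrected Akaike information criterion for least-squares fits
#'
#' Gaussian-residual form:
#' \eqn{AICc = n \ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param rss_value residual sum of squares (> 0).
#' @param n number of compared points (must exceed `k + 1`).
#' @param k number of free parameters (>= 0).
#' @return the AICc value.
#' @export
aicc <- function(rss_value, n, k) {
  stopifnot(k >= 0)
  if (n <= k + 1) stop("AICc undefined: need n > k + 1")
  if (rss_value <= 0) stop("AICc undefined for RSS <= 0 (perfect fit)")
  n * log(rss_value / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank models against a reference curve by AICc
#'
#' @param reference the reference `learning_curve` (surrogate-human data).
#' @param models named list of model `learning_curve`s.
#' @param k named integer vector of free-parameter counts (same names).
#' @return a data frame with columns model, k, rss, n, aicc, sorted by
#'   ascending AICc (a perfect fit, RSS = 0, is reported with `aicc = -Inf`
#'   and ranks first); ties in AICc are flagged in the `tied` column.
#' @export
compare_models <- function(reference, models, k) {
  stopifnot(length(models) >= 2L, !is.null(names(models)),
            all(names(models) %in% names(k)))
  rows <- lapply(names(models), function(nm) {
    r <- rss(reference, models[[nm]])
    n <- min(length(reference$y), length(models[[nm]]$y))
    a <- if (r > 0) aicc(r, n, k[[nm]]) else -Inf
    data.frame(model = nm, k = k[[nm]], rss = r, n = n, aicc = a)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aicc, out$k), ]
  out$tied <- duplicated(out$aicc) | duplicated(out$aicc, fromLast = TRUE)
  rownames(out) <- NULL
  out
}

#' Write a learning curve as CSV
#'
#' Columns: index, value, sem, n_runs.
#'
#' @param curve a `learning_curve`.
#' @param path output file.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(index = curve$x, value = curve$y,
                              sem = curve$sem, n_runs = curve$n_runs),
                   path, row.names = FALSE)
}

#' Read a learning curve written by [write_curve()]
#'
#' @param path CSV file.
#' @return a `learning_curve`.
#' @export
read_curve <- function(path) {
  d <- utils::read.csv(path)
  learning_curve(d$index, d$value, d$sem, n_runs = d$n_runs[1L])
}
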