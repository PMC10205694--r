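#' Multi-spin-lock image series
#'
#' Container for a stack of co-registered magnitude images acquired at
#' increasing spin-lock times (T1rho mapping) or echo times (T2 mapping).
#' The acquisition axis is the fourth array dimension.
#'
#' @param signals 4-D non-negative intensity array with dimensions
#'   `(slice, row, column, acquisition)`.
#' @param tsl_ms strictly increasing, non-negative spin-lock (or echo) times
#'   in milliseconds; length must equal `dim(signals)[4]`.
#' @param spacing_mm numeric length-3 voxel spacing `(slice, row, column)` in mm.
#' @param modality_tag `"T1rho"` or `"T2"`.
#' @return An object of class `spin_lock_series`.
#' @export
spin_lock_series <- function(signals, tsl_ms, spacing_mm = c(4, 1, 1),
                             modality_tag = c("T1rho", "T2")) {
  modality_tag <- match.arg(modality_tag)
  if (length(dim(signals)) != 4L)
    stop("`signals` must be a 4-D array (slice, row, column, acquisition)")
  check_tsl(tsl_ms)
  if (dim(signals)[4] != length(tsl_ms))
    stop("acquisition axis length (", dim(signals)[4],
         ") does not match length(tsl_ms) (", length(tsl_ms), ")")
  if (length(tsl_ms) < 2L)
    stop("at least 2 acquisitions are required (>= 3 for routine use)")
  if (any(signals < 0)) stop("`signals` must be non-negative")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive values")
  structure(list(signals = signals, tsl_ms = as.numeric(tsl_ms),
                 spacing_mm = as.numeric(spacing_mm),
                 modality_tag = modality_tag),
            class = "spin_lock_series")
}

#' @export
print.spin_lock_series <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf("<spin_lock_series> %s, %d x %d x %d voxels, %d acquisitions\n",
              x$modality_tag, d[1], d[2], d[3], d[4]))
  cat("  times (ms):", paste(x$tsl_ms, collapse = ", "), "\n")
  invisible(x)
}

check_tsl <- function(tsl_ms) {
  if (!is.numeric(tsl_ms) || anyNA(tsl_ms))
    stop("`tsl_ms` must be numeric without NA")
  if (any(tsl_ms < 0)) stop("`tsl_ms` must be non-negative")
  if (any(diff(tsl_ms) <= 0)) stop("`tsl_ms` must be strictly increasing")
  invisible(tsl_ms)
}

#' Relaxometry fitting configuration
#'
#' @param t_min,t_max clamp bounds (ms) for the fitted relaxation time.
#'   Fits landing on a bound are flagged invalid.
#' @param noise_sigma estimate of the background noise standard deviation on
#'   the magnitude images. Voxels with mean signal below
#'   `noise_threshold_factor * noise_sigma` are not fitted. `0` disables
#'   background masking.
#' @param noise_threshold_factor multiplier on `noise_sigma` for masking.
#' @param n_grid number of log-spaced points in the coarse profile-likelihood
#'   scan that brackets the 1-D refinement.
#' @return A list of class `relax_config`.
#' @export
relax_config <- function(t_min = 1, t_max = 500, noise_sigma = 0,
                         noise_threshold_factor = 3, n_grid = 200L) {
  if (t_min <= 0 || t_max <= t_min) stop("need 0 < t_min < t_max")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(t_min = t_min, t_max = t_max, noise_sigma = noise_sigma,
                 noise_threshold_factor = noise_threshold_factor,
                 n_grid = as.integer(n_grid)),
            class = "relax_config")
}

# Profiled residual sum of squares of the mono-exponential model
# S(t) = S0 * exp(-TSL / T) for a matrix of series Y (n voxels x m times),
# with S0 solved in closed form for each candidate T.  Returns the n x k
# SSE matrix for k candidate relaxation times.
profiled_sse <- function(Y, tsl_ms, t_candidates) {
  E <- exp(outer(-tsl_ms, 1 / t_candidates))      # m x k
  A <- colSums(E * E)                              # k
  B <- Y %*% E                                     # n x k
  C <- rowSums(Y * Y)                              # n
  sweep(-sweep(B * B, 2L, A, `/`), 1L, C, `+`)     # C - B^2/A
}

# scalar profiled SSE for one series, used by the 1-D refinement
profiled_sse1 <- function(y, tsl_ms, t) {
  e <- exp(-tsl_ms / t)
  sum(y * y) - sum(y * e)^2 / sum(e * e)
}

#' Fit the mono-exponential decay model to one voxel's signal series
#'
#' Estimates `S0` and the relaxation time `T` (ms) of
#' `SI(TSL) = S0 * exp(-TSL / T)` by least squares.  The amplitude is
#' profiled out in closed form (it enters linearly for fixed `T`), so the fit
#' reduces to a 1-D minimisation over `T`: a coarse log-spaced scan over the
#' clamp interval locates the basin and `stats::optimize()` refines it.  This
#' finds the global least-squares solution within the clamp without
#' requiring a starting value.
#'
#' @param signals non-negative signal intensities, one per acquisition.
#' @param tsl_ms spin-lock (or echo) times in ms, strictly increasing, same
#'   length as `signals`.  Two-point series are solved by the exact
#'   log-ratio closed form; routine use requires >= 3 points.
#' @param config a [relax_config()].
#' @return list with `s0`, `t_ms`, `fit_r2` (coefficient of determination of
#'   the decay fit, `<= 1`), and `valid`.  `valid` is `FALSE` when the mean
#'   signal is below the noise threshold, the fit is degenerate, or the
#'   relaxation time lands on a clamp bound.
#' @examples
#' fit_monoexponential(c(100, 100 * exp(-1)), c(0, 100))$t_ms  # exactly 100
#' @export
fit_monoexponential <- function(signals, tsl_ms, config = relax_config()) {
  if (length(signals) != length(tsl_ms))
    stop("`signals` and `tsl_ms` must have the same length")
  check_tsl(tsl_ms)
  if (length(signals) < 2L) stop("need at least 2 points")
  if (!all(is.finite(signals))) stop("`signals` must be finite")

  if (length(signals) == 2L) return(fit_two_point(signals, tsl_ms, config))

  ans <- fit_series_matrix(matrix(signals, nrow = 1L), tsl_ms, config)
  lapply(ans, `[`, 1L)
}

# exact two-point log-ratio solution (testing path)
fit_two_point <- function(signals, tsl_ms, config) {
  if (signals[1] > 0 && signals[2] > 0 && signals[2] < signals[1]) {
    t_ms <- (tsl_ms[2] - tsl_ms[1]) / log(signals[1] / signals[2])
    s0 <- signals[1] * exp(tsl_ms[1] / t_ms)
    clamped <- t_ms <= config$t_min || t_ms >= config$t_max
    t_ms <- min(max(t_ms, config$t_min), config$t_max)
    valid <- !clamped &&
      mean(signals) >= config$noise_threshold_factor * config$noise_sigma
    list(s0 = s0, t_ms = t_ms, fit_r2 = 1, valid = valid)
  } else {
    list(s0 = signals[1], t_ms = config$t_max, fit_r2 = -Inf, valid = FALSE)
  }
}

# Vectorised fit of many series (rows of Y) sharing one TSL grid.
# Each series is normalised by its mean first, which makes the estimated
# relaxation time exactly invariant to rescaling the signal.
fit_series_matrix <- function(Y, tsl_ms, config = relax_config()) {
  n <- nrow(Y)
  m <- length(tsl_ms)
  sig_scale <- rowMeans(Y)
  mean_signal <- sig_scale
  sig_scale[sig_scale <= 0] <- 1
  Y <- Y / sig_scale
  grid <- exp(seq(log(config$t_min), log(config$t_max),
                  length.out = config$n_grid))
  sse <- profiled_sse(Y, tsl_ms, grid)
  k <- max.col(-sse, ties.method = "first")

  t_hat <- numeric(n)
  sse_hat <- numeric(n)
  for (i in seq_len(n)) {
    lo <- grid[max(k[i] - 1L, 1L)]
    hi <- grid[min(k[i] + 1L, length(grid))]
    if (hi - lo < sqrt(.Machine$double.eps)) {
      t_hat[i] <- grid[k[i]]; sse_hat[i] <- sse[i, k[i]]
    } else {
      opt <- stats::optimize(function(t) profiled_sse1(Y[i, ], tsl_ms, t),
                             lower = lo, upper = hi, tol = 1e-8)
      if (opt$objective <= sse[i, k[i]]) {
        t_hat[i] <- opt$minimum; sse_hat[i] <- opt$objective
      } else {
        t_hat[i] <- grid[k[i]]; sse_hat[i] <- sse[i, k[i]]
      }
    }
  }
  e_hat <- exp(outer(-tsl_ms, 1 / t_hat))          # m x n
  s0 <- sig_scale * colSums(t(Y) * e_hat) / colSums(e_hat * e_hat)
  sst <- rowSums(sweep(Y, 1L, rowMeans(Y))^2)
  fit_r2 <- ifelse(sst > 0, 1 - pmax(sse_hat, 0) / sst, -Inf)

  # clamp detection uses the refinement resolution, not exact equality
  eps <- 1e-3
  at_clamp <- t_hat <= config$t_min * (1 + eps) |
              t_hat >= config$t_max * (1 - eps)
  low_signal <- mean_signal < config$noise_threshold_factor * config$noise_sigma
  valid <- is.finite(t_hat) & is.finite(s0) & !at_clamp & !low_signal
  list(s0 = s0, t_ms = t_hat, fit_r2 = fit_r2, valid = valid)
}

#' Compute a voxel-wise relaxation-time map
#'
#' Applies [fit_monoexponential()] to every in-mask voxel whose
#' first-acquisition signal exceeds the noise threshold.  Out-of-mask and
#' sub-threshold voxels are marked invalid and carry `NA` (never silent
#' zeros) in the parameter volumes.
#'
#' @param series a [spin_lock_series()].
#' @param mask optional logical/0-1 array matching the spatial dimensions of
#'   `series`; `NULL` fits every voxel passing the noise threshold.
#' @param config a [relax_config()].
#' @return An object of class `relaxation_map`: arrays `s0`, `t_ms`,
#'   `fit_r2`, `valid` over `(slice, row, column)`, plus `spacing_mm` and
#'   `modality_tag`.
#' @export
fit_map <- function(series, mask = NULL, config = relax_config()) {
  stopifnot(inherits(series, "spin_lock_series"))
  d <- dim(series$signals)
  sp <- d[1:3]
  if (!is.null(mask)) {
    if (!identical(as.integer(dim(mask)), as.integer(sp)))
      stop("mask dimensions do not match the series' spatial dimensions")
    mask <- array(as.logical(mask), dim = sp)
    if (!any(mask)) stop("mask is empty")
  } else {
    mask <- array(TRUE, dim = sp)
  }

  nvox <- prod(sp)
  Ymat <- matrix(series$signals, nrow = nvox)   # voxels x acquisitions
  thr <- config$noise_threshold_factor * config$noise_sigma
  idx <- which(as.vector(mask) & Ymat[, 1L] > thr)

  t_ms <- array(NA_real_, sp); s0 <- array(NA_real_, sp)
  fit_r2 <- array(NA_real_, sp); valid <- array(FALSE, sp)
  if (length(idx)) {
    fits <- fit_series_matrix(Ymat[idx, , drop = FALSE], series$tsl_ms, config)
    t_ms[idx] <- fits$t_ms; s0[idx] <- fits$s0
    fit_r2[idx] <- fits$fit_r2; valid[idx] <- fits$valid
  }
  if (!any(valid))
    warning("relaxation map contains no valid voxels")
  structure(list(s0 = s0, t_ms = t_ms, fit_r2 = fit_r2, valid = valid,
                 spacing_mm = series$spacing_mm,
                 modality_tag = series$modality_tag),
            class = "relaxation_map")
}

#' @export
print.relaxation_map <- function(x, ...) {
  cat(sprintf("<relaxation_map> %s, %s voxels, %d valid\n", x$modality_tag,
              paste(dim(x$t_ms), collapse = " x "), sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  t_ms over valid voxels: %.1f - %.1f (median %.1f)\n",
                min(x$t_ms[x$valid]), max(x$t_ms[x$valid]),
                stats::median(x$t_ms[x$valid])))
  invisible(x)
}
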