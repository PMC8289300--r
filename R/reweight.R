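# Tiwary-Parrinello reweighting of well-tempered (parallel-bias)
# metadynamics runs: bias reconstruction on a grid, the time-dependent
# offset c(t), frame weights, weighted distributions / free-energy
# surfaces, and drift-based convergence checks.

#' Reconstruct the bias potential on a grid
#'
#' Sums the Gaussians deposited up to time `t`. Hill heights are the
#' heights actually deposited (already scaled by the well-tempering
#' factor at deposition time), as written by production engines.
#'
#' @param hills data.frame with columns `time` (ps), `center`, `sigma`,
#'   `height` (kJ/mol), e.g. from [read_hills()] or a
#'   [sample_metad_double_well()] run.
#' @param grid numeric grid of CV values; should cover every hill
#'   centre plus a few sigma.
#' @param t only hills with `time <= t` contribute (default all).
#' @return numeric V(s) on the grid, kJ/mol.
#' @export
bias_on_grid <- function(hills, grid, t = Inf) {
  V <- numeric(length(grid))
  keep <- which(hills$time <= t)
  for (i in keep)
    V <- V + hills$height[i] *
      exp(-(grid - hills$center[i])^2 / (2 * hills$sigma[i]^2))
  V
}

#' Time-dependent reweighting offset c(t)
#'
#' c(t) = kT * ln( int exp(gamma V / ((gamma-1) kT)) ds /
#'                 int exp(V / ((gamma-1) kT)) ds ),
#' evaluated by trapezoidal quadrature on the grid after each hill
#' deposition. Under well-tempered deposition c(t) is non-decreasing
#' and converges to the reversible-work offset of the bias.
#'
#' @param hills hill table (see [bias_on_grid()]).
#' @param grid quadrature grid; hill centres must lie well inside it.
#' @param bias_factor well-tempering factor gamma.
#' @param kT thermal energy (kJ/mol).
#' @return data.frame `time`, `ct` (kJ/mol), one row per deposition.
#' @export
estimate_ct <- function(hills, grid, bias_factor, kT) {
  ng <- length(grid)
  if (ng < 50) stop("grid too coarse for stable quadrature; use >= 50 points")
  if (max(hills$sigma) < 2 * (grid[2] - grid[1]))
    stop("grid too coarse for stable quadrature: spacing exceeds sigma/2")
  gm1 <- (bias_factor - 1) * kT
  V <- numeric(ng)
  ct <- numeric(nrow(hills))
  for (i in seq_len(nrow(hills))) {
    V <- V + hills$height[i] *
      exp(-(grid - hills$center[i])^2 / (2 * hills$sigma[i]^2))
    a <- bias_factor * V / gm1
    b <- V / gm1
    ct[i] <- kT * (log_trapz(a, grid) - log_trapz(b, grid))
  }
  data.frame(time = hills$time, ct = ct)
}

# log of the trapezoid integral of exp(logf) over x, overflow-safe
log_trapz <- function(logf, x) {
  m <- max(logf)
  w <- exp(logf - m)
  n <- length(x)
  m + log(sum((w[-1] + w[-n]) / 2 * diff(x)))
}

#' Tiwary-Parrinello frame weights
#'
#' w_t proportional to exp( (V(s_t, t) - c(t)) / kT ), normalized to
#' mean 1. c(t) is carried to frame times as a step function of the
#' deposition series (0 before the first hill).
#'
#' @param bias numeric per-frame instantaneous bias V(s_t, t), kJ/mol.
#' @param times per-frame times (ps), same length as `bias`.
#' @param ct data.frame `time`, `ct` from [estimate_ct()]; NULL for an
#'   unbiased run (all c = 0).
#' @param kT thermal energy (kJ/mol).
#' @return numeric weights, mean 1.
#' @export
frame_weights <- function(bias, times, ct = NULL, kT) {
  if (length(bias) != length(times))
    stop("bias and times are misaligned: lengths differ")
  cvals <- if (is.null(ct) || nrow(ct) == 0) rep(0, length(times)) else {
    approx(x = c(-Inf, ct$time), y = c(0, ct$ct), xout = times,
           method = "constant", rule = 2)$y
  }
  logw <- (bias - cvals) / kT
  w <- exp(logw - max(logw))
  w / mean(w)
}

#' Weighted probability distribution of a collective variable
#'
#' @param cv_values per-frame CV values.
#' @param weights per-frame weights (default uniform).
#' @param bins number of bins or an explicit vector of bin edges.
#' @return object of class `cdx_weighted_distribution`: `bin_edges`,
#'   `bin_centers`, `probability` (sums to 1), `effective_sample_size`.
#' @export
weighted_distribution <- function(cv_values, weights = NULL, bins = 50) {
  n <- length(cv_values)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("cv_values and weights lengths differ")
  if (all(weights == 0)) stop("all weights are zero")
  edges <- if (length(bins) > 1) bins else
    seq(min(cv_values), max(cv_values), length.out = bins + 1L)
  b <- findInterval(cv_values, edges, rightmost.closed = TRUE,
                    all.inside = TRUE)
  p <- vapply(seq_len(length(edges) - 1L),
              function(i) sum(weights[b == i]), numeric(1))
  p <- p / sum(p)
  structure(list(bin_edges = edges,
                 bin_centers = (edges[-1L] + edges[-length(edges)]) / 2,
                 probability = p,
                 effective_sample_size = sum(weights)^2 / sum(weights^2)),
            class = "cdx_weighted_distribution")
}

#' Free-energy surface from a weighted distribution
#'
#' F = -kT ln p per bin, shifted so the minimum is 0; empty bins are NA.
#'
#' @param dist a [weighted_distribution()].
#' @param kT thermal energy (kJ/mol).
#' @return data.frame `cv`, `fes` (kJ/mol, NA where undefined).
#' @export
fes <- function(dist, kT) {
  stopifnot(inherits(dist, "cdx_weighted_distribution"))
  f <- ifelse(dist$probability > 0, -kT * log(dist$probability), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  data.frame(cv = dist$bin_centers, fes = f)
}

#' Reweighted free-energy surface of a toy metadynamics run
#'
#' Convenience wrapper: c(t) from the run's hills, Tiwary-Parrinello
#' frame weights, weighted histogram, F = -kT ln p. Several runs
#' (multiple walkers) may be given; their frames are pooled after
#' per-walker weighting, before histogramming.
#'
#' @param runs one `cdx_toyrun` or a list of them.
#' @param bins histogram bins (count or edge vector).
#' @param burnin_fraction initial fraction of each run discarded before
#'   histogramming (transient before the bias stabilises).
#' @return list(fes = data.frame(cv, fes), dist, weights).
#' @export
toyrun_fes <- function(runs, bins = seq(-1.6, 1.6, by = 0.08),
                       burnin_fraction = 0.2) {
  if (inherits(runs, "cdx_toyrun")) runs <- list(runs)
  cv <- numeric(0); w <- numeric(0)
  for (run in runs) {
    keep <- seq.int(floor(length(run$time) * burnin_fraction) + 1L,
                    length(run$time))
    ct <- if (nrow(run$hills)) estimate_ct(run$hills, run$grid,
                                           run$params$bias_factor,
                                           run$params$kT) else NULL
    wk <- frame_weights(run$bias[keep], run$time[keep], ct, run$params$kT)
    cv <- c(cv, run$position[keep])
    w <- c(w, wk)
  }
  dist <- weighted_distribution(cv, w, bins)
  list(fes = fes(dist, runs[[1]]$params$kT), dist = dist, weights = w)
}

#' Convergence drift of collective-variable series
#'
#' For each column, the absolute difference between the mean over the
#' last `fraction` of the series and the mean over the preceding window
#' of equal length, with a block standard error for scale (10 blocks
#' per window, 5 for short windows).
#'
#' @param cv_series numeric vector, matrix or data.frame (columns = CVs).
#' @param fraction trailing fraction defining the window (default 0.10).
#' @return data.frame `cv`, `drift`, `block_se`.
#' @export
convergence_drift <- function(cv_series, fraction = 0.10) {
  X <- as.matrix(cv_series)
  n <- nrow(X)
  w <- floor(n * fraction)
  if (w < 2 || n < 2 * w) stop("series shorter than two windows of the given fraction")
  i_last <- (n - w + 1L):n
  i_prev <- (n - 2L * w + 1L):(n - w)
  block_se <- function(v) {
    nb <- if (length(v) >= 30L) 10L else 5L
    bl <- split(v, cut(seq_along(v), nb, labels = FALSE))
    bm <- vapply(bl, mean, numeric(1))
    sqrt(stats::var(bm) / nb)
  }
  out <- lapply(seq_len(ncol(X)), function(j) {
    d <- abs(mean(X[i_last, j]) - mean(X[i_prev, j]))
    se <- sqrt(block_se(X[i_last, j])^2 + block_se(X[i_prev, j])^2)
    data.frame(cv = colnames(X)[j] %||% paste0("cv", j),
               drift = d, block_se = se)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
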