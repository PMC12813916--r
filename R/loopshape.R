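#' Time-normalized pressure-strain loop
#'
#' Resamples one subject's pressure-strain loop to 1000 points, as four
#' piecewise-linear segments of 250 uniformly spaced samples between
#' consecutive valve events: MVC to AVO, AVO to AVC, AVC to MVO, and MVO to
#' end of cycle (wrapping back to MVC). The segment boundaries therefore sit
#' at (1-based) indices 1, 251, 501 and 751 and equal the linear
#' interpolants of each axis at the four event times.
#'
#' @param strain A [strain_trace()].
#' @param pressure A [pressure_curve()].
#' @param events A [valve_events()] object.
#' @param cycle_length Cycle length in ms (defaults to the pressure curve's
#'   attribute).
#' @return An object of class `resampled_loop`: a 1000 x 2 matrix with
#'   columns `strain` and `pressure`, with `boundaries` and `events`
#'   attributes.
#' @export
resample_loop <- function(strain, pressure, events,
                          cycle_length = attr(pressure, "cycle_length")) {
  stopifnot(inherits(strain, "strain_trace"), inherits(pressure, "pressure_curve"))
  events <- check_events_in_cycle(events, cycle_length)
  if (events$mvc < min(strain$time) || events$mvc < min(pressure$time))
    stopf("valve events lie outside the signal support")
  bounds <- c(events$mvc, events$avo, events$avc, events$mvo,
              events$mvc + cycle_length)
  tt <- unlist(lapply(1:4, function(k)
    seq(bounds[k], bounds[k + 1L], length.out = 251L)[1:250]))
  s <- interp_linear(strain$time, strain$strain, tt, period = cycle_length)
  p <- interp_linear(pressure$time, pressure$pressure, tt, period = cycle_length)
  m <- cbind(strain = s, pressure = p)
  structure(m, class = "resampled_loop",
            boundaries = c(1L, 251L, 501L, 751L), events = events,
            time = tt)
}

# Accept a resampled_loop, a mean_loop or a plain 2-column matrix.
loop_coords <- function(x) {
  if (inherits(x, "mean_loop")) return(x$mean)
  m <- unclass(x)
  if (!is.matrix(m) || ncol(m) != 2L)
    stopf("expected a resampled loop, mean loop, or a 2-column matrix")
  m
}

#' Pointwise mean loop with variability band
#'
#' Averages a set of time-normalized loops pointwise per axis and attaches a
#' per-point band of marginal standard deviations, taken from the diagonal of
#' the per-point 2 x 2 covariance of (strain, pressure) across loops. The
#' mean of a single loop is the loop itself with a zero band.
#'
#' @param loops A list of [resample_loop()] results (equal point counts).
#' @return An object of class `mean_loop`: list with `mean` (n x 2 matrix),
#'   `band` (n x 2 matrix of SDs) and `n`.
#' @export
mean_loop <- function(loops) {
  if (!is.list(loops) || length(loops) == 0L)
    stopf("'loops' must be a non-empty list of resampled loops")
  mats <- lapply(loops, loop_coords)
  np <- nrow(mats[[1L]])
  if (!all(vapply(mats, nrow, 0L) == np))
    stopf("all loops must have the same number of points")
  k <- length(mats)
  flat <- vapply(mats, as.numeric, numeric(2L * np))
  mu <- matrix(rowMeans(flat), np, 2L)
  band <- if (k == 1L) matrix(0, np, 2L)
  else matrix(apply(flat, 1L, stats::sd), np, 2L)
  colnames(mu) <- colnames(band) <- c("strain", "pressure")
  structure(list(mean = mu, band = band, n = k), class = "mean_loop")
}

#' Dynamic time warping distance between loops
#'
#' Classical DTW cumulative cost between two loops regarded as sequences of
#' (strain, pressure) points, with per-step Euclidean distance in the plane,
#' boundary-matched endpoints and an unconstrained (full-cycle) warping
#' path. By default distances are taken in raw units (percent and mmHg);
#' `standardize = TRUE` z-scores each axis using the pooled mean and SD of
#' both loops first, for users who prefer unit-balanced matching. The cost
#' is not path-length normalized unless `normalize = TRUE`.
#'
#' @param a,b Loops ([resample_loop()], [mean_loop()] or 2-column matrices).
#' @param standardize Z-score both axes with pooled statistics before
#'   matching (default `FALSE`).
#' @param normalize Divide the cumulative cost by the summed sequence
#'   lengths (default `FALSE`).
#' @return A non-negative cost (0 for identical loops).
#' @export
dtw_distance <- function(a, b, standardize = FALSE, normalize = FALSE) {
  A <- loop_coords(a); B <- loop_coords(b)
  if (standardize) {
    pool <- rbind(A, B)
    for (k in 1:2) {
      s <- stats::sd(pool[, k])
      if (s == 0) s <- 1
      mu <- mean(pool[, k])
      A[, k] <- (A[, k] - mu) / s
      B[, k] <- (B[, k] - mu) / s
    }
  }
  d <- dtw_cost_cpp(A[, 1L], A[, 2L], B[, 1L], B[, 2L])
  if (normalize) d <- d / (nrow(A) + nrow(B))
  d
}

#' Procrustes shape disparity between loops
#'
#' Standardized residual sum of squares after optimally superimposing one
#' loop onto the other by translation, rotation and isotropic scaling
#' (reflection excluded). Both configurations are centred and scaled to unit
#' Frobenius norm, so the disparity is dimensionless in `[0, 1]` and is
#' invariant to any proper similarity transform of either input.
#'
#' @param a,b Loops with equal point counts and nonzero spread.
#' @return The disparity (0 for similarity-equivalent loops).
#' @export
procrustes_distance <- function(a, b) {
  A <- loop_coords(a); B <- loop_coords(b)
  if (nrow(A) != nrow(B)) stopf("loops must have equal point counts")
  A <- sweep(A, 2L, colMeans(A))
  B <- sweep(B, 2L, colMeans(B))
  na <- sqrt(sum(A^2)); nb <- sqrt(sum(B^2))
  if (na == 0 || nb == 0)
    stopf("degenerate loop: zero spread, shape undefined")
  A <- A / na; B <- B / nb
  M <- crossprod(A, B)
  sv <- svd(M)
  d <- sign(det(M))
  if (d == 0) d <- 1
  tr <- sv$d[1L] + d * sv$d[2L]
  max(1 - tr^2, 0)
}

#' Permutation test for loop-shape differences between two groups
#'
#' Computes the DTW and Procrustes distances between the two group mean
#' loops, then re-derives both distances under `n_perm` random relabelings
#' that preserve group sizes. P-values are the plain proportion of permuted
#' distances greater than or equal to the observed distance (optionally with
#' add-one smoothing so p is never exactly 0). The combined p-value follows
#' the two-sided reporting rule: the larger of the two p-values for
#' age-group comparisons (conservative evidence of difference), the smaller
#' for reproducibility comparisons (conservative evidence of agreement).
#'
#' @param loops List of loops, one per subject.
#' @param labels Group labels, exactly two distinct values (pairwise
#'   comparisons only).
#' @param n_perm Number of permutations (>= 1; 10000 in the reference
#'   analysis).
#' @param seed Integer seed for the permutation stream.
#' @param mode `"age_group"` (combined p = max) or `"reproducibility"`
#'   (combined p = min).
#' @param standardize Passed to [dtw_distance()].
#' @param smoothing Use add-one smoothing `(1 + k) / (1 + n_perm)` for the
#'   p-values (default `FALSE`, the plain proportion).
#' @return An object of class `permutation_result`: observed distances,
#'   `p_dtw`, `p_procrustes`, `p_combined`, `mode`, `n_perm`, `seed`.
#' @export
permutation_test <- function(loops, labels, n_perm = 10000, seed = 1L,
                             mode = c("age_group", "reproducibility"),
                             standardize = FALSE, smoothing = FALSE) {
  mode <- match.arg(mode)
  labels <- as.factor(labels)
  if (length(labels) != length(loops))
    stopf("'labels' must have one entry per loop")
  if (nlevels(droplevels(labels)) != 2L)
    stopf("permutation test compares exactly two groups (got %d); run pairwise",
          nlevels(droplevels(labels)))
  if (!is_number(n_perm) || n_perm < 1) stopf("'n_perm' must be >= 1")
  labels <- droplevels(labels)
  mats <- lapply(loops, loop_coords)
  np <- nrow(mats[[1L]])
  flat <- vapply(mats, as.numeric, numeric(2L * np))

  group_dist <- function(lab) {
    g1 <- lab == levels(labels)[1L]
    m1 <- matrix(rowMeans(flat[, g1, drop = FALSE]), np, 2L)
    m2 <- matrix(rowMeans(flat[, !g1, drop = FALSE]), np, 2L)
    c(dtw = dtw_distance(m1, m2, standardize = standardize),
      procrustes = procrustes_distance(m1, m2))
  }

  obs <- group_dist(labels)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) group_dist(sample(labels)),
           numeric(2L))
  })
  pval <- function(stat, observed) {
    k <- sum(stat >= observed)
    if (smoothing) (1 + k) / (1 + n_perm) else k / n_perm
  }
  p_dtw <- pval(perm["dtw", ], obs[["dtw"]])
  p_pro <- pval(perm["procrustes", ], obs[["procrustes"]])
  p_comb <- if (mode == "age_group") max(p_dtw, p_pro) else min(p_dtw, p_pro)
  structure(list(observed = list(dtw = obs[["dtw"]],
                                 procrustes = obs[["procrustes"]]),
                 p_dtw = p_dtw, p_procrustes = p_pro, p_combined = p_comb,
                 mode = mode, n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("Loop-shape permutation test (%s, %d permutations)\n",
                     "  DTW %.4g (p = %.4g) | Procrustes %.4g (p = %.4g)\n",
                     "  combined p = %.4g\n"),
              x$mode, x$n_perm, x$observed$dtw, x$p_dtw,
              x$observed$procrustes, x$p_procrustes, x$p_combined))
  invisible(x)
}

#' Export a resampled loop as CSV
#'
#' @param loop A [resample_loop()] result.
#' @param path Output file (columns `index`, `strain_pct`, `pressure_mmHg`,
#'   `segment`).
#' @export
write_loop <- function(loop, path) {
  m <- loop_coords(loop)
  seg <- rep(c("ivc", "ejection", "ivr", "diastole"), each = nrow(m) / 4L)
  utils::write.csv(data.frame(index = seq_len(nrow(m)),
                              strain_pct = m[, 1L], pressure_mmHg = m[, 2L],
                              segment = seg),
                   path, row.names = FALSE)
  invisible(path)
}
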