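# Independent oracles and small fixtures used across the suite.
# Every oracle here re-derives the quantity from first principles and never
# calls the implementation it is checking.

# --- fixtures -------------------------------------------------------------

std_events <- function() valve_events(25, 80, 369, 465)

# smooth closed synthetic loop over [mvc, mvo]: strain descends and returns,
# pressure is a hump; the valve events sit exactly on the sample grid and the
# strain/pressure values coincide at MVC and MVO, so the windowed path is a
# closed sampled polygon.
make_closed_loop_signals <- function(cycle = 900, step = 2) {
  ev <- valve_events(24, 80, 368, 464)
  t <- seq(0, cycle - step, by = step)
  u <- pmin(pmax((t - ev$mvc) / (ev$mvo - ev$mvc), 0), 1)
  eps <- -20 * sin(pi * u)^2
  pr <- 10 + 110 * sin(pi * u)^2 * (1 + 0.3 * sin(2 * pi * u))
  pr <- pmax(pr, 0)
  list(strain = strain_trace(t, eps, cycle_length = cycle),
       pressure = pressure_curve(t, pr, cycle_length = cycle),
       events = ev, time = t)
}

# random smooth loop via a short Fourier series (deterministic given seed)
make_random_loop <- function(seed, n_points = 120, cycle = 909) {
  set.seed(seed)
  ev <- std_events()
  t <- seq(0, cycle - 1e-6, length.out = n_points)
  u <- 2 * pi * t / cycle
  eps <- -10 + 6 * cos(u + runif(1, 0, 2 * pi)) +
    2 * cos(2 * u + runif(1, 0, 2 * pi)) + rnorm(1, 0, 0.5)
  pr <- 70 + 40 * sin(u + runif(1, 0, 2 * pi)) +
    8 * sin(3 * u + runif(1, 0, 2 * pi))
  pr <- pmax(pr, 1)
  resample_loop(strain_trace(t, eps, cycle_length = cycle),
                pressure_curve(t, pr, cycle_length = cycle), ev,
                cycle_length = cycle)
}

# a physiologic participant loop from the package generators
make_participant_loop <- function(seed, noise_sd = 0.4) {
  set.seed(seed)
  ev <- valve_events(25 + rnorm(1, 0, 4), 80 + rnorm(1, 0, 5),
                     369 + rnorm(1, 0, 10), 465 + rnorm(1, 0, 12))
  cycle <- runif(1, 820, 1000)
  sbp <- runif(1, 105, 145)
  gls <- runif(1, -23, -16)
  p <- estimate_pressure(sbp, ev, cycle)
  s <- synth_strain_trace(gls, ev, cycle, 71, noise_sd = noise_sd,
                          seed = seed + 1000L)
  resample_loop(s, p, ev, cycle_length = cycle)
}

# sample with exactly the requested mean and SD (moment matching)
moment_matched <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  (x - mean(x)) / sd(x) * sd + mean
}

# --- oracles --------------------------------------------------------------

# shoelace signed polygon area of the closed polygon (x_i, y_i)
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  0.5 * sum(x * y[j] - x[j] * y)
}

# DTW minimal cost by exhaustive enumeration of monotone boundary-matched
# warping paths (feasible for sequences of <= ~5 points)
dtw_enumerate <- function(A, B) {
  n <- nrow(A); m <- nrow(B)
  d <- function(i, j) sqrt(sum((A[i, ] - B[j, ])^2))
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + d(i, j)
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    invisible()
  }
  recurse(1, 1, 0)
  best
}

# Procrustes disparity by grid search over rotation angle and scale after
# centering and unit-norm standardization of both configurations
procrustes_grid_oracle <- function(A, B, angle_step = 1e-3) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  A <- A / sqrt(sum(A^2)); B <- B / sqrt(sum(B^2))
  best <- Inf
  for (th in seq(0, 2 * pi, by = angle_step)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    BR <- B %*% R
    s <- sum(A * BR) # optimal scale in closed form given the angle
    err <- sum((A - s * BR)^2)
    if (err < best) best <- err
  }
  best
}

# type-7 percentile: linear interpolation between closest order statistics
quantile_type7_oracle <- function(x, p) {
  x <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# ICC(2,1) point estimate from explicitly enumerated ANOVA sums of squares
icc21_anova_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  ss_subj <- k * sum((rowMeans(x) - grand)^2)
  ss_rater <- n * sum((colMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_rater
  msr <- ss_subj / (n - 1)
  msc <- ss_rater / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
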