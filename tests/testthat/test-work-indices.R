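test_that("work rate obeys closed forms on degenerate signals", {
  t <- seq(0, 900, by = 10)
  pconst <- pressure_curve(t, rep(100, length(t)))
  # constant strain: identically zero power
  wr0 <- work_rate(strain_trace(t, rep(-10, length(t))), pconst)
  expect_true(all(wr0$power == 0))
  # linear strain, constant pressure: constant power P * slope
  wr1 <- work_rate(strain_trace(t, -0.02 * t), pconst)
  expect_equal(wr1$power, rep(100 * -0.02, nrow(wr1)), tolerance = 1e-12)
  expect_error(work_rate(strain_trace(t + 5000, rep(-1, length(t))), pconst),
               "overlap")
})

test_that("work rate matches a refined-grid finite-difference oracle", {
  cycle <- 909
  t1 <- seq(0, cycle, length.out = 181)
  t2 <- seq(0, cycle, length.out = 361) # double resolution
  epsf <- function(t) -18 * sin(pi * t / cycle)^2
  prf <- function(t) 10 + 100 * sin(pi * t / cycle)
  wr <- work_rate(strain_trace(t1, epsf(t1)), pressure_curve(t1, prf(t1)))
  oracle <- prf(t2) * c((epsf(t2[2]) - epsf(t2[1])) / diff(t2)[1],
                        (epsf(t2[-(1:2)]) - epsf(t2[1:359])) / (t2[-(1:2)] - t2[1:359]),
                        (epsf(t2[361]) - epsf(t2[360])) / diff(t2)[1])
  oi <- approx(t2, oracle, xout = wr$time)$y
  rms_rel <- sqrt(mean((wr$power - oi)^2)) / sqrt(mean(oi^2))
  expect_lt(rms_rel, 0.01)
})

test_that("GWI reproduces the rectangle loop and degenerate cases", {
  # rectangle: shorten 0 -> -20 % at P = 100, re-lengthen at P = 0
  ev <- valve_events(0, 100, 300, 600)
  t <- c(0, 300, 300.0001, 600)
  s <- strain_trace(t, c(0, -20, -20, 0), cycle_length = 650)
  p <- pressure_curve(t, c(100, 100, 0, 0), cycle_length = 650)
  seg <- phase_segmentation(ev)
  expect_equal(compute_gwi(s, p, seg), 2000, tolerance = 1e-6)
  # constant strain: zero area
  sc <- strain_trace(t, rep(-10, 4), cycle_length = 650)
  expect_equal(compute_gwi(sc, p, seg), 0)
  expect_error(compute_gwi(strain_trace(c(700, 800), c(0, 0)),
                           p, seg), "not covered")
})

test_that("GWI equals the shoelace polygon area on a closed sampled loop", {
  sig <- make_closed_loop_signals()
  seg <- phase_segmentation(sig$events)
  gwi <- compute_gwi(sig$strain, sig$pressure, seg)
  # oracle: polygon area of the sampled vertices inside the window
  w <- sig$time >= sig$events$mvc & sig$time <= sig$events$mvo
  area <- shoelace_area(sig$strain$strain[w], sig$pressure$pressure[w])
  expect_equal(gwi, abs(area), tolerance = 1e-6)
})

test_that("constructive/wasted split matches restricted-integral oracles", {
  ev <- std_events()
  seg <- phase_segmentation(ev)
  cycle <- 909
  p <- estimate_pressure(124, ev, cycle)
  # strain monotone per phase, sampled on a grid containing the valve events
  # (so the piecewise-linear interpolant is exactly monotone per phase)
  tt <- sort(unique(c(seq(0, cycle - 1, by = 2.5), 25, 369, 465)))
  eps <- numeric(length(tt))
  ix <- tt >= 25 & tt <= 369
  eps[ix] <- -20 * 0.5 * (1 - cos(pi * (tt[ix] - 25) / 344))
  ix <- tt > 369 & tt <= 465
  eps[ix] <- -20 + 8 * 0.5 * (1 - cos(pi * (tt[ix] - 369) / 96))
  ix <- tt > 465
  eps[ix] <- -12 * 0.5 * (1 + cos(pi * (tt[ix] - 465) / (cycle - 465)))
  s0 <- strain_trace(tt, eps, cycle_length = cycle)
  # monotone shortening in systole, monotone lengthening in IVR: GWW = 0
  cw0 <- compute_gcw_gww(s0, p, seg)
  expect_equal(unname(cw0["gww"]), 0, tolerance = 1e-9)
  expect_gt(cw0[["gcw"]], 0)

  # add a mid-systolic lengthening blip; GWW = |trapezoid of P d(eps)| there
  tb <- c(150, 160, 170) # blip support inside systole
  blip <- ifelse(tt >= tb[1] & tt <= tb[3],
                 1.5 * (1 - abs(tt - tb[2]) / 10), 0)
  sb <- strain_trace(tt, eps + pmax(blip, 0), cycle_length = cycle)
  cwb <- compute_gcw_gww(sb, p, seg)
  # oracle: trapezoid integral of P d(eps) over intervals where eps rises
  g <- sort(unique(c(tt, p$time)))
  g <- g[g >= ev$mvc & g <= ev$avc]
  eb <- approx(tt, sb$strain, xout = g)$y
  pb <- approx(p$time, p$pressure, xout = g)$y
  dW <- (pb[-1] + pb[-length(pb)]) / 2 * diff(eb)
  expect_equal(unname(cwb["gww"]), sum(pmax(dW, 0)), tolerance = 1e-9)

  # sign-flipped trace: the classification swaps the two components
  sf <- strain_trace(sb$time, -sb$strain, cycle_length = cycle)
  cwf <- compute_gcw_gww(sf, p, seg)
  expect_equal(unname(cwf["gcw"]), unname(cwb["gww"]), tolerance = 1e-12)
  expect_equal(unname(cwf["gww"]), unname(cwb["gcw"]), tolerance = 1e-12)
})

test_that("work efficiency follows its defining ratio and contracts", {
  expect_equal(compute_gwe(2318, 0), 100)
  expect_equal(round(compute_gwe(2345, 106), 1), 95.7)
  expect_equal(compute_gwe(5, 5), 50)
  expect_warning(res <- compute_gwe(0, 0), "undefined")
  expect_true(is.na(res))
  expect_error(compute_gwe(-1, 5), "'gcw'")
})

test_that("index identities and invariances hold on random synthetic loops", {
  for (seed in 1:6) {
    set.seed(seed)
    ev <- std_events()
    cycle <- runif(1, 850, 950)
    p <- estimate_pressure(runif(1, 110, 150), ev, cycle)
    s <- synth_strain_trace(runif(1, -24, -15), ev, cycle, 71,
                            noise_sd = 0.5, seed = seed)
    seg <- phase_segmentation(ev)
    gwi <- compute_gwi(s, p, seg)
    cw <- compute_gcw_gww(s, p, seg)
    expect_true(cw["gcw"] >= 0 && cw["gww"] >= 0)
    expect_lte(abs(gwi), cw[["gcw"]] + cw[["gww"]] + 1e-9)
    # physiologic ordering: constructive work exceeds net loop area
    expect_lt(gwi, cw[["gcw"]])
    gwe <- compute_gwe(cw[["gcw"]], cw[["gww"]])
    expect_true(gwe >= 0 && gwe <= 100)

    # time-reparameterization: uniform speed-up leaves all indices unchanged
    k <- 0.5
    s2 <- strain_trace(s$time * k, s$strain, cycle_length = cycle * k)
    p2 <- pressure_curve(p$time * k, p$pressure, cycle_length = cycle * k)
    ev2 <- valve_events(ev$mvc * k, ev$avo * k, ev$avc * k, ev$mvo * k)
    seg2 <- phase_segmentation(ev2)
    expect_equal(compute_gwi(s2, p2, seg2), gwi, tolerance = 1e-9)
    expect_equal(compute_gcw_gww(s2, p2, seg2), cw, tolerance = 1e-9)
  }
})

test_that("indices converge under grid refinement", {
  ev <- std_events()
  cycle <- 909
  s <- synth_strain_trace(-19.5, ev, cycle, 71, noise_sd = 0)
  p1 <- estimate_pressure(124, ev, cycle, n_samples = 1000)
  p2 <- estimate_pressure(124, ev, cycle, n_samples = 2000)
  s2 <- synth_strain_trace(-19.5, ev, cycle, 142, noise_sd = 0)
  w1 <- work_indices(s, p1, ev)
  w2 <- work_indices(s2, p2, ev)
  expect_lt(abs(w1$gwi - w2$gwi) / abs(w2$gwi), 0.005)
  expect_lt(abs(w1$gcw - w2$gcw) / abs(w2$gcw), 0.005)
})
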