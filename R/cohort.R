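#' Synthetic cohort configuration
#'
#' Parameters of the synthetic population generator. Defaults are calibrated
#' to the published characteristics of a large healthy adult echocardiography
#' cohort: GLS -19.5 +/- 2.3 %, sitting SBP median 124 (IQR 20) mmHg, heart
#' rate median 66 (IQR 15) bpm, valve-event medians MVC 25 / AVO 80 /
#' AVC 369 / MVO 465 ms, frame rate 71 +/- 4 fps, 55 % female, GWI
#' 1975 mmHg% falling 1.45 mmHg% per year of age, GCW 2318 mmHg% rising
#' 2.32 mmHg% per year, log-normal GWW (median 104, IQR 73-146 mmHg%) with a
#' 1.1 % relative increase per year. Work-index values are drawn directly
#' from this population model (they are the reference quantities the
#' statistical stages consume), while each participant also carries a raw
#' strain trace and blood pressure from which the signal pipeline computes
#' indices independently.
#'
#' Age and sex effects are centred at the mean age / configured female
#' fraction so the marginal moments stay at their configured values
#' regardless of the slopes. A fraction `contamination_rate` of participants
#' is given exactly one quality-control violation (SBP above the exclusion
#' threshold, beat-timing mismatch above 12 ms, or heart-rate variation
#' above 30 %); clean participants are generated inside all limits, so the
#' expected excluded proportion equals the contamination rate.
#'
#' @param n Number of participants (>= 0).
#' @param seed Integer seed; participants are drawn sequentially from a
#'   single stream seeded once, making generation reproducible and the
#'   leading participants shared across cohort sizes.
#' @param age_range Uniform age range in years.
#' @param sex_fraction_female Proportion of females in `[0, 1]`.
#' @param gls_mean,gls_sd Peak GLS mean and SD, percent (negative mean).
#' @param sbp_median,sbp_iqr,sbp_shift Sitting SBP shifted log-normal:
#'   median, interquartile range and shift (floor), mmHg.
#' @param hr_median,hr_iqr,hr_shift,hr_range Heart rate shifted log-normal
#'   parameters (bpm) and the physiologic truncation range.
#' @param valve_event_medians,valve_event_jitter Named vectors (mvc, avo,
#'   avc, mvo) of event-time medians and Gaussian jitter SDs, ms.
#' @param frame_rate_mean,frame_rate_sd Acquisition frame rate, frames/s.
#' @param age_slope_gls GLS change per year of age, %/yr.
#' @param age_slope_sbp SBP change per year of age, mmHg/yr.
#' @param sex_offset_gls Additive GLS offset for females, %.
#' @param gwi_mean,gwi_sd,gcw_mean,gcw_sd Work-index population mean and
#'   residual SD, mmHg%.
#' @param age_slope_gwi,age_slope_gcw Work-index change per year, mmHg%/yr.
#' @param sex_offset_gwi,sex_offset_gcw Additive female offsets, mmHg%.
#' @param gww_log_mean,gww_log_sd,age_slope_log_gww Log-scale GWW location,
#'   scale and per-year slope (log mmHg%).
#' @param gls_sbp_correlation Correlation between the GLS and SBP
#'   innovations (the population tables publish no inter-variable
#'   correlations, so the default is 0).
#' @param strain_noise_sd Additive noise on the synthetic strain trace, %.
#' @param diastolic_floor Diastolic pressure floor handed to the pressure
#'   model, mmHg.
#' @param contamination_rate Proportion of participants generated with one
#'   QC violation, in `[0, 1]`.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n = 1239, seed = 1L,
                          age_range = c(20, 90),
                          sex_fraction_female = 0.55,
                          gls_mean = -19.5, gls_sd = 2.3,
                          sbp_median = 124, sbp_iqr = 20, sbp_shift = 70,
                          hr_median = 66, hr_iqr = 15, hr_shift = 40,
                          hr_range = c(40, 100),
                          valve_event_medians = c(mvc = 25, avo = 80,
                                                  avc = 369, mvo = 465),
                          valve_event_jitter = c(mvc = 8, avo = 10,
                                                 avc = 20, mvo = 24),
                          frame_rate_mean = 71, frame_rate_sd = 4,
                          age_slope_gls = 0.043, age_slope_sbp = 0.37,
                          sex_offset_gls = -0.9,
                          gwi_mean = 1975, gwi_sd = 300,
                          gcw_mean = 2318, gcw_sd = 300,
                          age_slope_gwi = -1.45, age_slope_gcw = 2.32,
                          sex_offset_gwi = 109, sex_offset_gcw = 61,
                          gww_log_mean = log(104), gww_log_sd = 0.514,
                          age_slope_log_gww = 0.011,
                          gls_sbp_correlation = 0,
                          strain_noise_sd = 0.3,
                          diastolic_floor = 10,
                          contamination_rate = 0.07) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  err <- function(field, msg) stopf("invalid cohort configuration field '%s': %s", field, msg)
  if (!is_number(cfg$n) || cfg$n < 0 || cfg$n != round(cfg$n))
    err("n", "must be a non-negative integer")
  if (!is_number(cfg$seed)) err("seed", "must be a single integer")
  if (!is.numeric(cfg$age_range) || length(cfg$age_range) != 2L ||
      cfg$age_range[1L] >= cfg$age_range[2L])
    err("age_range", "must be an increasing length-2 range")
  if (!is_number(cfg$sex_fraction_female) || cfg$sex_fraction_female < 0 ||
      cfg$sex_fraction_female > 1)
    err("sex_fraction_female", "must be a proportion in [0, 1]")
  if (cfg$gls_mean >= 0) err("gls_mean", "peak GLS must be negative")
  for (f in c("gls_sd", "sbp_iqr", "hr_iqr", "frame_rate_sd", "gww_log_sd",
              "gwi_sd", "gcw_sd"))
    if (!is_number(cfg[[f]]) || cfg[[f]] <= 0) err(f, "dispersion must be > 0")
  if (cfg$sbp_shift >= cfg$sbp_median) err("sbp_shift", "must lie below the median")
  if (cfg$hr_shift >= cfg$hr_median) err("hr_shift", "must lie below the median")
  m <- cfg$valve_event_medians
  if (!all(c("mvc", "avo", "avc", "mvo") %in% names(m)))
    err("valve_event_medians", "must name mvc, avo, avc, mvo")
  if (!(m[["mvc"]] < m[["avo"]] && m[["avo"]] < m[["avc"]] && m[["avc"]] < m[["mvo"]]))
    err("valve_event_medians", "must satisfy MVC < AVO < AVC < MVO")
  if (any(cfg$valve_event_jitter <= 0)) err("valve_event_jitter", "must be > 0")
  if (!is_number(cfg$contamination_rate) || cfg$contamination_rate < 0 ||
      cfg$contamination_rate > 1)
    err("contamination_rate", "must be a proportion in [0, 1]")
  if (abs(cfg$gls_sbp_correlation) > 1)
    err("gls_sbp_correlation", "must be in [-1, 1]")
  if (cfg$strain_noise_sd < 0) err("strain_noise_sd", "must be >= 0")
  invisible(cfg)
}

# sigma of a shifted log-normal matched to a target median and IQR
lognormal_sigma_from_iqr <- function(median, iqr, shift) {
  asinh(iqr / (2 * (median - shift))) / stats::qnorm(0.75)
}

r_shifted_lognormal <- function(z, median, iqr, shift) {
  sigma <- lognormal_sigma_from_iqr(median, iqr, shift)
  shift + exp(log(median - shift) + sigma * z)
}

#' Synthetic global longitudinal strain trace
#'
#' Generates a guideline-shaped smooth GLS trace for one cardiac cycle from
#' piecewise raised-cosine segments anchored at the valve events: zero strain
#' up to mitral valve closure, cosine shortening to the (negative) peak at
#' aortic valve closure (so the extremum sits between AVO and MVO with a flat
#' plateau around AVC), partial early-diastolic re-lengthening to MVO, and a
#' cosine return to zero by end of cycle. Sampled at the frame interval with
#' optional additive Gaussian noise.
#'
#' @param peak_gls Peak (most negative) strain, percent; must be negative.
#' @param valve_events A [valve_events()] object.
#' @param cycle_length Cycle length, ms.
#' @param frame_rate Sampling rate, frames/s.
#' @param noise_sd Additive Gaussian noise SD, percent (default 0).
#' @param seed Optional integer seed; when given, two calls with the same
#'   arguments return identical traces and the caller's RNG is untouched.
#' @return A [strain_trace()].
#' @export
synth_strain_trace <- function(peak_gls, valve_events, cycle_length,
                               frame_rate, noise_sd = 0, seed = NULL) {
  if (!is_number(peak_gls) || peak_gls >= 0)
    stopf("'peak_gls' must be negative (strain shortening), got %s",
          format(peak_gls))
  events <- check_events_in_cycle(valve_events, cycle_length)
  check_number(frame_rate, "frame_rate", lower = 1)
  check_number(noise_sd, "noise_sd", lower = 0)
  dt <- 1000 / frame_rate
  t <- seq(0, cycle_length - 1e-9, by = dt)
  base <- strain_waveform(t, peak_gls, events, cycle_length)
  noise <- if (noise_sd > 0) {
    if (is.null(seed)) rnorm(length(t), 0, noise_sd)
    else with_seed(seed, rnorm(length(t), 0, noise_sd))
  } else 0
  strain_trace(t, base + noise, cycle_length = cycle_length)
}

# early-diastolic recovery fraction of the peak reached by MVO
.strain_recovery <- 0.4

strain_waveform <- function(t, peak, events, cycle_length) {
  y <- numeric(length(t))
  contr <- t >= events$mvc & t < events$avc
  if (any(contr)) {
    u <- (t[contr] - events$mvc) / (events$avc - events$mvc)
    y[contr] <- peak * 0.5 * (1 - cos(pi * u))
  }
  ivr <- t >= events$avc & t < events$mvo
  if (any(ivr)) {
    u <- (t[ivr] - events$avc) / (events$mvo - events$avc)
    y[ivr] <- peak * (1 - .strain_recovery * 0.5 * (1 - cos(pi * u)))
  }
  dia <- t >= events$mvo
  if (any(dia)) {
    u <- (t[dia] - events$mvo) / (cycle_length - events$mvo)
    y[dia] <- peak * (1 - .strain_recovery) * 0.5 * (1 + cos(pi * u))
  }
  y
}

#' One synthetic participant record
#'
#' Low-level constructor validating the invariants of the analysable unit:
#' positive blood pressure, valve events inside the cycle, strain sampled on
#' a strictly increasing grid covering the cycle.
#'
#' @param id Participant identifier.
#' @param age Age in years. @param sex "female" or "male".
#' @param sbp_sitting Sitting brachial systolic pressure, mmHg.
#' @param heart_rate Heart rate, bpm.
#' @param cycle_length Cycle length, ms.
#' @param valve_events A [valve_events()] object.
#' @param strain A [strain_trace()].
#' @param frame_rate Frames/s.
#' @param modality_cycle_lengths Cycle lengths measured on the different
#'   acquisitions used for event timing (ms); their agreement feeds QC.
#' @param gls Peak global longitudinal strain, percent (defaults to the
#'   most negative value of the strain trace).
#' @param indices Optional named list of population-model work-index values
#'   (gwi, gcw, gww, gwe) carried for statistical analyses.
#' @return An object of class `participant_record`.
#' @export
participant_record <- function(id, age, sex, sbp_sitting, heart_rate,
                               cycle_length, valve_events, strain,
                               frame_rate, modality_cycle_lengths,
                               gls = NULL, indices = NULL) {
  if (!is_number(sbp_sitting) || sbp_sitting <= 0)
    stopf("'sbp_sitting' must be positive")
  sex <- match.arg(sex, c("female", "male"))
  events <- check_events_in_cycle(valve_events, cycle_length)
  stopifnot(inherits(strain, "strain_trace"))
  structure(list(id = id, age = age, sex = sex, sbp_sitting = sbp_sitting,
                 heart_rate = heart_rate, cycle_length = cycle_length,
                 valve_events = events, strain = strain,
                 frame_rate = frame_rate,
                 modality_cycle_lengths = modality_cycle_lengths,
                 gls = gls %||% min(strain$strain), indices = indices),
            class = "participant_record")
}

simulate_participant <- function(cfg, i) {
  {
    age <- runif(1, cfg$age_range[1L], cfg$age_range[2L])
    age_c <- mean(cfg$age_range)
    female <- runif(1) < cfg$sex_fraction_female
    fem_c <- as.numeric(female) - cfg$sex_fraction_female

    rho <- cfg$gls_sbp_correlation
    z <- rnorm(2)
    z_sbp <- rho * z[1L] + sqrt(1 - rho^2) * z[2L]
    gls <- cfg$gls_mean + cfg$age_slope_gls * (age - age_c) +
      cfg$sex_offset_gls * fem_c + cfg$gls_sd * z[1L]
    gls <- min(max(gls, -35), -5)
    sbp <- r_shifted_lognormal(z_sbp, cfg$sbp_median, cfg$sbp_iqr, cfg$sbp_shift) +
      cfg$age_slope_sbp * (age - age_c)
    hr <- r_shifted_lognormal(rnorm(1), cfg$hr_median, cfg$hr_iqr, cfg$hr_shift)
    hr <- min(max(hr, cfg$hr_range[1L]), cfg$hr_range[2L])
    cycle <- 60000 / hr

    m <- cfg$valve_event_medians; j <- cfg$valve_event_jitter
    mvc <- max(rnorm(1, m[["mvc"]], j[["mvc"]]), 5)
    avo <- mvc + max(rnorm(1, m[["avo"]] - m[["mvc"]], j[["avo"]]), 15)
    avc <- avo + max(rnorm(1, m[["avc"]] - m[["avo"]], j[["avc"]]), 120)
    mvo <- avc + max(rnorm(1, m[["mvo"]] - m[["avc"]], j[["mvo"]]), 30)
    if (mvo > 0.92 * cycle) { # compress timings into short cycles
      k <- 0.92 * cycle / mvo
      mvc <- mvc * k; avo <- avo * k; avc <- avc * k; mvo <- mvo * k
    }
    events <- valve_events(mvc, avo, avc, mvo)

    frame_rate <- max(rnorm(1, cfg$frame_rate_mean, cfg$frame_rate_sd), 30)

    gwi <- cfg$gwi_mean + cfg$age_slope_gwi * (age - age_c) +
      cfg$sex_offset_gwi * fem_c + rnorm(1, 0, cfg$gwi_sd)
    gcw <- max(cfg$gcw_mean + cfg$age_slope_gcw * (age - age_c) +
                 cfg$sex_offset_gcw * fem_c + rnorm(1, 0, cfg$gcw_sd), 200)
    gww <- exp(rnorm(1, cfg$gww_log_mean +
                       cfg$age_slope_log_gww * (age - age_c), cfg$gww_log_sd))
    gwe <- 100 * gcw / (gcw + gww)

    # QC structure: clean records sit inside every limit; a contaminated
    # record receives exactly one violation type.
    contaminated <- runif(1) < cfg$contamination_rate
    mod_jitter <- runif(1, -8, 8)
    modality <- c(cycle, cycle + mod_jitter)
    if (contaminated) {
      type <- sample(c("sbp", "beat", "hr"), 1L)
      if (type == "sbp") sbp <- runif(1, 161, 185)
      if (type == "beat") modality <- c(cycle, cycle + sample(c(-1, 1), 1L) * runif(1, 13, 30))
      if (type == "hr") modality <- c(cycle, cycle * (1 + runif(1, 0.31, 0.5)))
    } else {
      sbp <- min(max(sbp, 85), 159)
    }

    strain <- synth_strain_trace(gls, events, cycle, frame_rate,
                                 noise_sd = cfg$strain_noise_sd)
    participant_record(id = sprintf("P%05d", i), age = age,
                       sex = if (female) "female" else "male",
                       sbp_sitting = sbp, heart_rate = hr,
                       cycle_length = cycle, valve_events = events,
                       strain = strain, frame_rate = frame_rate,
                       modality_cycle_lengths = modality,
                       gls = gls,
                       indices = list(gwi = gwi, gcw = gcw, gww = gww,
                                      gwe = gwe))
  }
}

#' Generate a synthetic cohort
#'
#' Draws `config$n` participants from the population model described in
#' [cohort_config()]. Generation is bit-reproducible for a fixed seed: all
#' participants are drawn sequentially from a single stream seeded once, so
#' the first `k` participants of two cohorts sharing a seed are identical
#' regardless of `n`, and cohorts with different seeds are independent. The
#' caller's RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return An object of class `cohort`: a list of
#'   [participant_record()] objects with the config attached as an
#'   attribute. Use [as.data.frame()] for the participant-level table.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 5, seed = 42))
#' as.data.frame(coh)[, c("id", "age", "sex", "gls", "gwi")]
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  records <- with_seed(config$seed, lapply(seq_len(config$n), function(i)
    simulate_participant(config, i)))
  structure(records, class = "cohort", config = config)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (seed %d)\n",
              length(x), attr(x, "config")$seed))
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  rows <- lapply(unclass(x), function(r) {
    data.frame(id = r$id, age = r$age, sex = r$sex,
               sbp_sitting = r$sbp_sitting, heart_rate = r$heart_rate,
               cycle_length = r$cycle_length,
               mvc = r$valve_events$mvc, avo = r$valve_events$avo,
               avc = r$valve_events$avc, mvo = r$valve_events$mvo,
               frame_rate = r$frame_rate,
               cycle_length_mod1 = r$modality_cycle_lengths[1L],
               cycle_length_mod2 = r$modality_cycle_lengths[2L],
               gls = r$gls,
               gwi = r$indices$gwi %||% NA_real_,
               gcw = r$indices$gcw %||% NA_real_,
               gww = r$indices$gww %||% NA_real_,
               gwe = r$indices$gwe %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Quality-control thresholds
#'
#' Defaults follow the published exclusion rules: sitting SBP above
#' 160 mmHg, beat-timing mismatch between acquisitions above 12 ms, and
#' heart-rate variation between acquisitions above 30 %.
#'
#' @param sbp_max Maximum sitting SBP, mmHg.
#' @param beat_timing_max Maximum cycle-length difference between
#'   acquisitions, ms.
#' @param hr_variation_max Maximum relative cycle-length variation between
#'   acquisitions, proportion ((max - min) / min).
#' @return A list of thresholds.
#' @export
qc_thresholds <- function(sbp_max = 160, beat_timing_max = 12,
                          hr_variation_max = 0.30) {
  list(sbp_max = sbp_max, beat_timing_max = beat_timing_max,
       hr_variation_max = hr_variation_max)
}

#' Apply quality control to one participant
#'
#' Flags every violated exclusion rule: `sbp_gt_160` (sitting SBP above the
#' threshold), `beat_timing_gt_12ms` (cycle lengths from the acquisitions
#' used for event timing differ by more than the limit),
#' `hr_variation_gt_30pct` (relative cycle-length variation above the
#' limit), and `missing_events` (valve events absent or out of order).
#' Reason tokens are fixed regardless of the configured threshold values.
#'
#' @param record A [participant_record()].
#' @param thresholds A [qc_thresholds()] list.
#' @return An object of class `qc_result`: list with `passed` (flag) and
#'   `reasons` (character vector, empty iff passed).
#' @export
apply_qc <- function(record, thresholds = qc_thresholds()) {
  reasons <- character()
  ev <- record$valve_events
  ev_ok <- !is.null(ev) &&
    all(vapply(c("mvc", "avo", "avc", "mvo"),
               function(f) is_number(ev[[f]]), logical(1))) &&
    ev$mvc < ev$avo && ev$avo < ev$avc && ev$avc < ev$mvo
  if (!ev_ok) reasons <- c(reasons, "missing_events")
  if (is_number(record$sbp_sitting) && record$sbp_sitting > thresholds$sbp_max)
    reasons <- c(reasons, "sbp_gt_160")
  mcl <- record$modality_cycle_lengths
  if (length(mcl) >= 2L && all(is.finite(mcl))) {
    if (max(mcl) - min(mcl) > thresholds$beat_timing_max)
      reasons <- c(reasons, "beat_timing_gt_12ms")
    if ((max(mcl) - min(mcl)) / min(mcl) > thresholds$hr_variation_max)
      reasons <- c(reasons, "hr_variation_gt_30pct")
  }
  structure(list(passed = length(reasons) == 0L, reasons = reasons),
            class = "qc_result")
}
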