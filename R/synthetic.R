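#' Simulation configuration
#'
#' Defaults emulate the study conditions this package is validated under:
#' overnight (8 h) 1-Hz recordings, resting saturation near 94% for
#' subjects without chronic obstructive pulmonary disease (COPD) and near
#' 91% with a high fraction of time below 90% when `copd_mode` is on,
#' trapezoidal desaturation events (linear fall over 20-40 s, 5 s nadir
#' hold, resaturation over `resat_time`) arriving as a hard-core renewal
#' process at `event_rate` per hour, plus Gaussian measurement noise.
#'
#' @param duration_hours Recording length in hours (default 8).
#' @param baseline_spo2 Resting saturation in %; default 94, or 91 when
#'   `copd_mode` (matching the basal saturations of the two test groups).
#' @param event_rate Implanted desaturation events per hour (true AHI
#'   surrogate).
#' @param depth_mean,depth_sd Desaturation depth distribution in % points
#'   (default 5 +/- 1, truncated below at 3).
#' @param fall_range Linear desaturation time range in s (default 20-40).
#' @param hold_s Nadir hold in s (default 5).
#' @param resat_time Resaturation time in s (default 15).
#' @param noise_sd Gaussian measurement noise SD in % (default 0.5).
#' @param artifact_rate Artifacts per hour used by [inject_artifacts()]
#'   (default 0: the simulator emits clean signals and corruption is a
#'   separate, controlled step).
#' @param copd_mode Adds a slow baseline drift (2% amplitude, 1 h period)
#'   producing sustained sub-90% epochs (default `FALSE`).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration_hours = 8, baseline_spo2 = if (copd_mode) 91 else 94,
                       event_rate = 20, depth_mean = 5, depth_sd = 1,
                       fall_range = c(20, 40), hold_s = 5, resat_time = 15,
                       noise_sd = 0.5, artifact_rate = 0, copd_mode = FALSE,
                       seed = 1L) {
  stopifnot(duration_hours > 0, event_rate >= 0, noise_sd >= 0,
            artifact_rate >= 0, baseline_spo2 > 50, baseline_spo2 <= 100)
  structure(list(duration_hours = duration_hours, baseline_spo2 = baseline_spo2,
                 event_rate = event_rate, depth_mean = depth_mean,
                 depth_sd = depth_sd, fall_range = fall_range, hold_s = hold_s,
                 resat_time = resat_time, noise_sd = noise_sd,
                 artifact_rate = artifact_rate, copd_mode = copd_mode,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an overnight SpO2 recording with known ground truth
#'
#' The series is baseline + (optional COPD drift) + implanted trapezoidal
#' desaturations + Gaussian noise, clipped to \[50, 100\]. Events arrive as
#' a renewal process with exponential gaps and a 10 s hard core, so they
#' never overlap; the realized event times are returned as ground truth and
#' the realized rate (implanted events per hour) is the recording's true
#' AHI surrogate.
#'
#' @param config A [sim_config()].
#' @param subject_id,setting Passed to the returned [spo2_recording()].
#' @return List with `rec` (the recording) and `truth` (list:
#'   `event_times` — start samples, `event_depths`, `n_events`,
#'   `true_rate` events/h).
#' @export
simulate_recording <- function(config = sim_config(), subject_id = "sim",
                               setting = "lab") {
  cf <- config
  n <- round(cf$duration_hours * 3600) + 1L
  with_local_seed(cf$seed, {
    x <- rep(cf$baseline_spo2, n)
    if (cf$copd_mode) {
      # sustained hypoxemic epochs: ~40% of the night spent 2-4% below the
      # resting level, entered/left over a one-minute ramp
      t0 <- 1L
      while (t0 < n) {
        t0 <- t0 + round(stats::runif(1, 15, 45) * 60)
        len <- round(stats::runif(1, 10, 30) * 60)
        if (t0 >= n) break
        dep <- stats::runif(1, 2, 4)
        idx <- t0:min(n, t0 + len)
        ramp <- pmin(1, pmin(seq_along(idx), rev(seq_along(idx))) / 60)
        x[idx] <- x[idx] - dep * ramp
        t0 <- t0 + len
      }
    }
    starts <- integer(0); depths <- numeric(0)
    if (cf$event_rate > 0) {
      mean_len <- mean(cf$fall_range) + cf$hold_s + cf$resat_time
      mean_gap <- 3600 / cf$event_rate - mean_len
      if (mean_gap < 10) {
        stop("infeasible config: event_rate ", cf$event_rate,
             "/h leaves no room between events")
      }
      t <- 1 + stats::rexp(1, rate = cf$event_rate / 3600)
      while (TRUE) {
        fall <- round(stats::runif(1, cf$fall_range[1], cf$fall_range[2]))
        len <- fall + cf$hold_s + cf$resat_time
        if (t + len >= n) break
        depth <- max(3, stats::rnorm(1, cf$depth_mean, cf$depth_sd))
        depth <- min(depth, cf$baseline_spo2 - 55)
        shape <- c(seq(0, depth, length.out = fall + 1L)[-1L],
                   rep(depth, cf$hold_s),
                   seq(depth, 0, length.out = cf$resat_time + 1L)[-1L])
        idx <- round(t) + seq_along(shape) - 1L
        x[idx] <- x[idx] - shape
        starts <- c(starts, as.integer(round(t)))
        depths <- c(depths, depth)
        t <- t + len + 10 + stats::rexp(1, rate = 1 / max(mean_gap - 10, 1))
      }
    }
    if (cf$noise_sd > 0) x <- x + stats::rnorm(n, 0, cf$noise_sd)
    x <- pmin(100, pmax(50, x))
    rec <- spo2_recording(x, subject_id = subject_id, setting = setting)
    list(rec = rec,
         truth = list(event_times = starts, event_depths = depths,
                      n_events = length(starts),
                      true_rate = length(starts) / cf$duration_hours))
  })
}

#' Inject oximetry artifacts into a clean recording
#'
#' Replaces seeded random samples with the three artifact classes the
#' preprocessing stage must remove: zeros (probe drop-out), impossible
#' values below 20%, and isolated spikes creating steps of at least 4 %/s.
#' Injection sites are kept at least 5 s apart and away from the ends, so
#' each artifact is counted once by the preprocessing report.
#'
#' @param rec A clean [spo2_recording()].
#' @param artifact_rate Artifacts per hour (split evenly across the three
#'   classes); `0` returns the recording unchanged.
#' @param seed Integer seed.
#' @return List with `rec` (corrupted recording) and `positions` (list of
#'   sample indices per class: `zero`, `low`, `spike`).
#' @export
inject_artifacts <- function(rec, artifact_rate = 6, seed = 1L) {
  stopifnot(inherits(rec, "spo2_recording"), artifact_rate >= 0)
  if (artifact_rate == 0) {
    return(list(rec = rec, positions = list(zero = integer(0), low = integer(0),
                                            spike = integer(0))))
  }
  x <- rec$samples
  n <- length(x)
  hrs <- (n - 1L) / rec$sample_rate / 3600
  m <- max(1L, round(artifact_rate * hrs))
  with_local_seed(seed, {
    cand <- seq(5L, n - 5L)
    pos <- integer(0)
    while (length(pos) < m && length(cand) > 0L) {
      p <- sample(cand, 1L)
      pos <- c(pos, p)
      cand <- cand[abs(cand - p) > 5L]
    }
    pos <- sort(pos)
    cls <- rep_len(c("zero", "low", "spike"), length(pos))
    x[pos[cls == "zero"]] <- 0
    x[pos[cls == "low"]] <- stats::runif(sum(cls == "low"), 5, 15)
    x[pos[cls == "spike"]] <- pmax(50, x[pos[cls == "spike"]] - 8)
    out <- rec
    out$samples <- x
    list(rec = out, positions = split(pos, cls)[c("zero", "low", "spike")])
  })
}

#' Simulate a cohort of recordings with known true AHI
#'
#' Draws each subject's target event rate uniformly over `ahi_range` and
#' simulates an in-lab recording; when `setting_pair` is on, a second
#' "home" recording is generated for the same subject with the event rate
#' perturbed by a mean-one lognormal factor (`sdlog = 0.35`), emulating
#' night-to-night variability of the disease between the laboratory night
#' and the unattended home night.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param ahi_range True-AHI range in events/h (default `c(0, 60)`).
#' @param duration_hours Recording length (default 8).
#' @param setting_pair Also simulate a home night (default `FALSE`).
#' @param noise_sd,copd_mode Passed to [sim_config()].
#' @param seed Integer seed.
#' @return List with `ahi_true` (realized lab event rates), `recordings`
#'   (list of lab [spo2_recording()]s), `truths`, and when `setting_pair`
#'   `recordings_home` / `ahi_home` (realized home rates).
#' @export
simulate_cohort <- function(n_subjects, ahi_range = c(0, 60), duration_hours = 8,
                            setting_pair = FALSE, noise_sd = 0.5,
                            copd_mode = FALSE, seed = 1L) {
  stopifnot(n_subjects >= 2)
  rates <- with_local_seed(seed, stats::runif(n_subjects, ahi_range[1], ahi_range[2]))
  recs <- vector("list", n_subjects); truths <- vector("list", n_subjects)
  recs_h <- vector("list", n_subjects)
  ahi_true <- numeric(n_subjects); ahi_home <- numeric(n_subjects)
  jit <- with_local_seed(derive_seed(seed, 999L),
                         stats::rlnorm(n_subjects, -0.35^2 / 2, 0.35))
  for (i in seq_len(n_subjects)) {
    cf <- sim_config(duration_hours = duration_hours, event_rate = rates[i],
                     noise_sd = noise_sd, copd_mode = copd_mode,
                     seed = derive_seed(seed, i))
    s <- simulate_recording(cf, subject_id = sprintf("S%03d", i), setting = "lab")
    recs[[i]] <- s$rec; truths[[i]] <- s$truth
    ahi_true[i] <- s$truth$true_rate
    if (setting_pair) {
      cf_h <- sim_config(duration_hours = duration_hours,
                         event_rate = min(rates[i] * jit[i], 58),
                         noise_sd = noise_sd, copd_mode = copd_mode,
                         seed = derive_seed(seed, i, 2L))
      sh <- simulate_recording(cf_h, subject_id = sprintf("S%03d", i),
                               setting = "home")
      recs_h[[i]] <- sh$rec
      ahi_home[i] <- sh$truth$true_rate
    }
  }
  out <- list(ahi_true = ahi_true, recordings = recs, truths = truths)
  if (setting_pair) {
    out$recordings_home <- recs_h
    out$ahi_home <- ahi_home
  }
  out
}
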