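# Inhomogeneous-Poisson spike-train simulator and two-group cohorts.

#' Specification of a simulated single-unit recording
#'
#' Adapting cells respond to the threshold stimulus with an exponentially
#' decaying rate `r(t) = peak_rate * exp(-t / decay_tau)`; nonadapting cells
#' hold `r(t) = peak_rate` for the stimulus duration. Spontaneous activity
#' is a homogeneous Poisson background over the whole recording.
#'
#' @param cell_class `"adapting"` or `"nonadapting"`.
#' @param peak_rate evoked rate at stimulus onset, Hz.
#' @param decay_tau adaptation time constant, s (adapting cells only).
#' @param spontaneous_rate background rate, Hz.
#' @param n_trials repeats of the threshold stimulus (3 in the standard
#'   protocol; raise for Monte-Carlo convergence checks).
#' @param stimulus_duration s per stimulus application (default 2).
#' @param seed integer RNG seed.
#' @return A `spike_sim_spec` list.
#' @export
spike_sim_spec <- function(cell_class = c("adapting", "nonadapting"),
                           peak_rate = 40, decay_tau = 0.15,
                           spontaneous_rate = 1, n_trials = 3L,
                           stimulus_duration = 2, seed = 1L) {
  cell_class <- match.arg(cell_class)
  stopifnot(peak_rate >= 0, spontaneous_rate >= 0, decay_tau > 0,
            n_trials >= 1, stimulus_duration > 0)
  structure(list(cell_class = cell_class, peak_rate = peak_rate,
                 decay_tau = decay_tau, spontaneous_rate = spontaneous_rate,
                 n_trials = as.integer(n_trials),
                 stimulus_duration = stimulus_duration,
                 seed = as.integer(seed)),
            class = "spike_sim_spec")
}

# homogeneous Poisson times on [t0, t1)
hpp_times <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

# inhomogeneous Poisson by thinning against max_rate; rate_fn on [0, dur)
ipp_times <- function(rate_fn, max_rate, onset, dur) {
  cand <- hpp_times(max_rate, onset, onset + dur)
  if (!length(cand)) return(numeric(0))
  keep <- stats::runif(length(cand)) < rate_fn(cand - onset) / max_rate
  cand[keep]
}

#' Construct a single-unit recording object
#'
#' @param spike_times numeric, seconds from recording start; sorted
#'   internally.
#' @param epochs data.frame with columns `kind` (`"brush"`, `"vf"`,
#'   `"spontaneous"`), `filament_index` (1-10, `NA` unless `kind == "vf"`),
#'   `onset`, `duration` (s) and `trial`.
#' @param depth recording depth below the cord surface, um. Values outside
#'   200-550 um are flagged with a QC warning, not rejected.
#' @param receptive_field optional polygon vertex matrix (mm), columns x, y.
#' @param animal,group optional identifiers.
#' @return A `cell_recording` object.
#' @export
cell_recording <- function(spike_times, epochs, depth = NA_real_,
                           receptive_field = NULL, animal = NA_character_,
                           group = NA_character_) {
  spike_times <- sort(as.numeric(spike_times))
  req <- c("kind", "filament_index", "onset", "duration", "trial")
  miss <- setdiff(req, names(epochs))
  if (length(miss)) stop("epochs missing columns: ", paste(miss, collapse = ", "))
  if (any(epochs$duration <= 0)) stop("epoch durations must be > 0")
  if (any(epochs$kind == "vf" & is.na(epochs$filament_index)))
    stop("vf epochs need a filament_index")
  if (!is.na(depth) && (depth < 200 || depth > 550))
    warning(sprintf("QC: recording depth %.0f um outside 200-550 um", depth),
            call. = FALSE)
  structure(list(spike_times = spike_times, epochs = epochs, depth = depth,
                 receptive_field = receptive_field, animal = animal,
                 group = group),
            class = "cell_recording")
}

#' @export
print.cell_recording <- function(x, ...) {
  cat(sprintf("<cell_recording> %d spikes, %d epochs, depth %s um\n",
              length(x$spike_times), nrow(x$epochs),
              ifelse(is.na(x$depth), "?", format(x$depth))))
  invisible(x)
}

#' Simulate a single-unit recording
#'
#' Builds a full recording timeline: a spontaneous pre-stimulus window, a
#' short ascending series of sub-threshold von Frey filaments (constant
#' low-rate responses), then `n_trials` applications of the threshold
#' filament with the class-specific rate profile, separated by
#' `inter_trial` seconds. Spontaneous background spikes run throughout.
#'
#' @param spec a [spike_sim_spec].
#' @param threshold_filament index of the first filament evoking the full
#'   response (default 4).
#' @param subthreshold_rate evoked rate for filaments below threshold, Hz
#'   (default 2, well under the 10 Hz rule).
#' @param inter_trial gap between stimulus applications, s (default 10).
#' @param pre_window spontaneous recording before stimulation, s
#'   (default 60).
#' @param depth recording depth, um; drawn uniformly in 200-550 if `NULL`.
#' @return A [cell_recording] with attribute `true_class` = the simulated
#'   class.
#' @export
gen_spike_recording <- function(spec, threshold_filament = 4L,
                                subthreshold_rate = 2, inter_trial = 10,
                                pre_window = 60, depth = NULL) {
  stopifnot(inherits(spec, "spike_sim_spec"))
  with_seed(spec$seed, {
    rate_fn <- if (spec$cell_class == "adapting") {
      function(t) spec$peak_rate * exp(-t / spec$decay_tau)
    } else {
      function(t) rep(spec$peak_rate, length(t))
    }
    epochs <- data.frame(kind = "spontaneous", filament_index = NA_integer_,
                         onset = 0, duration = pre_window, trial = 1L,
                         stringsAsFactors = FALSE)
    spikes <- list()
    t_cur <- pre_window
    for (f in seq_len(max(threshold_filament - 1L, 0L))) {
      for (tr in 1:3) {
        epochs <- rbind(epochs, data.frame(
          kind = "vf", filament_index = f, onset = t_cur,
          duration = spec$stimulus_duration, trial = tr,
          stringsAsFactors = FALSE))
        spikes[[length(spikes) + 1L]] <-
          hpp_times(subthreshold_rate, t_cur, t_cur + spec$stimulus_duration)
        t_cur <- t_cur + spec$stimulus_duration + inter_trial
      }
    }
    for (tr in seq_len(spec$n_trials)) {
      epochs <- rbind(epochs, data.frame(
        kind = "vf", filament_index = threshold_filament, onset = t_cur,
        duration = spec$stimulus_duration, trial = tr,
        stringsAsFactors = FALSE))
      if (spec$peak_rate > 0)
        spikes[[length(spikes) + 1L]] <-
          ipp_times(rate_fn, spec$peak_rate, t_cur, spec$stimulus_duration)
      t_cur <- t_cur + spec$stimulus_duration + inter_trial
    }
    spikes[[length(spikes) + 1L]] <- hpp_times(spec$spontaneous_rate, 0, t_cur)
    if (is.null(depth)) depth <- stats::runif(1, 200, 550)
    # star-shaped receptive-field polygon on the plantar surface (mm):
    # jittered evenly spaced angles keep every angular gap under pi, so
    # the centre is interior and the polygon is always simple
    k <- sample(5:8, 1)
    ang <- 2 * pi * (seq_len(k) - 1) / k + stats::runif(k, 0, 2 * pi / k)
    rad <- stats::runif(1, 0.4, 1.0) * (0.75 + 0.5 * stats::runif(k))
    rf <- cbind(x = 2 + rad * cos(ang), y = 4 + rad * sin(ang))
    rec <- cell_recording(unlist(spikes), epochs, depth = depth,
                          receptive_field = rf)
    attr(rec, "true_class") <- spec$cell_class
    rec
  })
}

#' Specification of a two-group synthetic cohort
#'
#' @param n_per_group animals or cells per group (>= 2).
#' @param group_means,group_sds length-2 numeric: control then comparison
#'   group.
#' @param seed integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 20L, group_means = c(0, 1),
                        group_sds = c(1, 1), seed = 1L) {
  stopifnot(n_per_group >= 2, length(group_means) == 2L,
            length(group_sds) == 2L, all(group_sds > 0))
  structure(list(n_per_group = as.integer(n_per_group),
                 group_means = as.numeric(group_means),
                 group_sds = as.numeric(group_sds), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a two-group normal cohort
#'
#' @param spec a [cohort_spec].
#' @return List with numeric vectors `a` (control) and `b` (comparison) and
#'   the true mean difference `true_diff = mean(b) - mean(a)` of the
#'   generating distributions.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    list(a = stats::rnorm(spec$n_per_group, spec$group_means[1],
                          spec$group_sds[1]),
         b = stats::rnorm(spec$n_per_group, spec$group_means[2],
                          spec$group_sds[2]),
         true_diff = spec$group_means[2] - spec$group_means[1])
  })
}
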