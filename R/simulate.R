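# Seeded stochastic simulator of the loss assay: branching growth of MC+ and
# MC- subpopulations in synchronous MC+ generations, with event-level
# sampling that mimics cytometer acquisition.

#' Simulation configuration
#'
#' Bundles the parameters of one stochastic (or deterministic) growth
#' simulation. Doubling times are in minutes; `m_true` is the probability
#' that a progeny cell of an MC+ division lacks the mini-chromosome.
#'
#' @param m_true Loss probability per progeny cell, in `[0, 1)`.
#' @param T_plus,T_minus Doubling times of MC+ and MC- cells (minutes > 0).
#'   Their ratio `T_minus / T_plus` is the fitness ratio beta.
#' @param duration Simulated time in minutes (>= 0); the population advances
#'   in synchronous MC+ generations of length `T_plus`.
#' @param n_plus0,n_minus0 Initial cell counts (>= 0).
#' @param step `"per_generation_binomial"` for stochastic draws or
#'   `"deterministic_expectation"` for the exact expectation (which matches
#'   [forward_ratio()]).
#' @param seed Optional integer; when given, fixes the full trajectory and
#'   all downstream sampling of this simulation.
#' @return A `sim_config` object (list).
#' @export
sim_config <- function(m_true, T_plus = 90, T_minus = T_plus,
                       duration = 1440, n_plus0 = 1e6, n_minus0 = 0,
                       step = c("per_generation_binomial",
                                "deterministic_expectation"),
                       seed = NULL) {
  step <- match.arg(step)
  if (m_true < 0 || m_true >= 1) stop("m_true must lie in [0, 1)")
  if (T_plus <= 0 || T_minus <= 0) stop("doubling times must be positive")
  if (duration < 0) stop("duration must be non-negative")
  if (n_plus0 < 0 || n_minus0 < 0) stop("cell counts must be non-negative")
  structure(list(m_true = m_true, T_plus = T_plus, T_minus = T_minus,
                 duration = duration, n_plus0 = n_plus0,
                 n_minus0 = n_minus0, step = step, seed = seed),
            class = "sim_config")
}

# counts above this are propagated by expectation plus a Gaussian
# perturbation instead of exact binomial draws
.BIG_COUNT <- 1e7

# stochastic rounding: integer with expectation exactly x
.stoch_round <- function(x) {
  fl <- floor(x)
  fl + (stats::runif(1) < (x - fl))
}

#' Simulate MC+/MC- population growth
#'
#' Advances the two subpopulations in synchronous MC+ generations of length
#' `T_plus`. Per generation, stochastic mode draws the number of
#' MC-retaining progeny from `Binomial(2 N+, 1 - m_true)`; the complement
#' joins the MC- pool, which additionally multiplies by
#' `2^(T_plus/T_minus)` (non-integer factors applied with
#' expectation-preserving stochastic rounding). Counts above 1e7 switch to a
#' Gaussian approximation of the binomial to keep large populations cheap.
#' Deterministic mode replaces every draw by its expectation and reproduces
#' [forward_ratio()] exactly.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `time` (minutes), `n_plus`, `n_minus`, one
#'   row per completed generation including the initial state.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_gen <- floor(config$duration / config$T_plus)
  g_minus <- 2^(config$T_plus / config$T_minus)
  m <- config$m_true
  stochastic <- config$step == "per_generation_binomial"

  np <- numeric(n_gen + 1); nm <- numeric(n_gen + 1)
  np[1] <- config$n_plus0; nm[1] <- config$n_minus0
  for (i in seq_len(n_gen)) {
    prog <- 2 * np[i]
    if (!stochastic) {
      retained <- prog * (1 - m)
      nm_grown <- nm[i] * g_minus
    } else {
      if (prog <= .BIG_COUNT) {
        retained <- stats::rbinom(1, size = round(prog), prob = 1 - m)
      } else {
        mu <- prog * (1 - m); sdv <- sqrt(prog * m * (1 - m))
        retained <- max(0, round(mu + stats::rnorm(1) * sdv))
      }
      grown <- nm[i] * g_minus
      # above the count guard the sub-integer rounding noise is negligible
      nm_grown <- if (nm[i] <= .BIG_COUNT) .stoch_round(grown)
                  else round(grown)
    }
    np[i + 1] <- retained
    nm[i + 1] <- nm_grown + (prog - retained)
  }
  tibble::tibble(time = (0:n_gen) * config$T_plus, n_plus = np, n_minus = nm)
}

#' Two-mode log-normal intensity model
#'
#' Fluorescence intensity distributions for the two cell classes: GFP-
#' (MC+) events centred at `neg_median` a.u. and GFP+ (MC-) events at
#' `pos_median`, the default 100-fold separation reflecting the strong
#' de-repression of the reporter after chromosome loss.
#'
#' @param neg_median,pos_median Median intensities (a.u.).
#' @param log10_sd Standard deviation of log10 intensity per mode.
#' @return A list used by [sample_events()].
#' @export
intensity_model <- function(neg_median = 100, pos_median = 10000,
                            log10_sd = 0.2) {
  stopifnot(neg_median > 0, pos_median > 0, log10_sd > 0)
  list(neg_median = neg_median, pos_median = pos_median,
       log10_sd = log10_sd)
}

#' Sample cytometer events from a population state
#'
#' Draws the number of GFP+ events from `Binomial(n_events, f)` with
#' `f = N- / (N+ + N-)`, assigns log-normal intensities per class, and
#' shuffles acquisition order. Truth labels are retained so gating can be
#' scored against the planted classes.
#'
#' @param n_plus,n_minus Cell counts of the sampled population (total > 0).
#' @param n_events Number of events to acquire (> 0).
#' @param intensities An [intensity_model()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `event_id`, `gfp_intensity`,
#'   `truth_label` (`"pos"` for MC- cells, `"neg"` for MC+).
#' @export
sample_events <- function(n_plus, n_minus, n_events,
                          intensities = intensity_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_events <= 0) stop("n_events must be positive")
  total <- n_plus + n_minus
  if (total <= 0) stop("cannot sample events from an empty population")
  f <- n_minus / total
  n_pos <- stats::rbinom(1, n_events, f)
  n_neg <- n_events - n_pos
  lab <- sample(rep(c("pos", "neg"), c(n_pos, n_neg)))
  mu <- ifelse(lab == "pos", log10(intensities$pos_median),
               log10(intensities$neg_median))
  tibble::tibble(
    event_id = seq_len(n_events),
    gfp_intensity = 10^stats::rnorm(n_events, mu, intensities$log10_sd),
    truth_label = lab)
}

#' Simulate a two-timepoint loss assay
#'
#' Runs one stochastic culture via [simulate_population()] and measures it
#' at the requested timepoints the way the assay does: a fixed number of
#' cytometer events whose GFP+ count is binomially sampled from the current
#' MC- fraction, plus an OD reading proportional to total cells with
#' multiplicative log-normal noise. Sampling times snap down to the last
#' completed MC+ generation.
#'
#' `gfp_delay` models the one-cell-cycle lag before the de-repressed
#' reporter becomes detectable: when `TRUE`, the GFP+ fraction measured at
#' time t is the MC- fraction one generation earlier (default off).
#'
#' @param config A [sim_config()].
#' @param t_sample Sampling times in minutes (>= 2 values, within the
#'   simulated duration).
#' @param events_per_timepoint Cytometer events acquired per sample.
#' @param od_per_cell OD600 units per cell (calibration constant).
#' @param od_noise_cv Coefficient of variation of multiplicative OD noise.
#' @param gfp_delay Apply the one-generation reporter delay.
#' @return A tibble with one row per timepoint: `timepoint`, `time_min`,
#'   `gfp_pos`, `total_events`, `od`.
#' @export
simulate_assay <- function(config, t_sample = c(0, config$duration),
                           events_per_timepoint = 3e5,
                           od_per_cell = 5e-8, od_noise_cv = 0.02,
                           gfp_delay = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (length(t_sample) < 2) stop("need at least two sampling timepoints")
  if (any(t_sample < 0 | t_sample > config$duration))
    stop("sampling timepoints outside the simulated duration")
  traj <- simulate_population(config)
  rows <- lapply(seq_along(t_sample), function(i) {
    t <- t_sample[i]
    idx <- max(which(traj$time <= t))
    npl <- traj$n_plus[idx]; nmi <- traj$n_minus[idx]
    nmi_seen <- if (gfp_delay && idx > 1) traj$n_minus[idx - 1] else
                if (gfp_delay) traj$n_minus[1] else nmi
    total <- npl + nmi
    f_seen <- if (npl + nmi_seen > 0) nmi_seen / (npl + nmi_seen) else 0
    gfp_pos <- stats::rbinom(1, events_per_timepoint, f_seen)
    od <- total * od_per_cell *
      exp(stats::rnorm(1, 0, od_noise_cv) - od_noise_cv^2 / 2)
    tibble::tibble(timepoint = paste0("t", i - 1), time_min = t,
                   gfp_pos = gfp_pos, total_events = events_per_timepoint,
                   od = od)
  })
  dplyr::bind_rows(rows)
}
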