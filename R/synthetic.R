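# Synthetic-data stage: genome-scale screens with planted ground truth and
# synthetic growth plates, so every pipeline stage can be exercised and
# scored without any experimental input.

#' Synthetic screen configuration
#'
#' Defines the conditions of a simulated screen: strain count, planted
#' effects, replication, cytometer depth, and growth geometry. Defaults
#' mirror the assay's operating point — a basal loss rate of 1e-3 per
#' division (a mini-chromosome loss rate of a few 1e-4 to 1e-3 per division,
#' giving a basal GFP+ fraction of a few tenths of a percent after a few
#' generations), 0.3 million events per sample, 24-hour growth phases at a
#' 90-minute doubling time, and 8 replicates for validation screens.
#'
#' Strain-to-strain nuisance variation is modelled as log-normal jitter on
#' the true loss rate (`strain_cv`, default 10%, 0 to disable) so that null
#' calibration is tested under realistic overdispersion.
#'
#' @param n_strains Number of test strains (> 0), control excluded.
#' @param n_elevated,n_suppressed Numbers of planted hits in each direction;
#'   their sum may not exceed `n_strains`.
#' @param elevated_palette,suppressed_palette Fold changes sampled for
#'   planted hits (suppressed values must be < 1).
#' @param basal_m Basal loss rate per division.
#' @param replicates Replicates per strain (1 for a primary screen).
#' @param events_per_sample Cytometer events per timepoint.
#' @param duration Growth-phase length in minutes.
#' @param T_plus MC+ doubling time (minutes).
#' @param beta_true Fitness ratio applied to every strain (default 1).
#' @param od_noise_cv Multiplicative OD noise.
#' @param strain_cv Log-normal CV of strain-level loss-rate jitter.
#' @param initial_fraction GFP+ fraction at the start of the phase.
#' @param initial_cells Cells per culture at the start of the phase.
#' @param seed Integer seed fixing everything downstream.
#' @return A `synthetic_screen_config` list.
#' @export
synthetic_screen_config <- function(n_strains = 96, n_elevated = 0,
                                    n_suppressed = 0,
                                    elevated_palette = c(1.5, 2, 3, 5, 10),
                                    suppressed_palette = c(0.5, 0.67),
                                    basal_m = 1e-3, replicates = 8,
                                    events_per_sample = 3e5,
                                    duration = 1440, T_plus = 90,
                                    beta_true = 1, od_noise_cv = 0.02,
                                    strain_cv = 0.1,
                                    initial_fraction = 0.0025,
                                    initial_cells = 1e6, seed = 1) {
  if (n_strains <= 0) stop("n_strains must be positive")
  if (n_elevated + n_suppressed > n_strains)
    stop("planted hit fraction exceeds 1: more hits than strains")
  if (any(elevated_palette <= 1))
    stop("elevated fold changes must exceed 1")
  if (any(suppressed_palette >= 1 | suppressed_palette <= 0))
    stop("suppressed fold changes must lie in (0, 1)")
  if (basal_m <= 0 || basal_m >= 1) stop("basal_m must lie in (0, 1)")
  if (replicates < 1 || events_per_sample < 1 || initial_cells < 1)
    stop("counts must be positive")
  structure(list(n_strains = n_strains, n_elevated = n_elevated,
                 n_suppressed = n_suppressed,
                 elevated_palette = elevated_palette,
                 suppressed_palette = suppressed_palette,
                 basal_m = basal_m, replicates = replicates,
                 events_per_sample = events_per_sample,
                 duration = duration, T_plus = T_plus,
                 beta_true = beta_true, od_noise_cv = od_noise_cv,
                 strain_cv = strain_cv,
                 initial_fraction = initial_fraction,
                 initial_cells = initial_cells, seed = seed),
            class = "synthetic_screen_config")
}

# log-normal multiplicative jitter with unit mean
.lnorm_jitter <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic screen with planted ground truth
#'
#' Simulates every strain x replicate culture with the stochastic assay
#' simulator and emits (i) a manifest in exactly the schema [run_screen()]
#' consumes and (ii) a truth table of planted loss rates and effect classes
#' for scoring. The control strain carries the basal rate without jitter.
#' The output is reproducible bit-for-bit from the configuration seed.
#'
#' @param config A [synthetic_screen_config()].
#' @return A list: `manifest` (tibble), `truth` (tibble: strain, m_true,
#'   beta_true, effect, fold_change).
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "synthetic_screen_config"))
  set.seed(config$seed)
  ids <- sprintf("s%04d", seq_len(config$n_strains))
  effect <- rep("none", config$n_strains)
  fc <- rep(1, config$n_strains)
  n_hits <- config$n_elevated + config$n_suppressed
  if (n_hits > 0) {
    hit_idx <- sample(config$n_strains, n_hits)
    up <- hit_idx[seq_len(config$n_elevated)]
    dn <- setdiff(hit_idx, up)
    effect[up] <- "elevated"
    fc[up] <- config$elevated_palette[
      sample.int(length(config$elevated_palette), length(up),
                 replace = TRUE)]
    effect[dn] <- "suppressed"
    fc[dn] <- config$suppressed_palette[
      sample.int(length(config$suppressed_palette), length(dn),
                 replace = TRUE)]
  }
  m_true <- pmin(config$basal_m * fc *
                   .lnorm_jitter(config$n_strains, config$strain_cv), 0.5)

  truth <- tibble::tibble(
    strain = c(ids, "control"),
    m_true = c(m_true, config$basal_m),
    beta_true = config$beta_true,
    effect = c(effect, "none"),
    fold_change = c(fc, 1))

  n0_minus <- round(config$initial_cells * config$initial_fraction)
  n0_plus <- round(config$initial_cells) - n0_minus
  rows <- vector("list", nrow(truth) * config$replicates)
  k <- 0
  for (i in seq_len(nrow(truth))) {
    for (r in seq_len(config$replicates)) {
      cfg <- sim_config(m_true = truth$m_true[i],
                        T_plus = config$T_plus,
                        T_minus = config$T_plus * truth$beta_true[i],
                        duration = config$duration,
                        n_plus0 = n0_plus, n_minus0 = n0_minus)
      a <- simulate_assay(cfg,
                          events_per_timepoint = config$events_per_sample,
                          od_noise_cv = config$od_noise_cv)
      a$strain <- truth$strain[i]
      a$replicate <- paste0("r", r)
      k <- k + 1
      rows[[k]] <- a
    }
  }
  manifest <- dplyr::bind_rows(rows)
  manifest$phase <- "nonselective"
  manifest$dilution <- 1
  manifest <- manifest[, c("strain", "replicate", "phase", "timepoint",
                           "gfp_pos", "total_events", "od", "time_min",
                           "dilution")]
  list(manifest = tibble::as_tibble(manifest), truth = truth)
}

#' Generate a synthetic growth plate
#'
#' Logistic (default) or pure-exponential OD curves at 15-minute sampling,
#' starting at OD 0.05 with carrying capacity 3.0, one well per supplied
#' doubling time, with optional multiplicative log-normal noise.
#'
#' @param doubling_times Doubling time (minutes) per well.
#' @param noise_cv Multiplicative noise CV (0 for noiseless curves).
#' @param duration Observation window in minutes.
#' @param sample_every Sampling interval in minutes.
#' @param od0 Starting OD.
#' @param capacity Carrying capacity (logistic model).
#' @param model `"logistic"` or `"exponential"`.
#' @param seed Optional integer seed.
#' @return Long-format tibble: `well`, `time_min`, `od`, `T_true`.
#' @export
generate_growth_plate <- function(doubling_times, noise_cv = 0,
                                  duration = 1440, sample_every = 15,
                                  od0 = 0.05, capacity = 3,
                                  model = c("logistic", "exponential"),
                                  seed = NULL) {
  model <- match.arg(model)
  if (any(doubling_times <= 0)) stop("doubling times must be positive")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = sample_every)
  out <- lapply(seq_along(doubling_times), function(i) {
    r <- log(2) / doubling_times[i]
    od <- if (model == "exponential") od0 * exp(r * t) else
      capacity / (1 + (capacity / od0 - 1) * exp(-r * t))
    if (noise_cv > 0) od <- od * .lnorm_jitter(length(od), noise_cv)
    tibble::tibble(well = sprintf("w%03d", i), time_min = t, od = od,
                   T_true = doubling_times[i])
  })
  dplyr::bind_rows(out)
}
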