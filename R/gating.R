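# One-dimensional gating of GFP fluorescence event tables: automatic
# threshold at the density valley between the GFP- and GFP+ modes, counting,
# and conversion of gated fractions into MC-/MC+ population ratios.

.event_intensities <- function(events) {
  x <- if (is.data.frame(events)) events$gfp_intensity else events
  if (is.null(x)) stop("event table must carry a gfp_intensity column")
  if (any(x <= 0)) stop("fluorescence intensities must be positive")
  x
}

#' Automatic gating threshold from the intensity distribution
#'
#' Estimates a kernel density of log10 intensity and places the threshold at
#' the density minimum between the two largest modes — for the loss assay,
#' the bulk GFP- population and the roughly 100-fold brighter GFP+
#' population. When the density has a single mode (e.g. a pure negative
#' sample) the threshold falls back to the geometric midpoint of the 1st and
#' 99.9th intensity percentiles, which sits far above a unimodal bulk.
#'
#' @param events Event table (data frame with `gfp_intensity`) or a numeric
#'   intensity vector; at least 1000 events.
#' @return Threshold intensity (a.u.).
#' @export
auto_threshold <- function(events) {
  x <- .event_intensities(events)
  if (length(x) < 1000) stop("need at least 1000 events to set a gate")
  lx <- log10(x)
  degenerate <- max(lx) - min(lx) < sqrt(.Machine$double.eps)
  if (!degenerate) {
    d <- stats::density(lx, n = 1024)
    y <- d$y
    peaks <- which(diff(sign(diff(y))) == -2) + 1
    if (length(peaks) >= 2) {
      main <- peaks[which.max(y[peaks])]
      # second mode: the highest peak separated from the main one by a
      # valley dipping below half its own height, so KDE ripples riding on
      # one mode are not mistaken for a second population
      cand <- peaks[peaks != main]
      prominent <- vapply(cand, function(p) {
        between <- min(p, main):max(p, main)
        min(y[between]) < 0.5 * y[p]
      }, logical(1))
      cand <- cand[prominent]
      if (length(cand) > 0) {
        second <- cand[which.max(y[cand])]
        between <- min(main, second):max(main, second)
        valley <- between[which.min(y[between])]
        return(10^d$x[valley])
      }
    }
  }
  # unimodal (or constant) intensities: geometric midpoint of the 1st and
  # 99.9th percentiles, which a strict-inequality gate leaves empty for a
  # pure negative bulk
  q <- stats::quantile(lx, c(0.01, 0.999), names = FALSE)
  10^mean(q)
}

#' Count events above a gate
#'
#' Events with intensity strictly above the threshold are GFP+ (ties count
#' as negative — deterministic and conservative for rare positives). The
#' MC-/MC+ ratio `R = n_pos / n_neg` is flagged `NA` when every event is
#' positive.
#'
#' @param events Event table or intensity vector.
#' @param threshold Gate position (a.u., > 0).
#' @return A `gate_result` list: `threshold`, `n_pos`, `n_neg`, `n_total`,
#'   `fraction`, `ratio`.
#' @export
gate <- function(events, threshold) {
  x <- .event_intensities(events)
  if (threshold <= 0) stop("threshold must be positive")
  n_pos <- sum(x > threshold)
  n_total <- length(x)
  n_neg <- n_total - n_pos
  structure(list(threshold = threshold, n_pos = n_pos, n_neg = n_neg,
                 n_total = n_total, fraction = n_pos / n_total,
                 ratio = if (n_neg > 0) n_pos / n_neg else NA_real_),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf(
    "Gate at %.4g a.u.: %d / %d positive (fraction %.4g, R = %.4g)\n",
    x$threshold, x$n_pos, x$n_total, x$fraction, x$ratio))
  invisible(x)
}

#' Population ratio pair from two gated timepoints
#'
#' Converts the gated GFP+ fractions at the start and end of a growth phase
#' into the MC-/MC+ ratios `R0` and `Rn` (via `R = f / (1 - f)`) and
#' attaches the number of elapsed generations, producing the inputs of the
#' loss-rate estimators.
#'
#' @param g0,g1 `gate_result` objects at the start and end timepoints.
#' @param n Generations elapsed between them (> 0).
#' @return A list with `R0`, `Rn`, `n`.
#' @export
ratio_pair_from_gates <- function(g0, g1, n) {
  stopifnot(inherits(g0, "gate_result"), inherits(g1, "gate_result"))
  if (g0$fraction >= 1 || g1$fraction >= 1)
    stop("degenerate gate: no GFP- events, ratio undefined")
  if (n <= 0) stop("generation number n must be positive")
  list(R0 = g0$fraction / (1 - g0$fraction),
       Rn = g1$fraction / (1 - g1$fraction),
       n = n)
}

#' Read an event table from CSV
#'
#' Canonical schema: `event_id`, `gfp_intensity`, optional `truth_label`.
#'
#' @param path CSV file path.
#' @return Event tibble.
#' @export
read_event_table <- function(path) {
  df <- utils::read.csv(path)
  if (!"gfp_intensity" %in% names(df))
    stop("event CSV must contain a gfp_intensity column")
  tibble::as_tibble(df)
}

#' Write an event table to CSV
#'
#' @param events Event tibble from [sample_events()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_event_table <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
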