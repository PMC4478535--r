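# Genome-scale screen analysis: per-replicate loss-rate estimation from
# manifest rows, replicate aggregation, control-relative statistics,
# two-stage hit calling (rank selection in the primary screen, fold-change +
# p-value validation), and 2x2 enrichment testing.

#' Screen analysis configuration
#'
#' Thresholds and test choices for [run_screen()]. Defaults follow the
#' validation rule "fold change > 1.5, P < 0.01" with the exact
#' Mann-Whitney U test on 8 replicates, and the primary-stage selection of
#' the 105 highest and 101 lowest single-replicate rates.
#'
#' @param fc_threshold Fold-change threshold for hit calling (> 0).
#' @param p_threshold P-value threshold.
#' @param test `"mann_whitney"` (default) or `"welch_t"`.
#' @param top_k_high,top_k_low Primary-stage candidate counts.
#' @param control_strain Identifier of the reference strain in the manifest.
#' @param formula Loss-rate estimator: `"exact"` (beta = 1 closed form,
#'   default), `"general"` (fitness-corrected), or `"linear"`.
#' @param beta Fitness ratio used by the `"general"` formula.
#' @param p_adjust Optional multiple-testing correction passed to
#'   [stats::p.adjust()] (e.g. `"BH"`); `"none"` (default) matches the raw
#'   p-value rule.
#' @return A `screen_config` list.
#' @export
screen_config <- function(fc_threshold = 1.5, p_threshold = 0.01,
                          test = c("mann_whitney", "welch_t"),
                          top_k_high = 105, top_k_low = 101,
                          control_strain = "control",
                          formula = c("exact", "general", "linear"),
                          beta = 1, p_adjust = "none") {
  test <- match.arg(test)
  formula <- match.arg(formula)
  if (fc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be positive")
  if (top_k_high < 0 || top_k_low < 0) stop("top-k values must be >= 0")
  structure(list(fc_threshold = fc_threshold, p_threshold = p_threshold,
                 test = test, top_k_high = top_k_high,
                 top_k_low = top_k_low, control_strain = control_strain,
                 formula = formula, beta = beta, p_adjust = p_adjust),
            class = "screen_config")
}

#' Loss rate of one strain replicate from its two timepoints
#'
#' Composes the assay arithmetic for a single replicate: GFP+ fractions at
#' both timepoints become MC-/MC+ ratios (`R = f/(1-f)`), the OD readings
#' give the division number via [generations_from_od()], and the chosen
#' estimator returns the per-division loss rate.
#'
#' @param meas Two-row data frame (one strain replicate) with columns
#'   `gfp_pos`, `total_events`, `od` and a `timepoint` ordering, plus an
#'   optional `dilution` column; or a list with elements `gfp_pos`,
#'   `total_events`, `od` of length 2 (start, end) and optional `dilution`.
#' @param beta Fitness ratio (used by `formula = "general"`).
#' @param formula `"exact"`, `"general"`, or `"linear"`.
#' @param mode Solver mode for the general estimator.
#' @return A `loss_rate_estimate` object.
#' @examples
#' estimate_strain_cin(list(gfp_pos = c(738, 2238), total_events = c(3e5, 3e5),
#'                          od = c(0.064, 2.048)))$m
#' @export
estimate_strain_cin <- function(meas, beta = 1,
                                formula = c("exact", "general", "linear"),
                                mode = "self_consistent") {
  formula <- match.arg(formula)
  if (is.data.frame(meas)) {
    if (nrow(meas) != 2) stop("measurement must have exactly two timepoints")
    if ("timepoint" %in% names(meas)) meas <- meas[order(meas$timepoint), ]
    gfp <- meas$gfp_pos; tot <- meas$total_events; od <- meas$od
    dil <- if ("dilution" %in% names(meas)) meas$dilution[2] else 1
  } else {
    gfp <- meas$gfp_pos; tot <- meas$total_events; od <- meas$od
    dil <- if (!is.null(meas$dilution)) meas$dilution else 1
  }
  if (any(gfp > tot)) stop("GFP+ counts exceed total events")
  if (any(gfp == tot)) stop("no GFP- events at a timepoint: ratio undefined")
  f <- gfp / tot
  R <- f / (1 - f)
  n <- generations_from_od(od[1], od[2], dil)
  if (n <= 0) stop("no growth between timepoints: zero generations")
  switch(formula,
         exact = estimate_m_beta1(R[1], R[2], n),
         general = estimate_m_general(R[1], R[2], n, beta = beta,
                                      mode = mode),
         linear = estimate_m_linear(R[1], R[2], n))
}

#' Replicate mean and standard error
#'
#' @param m Numeric vector of per-replicate loss-rate estimates (negative
#'   values retained).
#' @return A list: `mean`, `sem` (`NA` for a single replicate), `n`.
#' @export
aggregate_replicates <- function(m) {
  if (length(m) == 0) stop("no replicate estimates to aggregate")
  list(mean = mean(m),
       sem = if (length(m) >= 2) stats::sd(m) / sqrt(length(m)) else
         NA_real_,
       n = length(m))
}

#' Fold change and p-value of a strain versus the control
#'
#' Fold change is the ratio of replicate means. The Mann-Whitney U test uses
#' the exact two-sided distribution for group sizes up to 12 without ties
#' and the normal approximation with tie correction otherwise; all-tied data
#' return p = 1. `"welch_t"` selects the two-sided Welch t-test.
#'
#' @param strain_m,control_m Per-replicate estimates (>= 3 each for a
#'   meaningful test).
#' @param test `"mann_whitney"` or `"welch_t"`.
#' @return A list: `fold_change`, `p_value`, `test`.
#' @export
compare_to_control <- function(strain_m, control_m,
                               test = c("mann_whitney", "welch_t")) {
  test <- match.arg(test)
  fc <- mean(strain_m) / mean(control_m)
  all_vals <- c(strain_m, control_m)
  if (length(unique(all_vals)) == 1) {
    p <- 1
  } else if (test == "mann_whitney") {
    ties <- any(duplicated(all_vals))
    small <- max(length(strain_m), length(control_m)) <= 12
    p <- suppressWarnings(stats::wilcox.test(
      strain_m, control_m, exact = small && !ties,
      correct = TRUE)$p.value)
  } else {
    p <- stats::t.test(strain_m, control_m)$p.value
  }
  list(fold_change = fc, p_value = p, test = test)
}

#' Classify strains by the fold-change and p-value rule
#'
#' A strain is `elevated` when `fold_change > fc_threshold` and
#' `p < p_threshold`, `suppressed` when `fold_change < 1/fc_threshold` and
#' `p < p_threshold`, otherwise `none`. Both directions are reported: screens
#' for genes whose extra copy suppresses instability live in the low tail.
#'
#' @param records Data frame with `fold_change` and `p_value` columns.
#' @param fc_threshold,p_threshold Calling thresholds.
#' @return `records` with a `hit_class` column added.
#' @export
call_hits <- function(records, fc_threshold = 1.5, p_threshold = 0.01) {
  stopifnot(all(c("fold_change", "p_value") %in% names(records)))
  sig <- records$p_value < p_threshold
  records$hit_class <- ifelse(
    sig & records$fold_change > fc_threshold, "elevated",
    ifelse(sig & records$fold_change < 1 / fc_threshold, "suppressed",
           "none"))
  records
}

#' Primary-screen candidate selection by rank
#'
#' Ranks single-replicate loss rates and returns the `top_k_high` largest
#' and `top_k_low` smallest strains; ties are broken by lexicographic strain
#' id so the selection is deterministic and invariant to input row order.
#'
#' @param records Data frame with `strain` and `m` columns, one row per
#'   strain.
#' @param top_k_high,top_k_low Candidate counts for the two tails.
#' @return Tibble of candidates: `strain`, `m`, `tail` (`"high"`/`"low"`).
#' @export
primary_select <- function(records, top_k_high, top_k_low) {
  stopifnot(all(c("strain", "m") %in% names(records)))
  if (anyDuplicated(records$strain))
    stop("primary selection expects one estimate per strain")
  if (top_k_high > nrow(records) || top_k_low > nrow(records))
    stop("top-k exceeds the number of strains")
  ord_high <- order(-records$m, records$strain)
  ord_low <- order(records$m, records$strain)
  dplyr::bind_rows(
    tibble::tibble(strain = records$strain[ord_high[seq_len(top_k_high)]],
                   m = records$m[ord_high[seq_len(top_k_high)]],
                   tail = "high"),
    tibble::tibble(strain = records$strain[ord_low[seq_len(top_k_low)]],
                   m = records$m[ord_low[seq_len(top_k_low)]],
                   tail = "low"))
}

#' Fisher's exact test on a 2x2 table
#'
#' Conditional hypergeometric two-sided p-value (sum of tables with
#' probability not exceeding the observed one) and the sample odds ratio,
#' with a Haldane correction of 0.5 per cell when any cell is zero.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A list: `odds_ratio`, `p_value`.
#' @export
enrichment_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (sum(table) == 0) stop("all-zero table")
  p <- stats::fisher.test(table)$p.value
  tt <- if (any(table == 0)) table + 0.5 else table
  or <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
  list(odds_ratio = or, p_value = p)
}

.MANIFEST_COLS <- c("strain", "replicate", "timepoint", "gfp_pos",
                    "total_events", "od")

#' Validate a screen manifest
#'
#' Checks the column set and row-level sanity (counts within totals,
#' positive ODs, two timepoints per strain replicate), naming every
#' violation.
#'
#' @param manifest Data frame to check.
#' @return The manifest, invisibly, or an error describing the violations.
#' @export
validate_manifest <- function(manifest) {
  missing <- setdiff(.MANIFEST_COLS, names(manifest))
  if (length(missing) > 0)
    stop("manifest is missing required columns: ",
         paste(missing, collapse = ", "))
  bad <- which(manifest$gfp_pos > manifest$total_events)
  if (length(bad) > 0)
    stop("gfp_pos exceeds total_events at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(manifest$od <= 0)
  if (length(bad) > 0)
    stop("non-positive od at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  tp <- table(paste(manifest$strain, manifest$replicate))
  if (any(tp != 2))
    stop("every strain x replicate needs exactly two timepoint rows; ",
         "offending: ", paste(utils::head(names(tp)[tp != 2], 5),
                              collapse = ", "))
  invisible(manifest)
}

#' Read a screen manifest CSV
#'
#' Schema: `strain, replicate, phase, timepoint, gfp_pos, total_events, od,
#' time_min, dilution` (phase, time_min and dilution optional).
#'
#' @param path CSV file path.
#' @return Validated manifest tibble.
#' @export
read_screen_manifest <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  validate_manifest(df)
  df
}

#' Run the full screen analysis
#'
#' End-to-end per-strain pipeline: per-replicate loss rates from the
#' manifest rows, replicate aggregation, fold change and p-value against the
#' control strain, and hit calling. With single-replicate data (the primary
#' screen) candidates are instead selected by rank via [primary_select()].
#' Replicates that fail estimation (no GFP- events, no growth) are logged in
#' the exclusion table with their reason, never dropped silently.
#'
#' @param manifest Screen manifest (see [read_screen_manifest()]).
#' @param config A [screen_config()].
#' @return A `qctf_screen` list: `results` (per-strain tibble), `candidates`
#'   (hit or primary-candidate tibble), `exclusions`, `stage`
#'   (`"primary"` or `"validation"`), and the `config`.
#' @export
run_screen <- function(manifest, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  validate_manifest(manifest)
  if (!config$control_strain %in% manifest$strain)
    stop("control strain '", config$control_strain,
         "' is missing from the manifest")

  key <- paste(manifest$strain, manifest$replicate, sep = "\r")
  groups <- split(seq_len(nrow(manifest)), key)
  est <- list(); excl <- list()
  for (g in names(groups)) {
    rows <- manifest[groups[[g]], ]
    id <- strsplit(g, "\r", fixed = TRUE)[[1]]
    res <- tryCatch(
      estimate_strain_cin(rows, beta = config$beta,
                          formula = config$formula),
      error = function(e) e)
    if (inherits(res, "error")) {
      excl[[g]] <- tibble::tibble(strain = id[1], replicate = id[2],
                                  reason = conditionMessage(res))
    } else {
      est[[g]] <- tibble::tibble(strain = id[1], replicate = id[2],
                                 m = res$m)
    }
  }
  est <- dplyr::bind_rows(est)
  exclusions <- dplyr::bind_rows(excl)
  if (is.null(est$strain) || !config$control_strain %in% est$strain)
    stop("no usable replicate of the control strain survived estimation")

  per_strain <- lapply(split(est$m, est$strain), aggregate_replicates)
  strains <- names(per_strain)
  results <- tibble::tibble(
    strain = strains,
    mean_m = unname(vapply(per_strain, `[[`, numeric(1), "mean")),
    sem = unname(vapply(per_strain, `[[`, numeric(1), "sem")),
    n = unname(vapply(per_strain, `[[`, numeric(1), "n")))

  control_m <- est$m[est$strain == config$control_strain]
  if (max(results$n) == 1) {
    stage <- "primary"
    test_strains <- results[results$strain != config$control_strain, ]
    candidates <- primary_select(
      tibble::tibble(strain = test_strains$strain, m = test_strains$mean_m),
      config$top_k_high, config$top_k_low)
    results$fold_change <- results$mean_m / mean(control_m)
  } else {
    stage <- "validation"
    cmp <- lapply(strains, function(s) {
      if (s == config$control_strain)
        return(list(fold_change = 1, p_value = 1))
      compare_to_control(est$m[est$strain == s], control_m,
                         test = config$test)
    })
    results$fold_change <- vapply(cmp, `[[`, numeric(1), "fold_change")
    results$p_value <- vapply(cmp, `[[`, numeric(1), "p_value")
    if (config$p_adjust != "none") {
      idx <- results$strain != config$control_strain
      results$p_value[idx] <- stats::p.adjust(results$p_value[idx],
                                              method = config$p_adjust)
    }
    results <- call_hits(results, config$fc_threshold, config$p_threshold)
    results$hit_class[results$strain == config$control_strain] <- "none"
    candidates <- results[results$hit_class != "none", ]
  }
  structure(list(results = results, candidates = candidates,
                 exclusions = exclusions, stage = stage, config = config),
            class = "qctf_screen")
}

#' @export
print.qctf_screen <- function(x, ...) {
  cat(sprintf("qCTF screen (%s stage): %d strains, %d candidates, %d excluded replicates\n",
              x$stage, nrow(x$results), nrow(x$candidates),
              if (is.null(x$exclusions) || nrow(x$exclusions) == 0) 0L
              else nrow(x$exclusions)))
  invisible(x)
}

#' Write screen outputs to CSV
#'
#' Writes the per-strain results, the candidate table, and the exclusion log
#' under a common file prefix.
#'
#' @param screen A `qctf_screen` from [run_screen()].
#' @param prefix Output path prefix (directory must exist).
#' @return Paths written, invisibly.
#' @export
write_screen_results <- function(screen, prefix) {
  stopifnot(inherits(screen, "qctf_screen"))
  paths <- c(results = paste0(prefix, "_results.csv"),
             candidates = paste0(prefix, "_candidates.csv"),
             exclusions = paste0(prefix, "_exclusions.csv"))
  utils::write.csv(screen$results, paths["results"], row.names = FALSE)
  utils::write.csv(screen$candidates, paths["candidates"],
                   row.names = FALSE)
  excl <- screen$exclusions
  if (is.null(excl) || nrow(excl) == 0)
    excl <- tibble::tibble(strain = character(), replicate = character(),
                           reason = character())
  utils::write.csv(excl, paths["exclusions"], row.names = FALSE)
  invisible(paths)
}
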