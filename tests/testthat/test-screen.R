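# Screen statistics: per-replicate estimation, aggregation, tests, hit
# calling, candidate selection, enrichment, and the end-to-end pipeline.

two_tp_meas <- function(f0, f1, od0, od1, n_events = 3e5) {
  tibble::tibble(timepoint = c("t0", "t1"),
                 gfp_pos = round(n_events * c(f0, f1)),
                 total_events = n_events, od = c(od0, od1))
}

test_that("strain loss rates compose gates, ratios and generations", {
  m <- estimate_strain_cin(two_tp_meas(0.00246, 0.00746, 0.064, 2.048))
  # hand evaluation of the closed form at R = f/(1-f), n = log2(32) = 5
  expect_equal(m$m, 1.0044820e-3, tolerance = 1e-6)
  expect_equal(m$inputs$n, 5)
  # list input and dilution accounting
  m2 <- estimate_strain_cin(list(gfp_pos = c(738, 2238),
                                 total_events = c(3e5, 3e5),
                                 od = c(1.6, 1.6), dilution = 32))
  expect_equal(m2$m, m$m, tolerance = 1e-9)
  # no change in fractions means zero loss
  expect_equal(estimate_strain_cin(two_tp_meas(0.004, 0.004, 0.05, 1.6))$m,
               0)
  # linear and exact agree to 5% in the small-loss regime
  ml <- estimate_strain_cin(two_tp_meas(0.00246, 0.00746, 0.064, 2.048),
                            formula = "linear")
  expect_lt(abs(ml$m - m$m) / m$m, 0.05)
  # degenerate inputs carry explicit errors
  expect_error(estimate_strain_cin(two_tp_meas(0.001, 1, 0.05, 1.6)),
               "no GFP-")
  expect_error(estimate_strain_cin(two_tp_meas(0.001, 0.002, 0.5, 0.5)),
               "zero generations")
})

test_that("replicate aggregation returns mean and SEM with negatives kept", {
  expect_equal(aggregate_replicates(c(1, 1, 1, 1)),
               list(mean = 1, sem = 0, n = 4L))
  agg <- aggregate_replicates(c(1, 2, 3, 4))
  expect_equal(agg$mean, 2.5)
  expect_equal(agg$sem, 0.6454972, tolerance = 1e-6)
  single <- aggregate_replicates(5)
  expect_true(is.na(single$sem))
  expect_equal(aggregate_replicates(c(-1, 3))$mean, 1)
  expect_error(aggregate_replicates(numeric(0)), "no replicate")
})

test_that("control comparison produces exact Mann-Whitney p for separated groups", {
  x <- 1:8; y <- 11:18
  out <- compare_to_control(y, x)
  # exact two-sided p for complete separation: 2 / choose(16, 8)
  expect_equal(out$p_value, 2 / choose(16, 8), tolerance = 1e-12)
  expect_equal(compare_to_control(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  expect_equal(compare_to_control(c(2, 2, 2), c(2, 2, 2))$fold_change, 1)
  expect_equal(compare_to_control(rep(5e-3, 4), rep(1e-3, 4))$fold_change,
               5)
  # ties fall back to the corrected normal approximation without warnings
  expect_warning(
    p_tie <- compare_to_control(c(1, 1, 2, 3), c(1, 2, 2, 4))$p_value,
    regexp = NA)
  expect_true(p_tie > 0.1)
  # Welch option
  out_t <- compare_to_control(y, x, test = "welch_t")
  expect_equal(out_t$p_value, stats::t.test(y, x)$p.value)
})

test_that("hit calling applies the fold-change and p-value rule in both tails", {
  rec <- tibble::tibble(
    fold_change = c(5, 1.4, 0.6, 2, 0.5, 1),
    p_value = c(1e-6, 1e-6, 0.005, 0.05, 0.5, 0.9))
  out <- call_hits(rec)
  expect_equal(out$hit_class,
               c("elevated", "none", "suppressed", "none", "none", "none"))
})

test_that("primary selection is deterministic, tie-stable and order-invariant", {
  set.seed(12)
  rec <- tibble::tibble(strain = sprintf("s%02d", 1:10),
                        m = c(5, 9, 1, 7, 3, 8, 2, 6, 4, 10) / 1000)
  sel <- primary_select(rec, 2, 1)
  expect_equal(sel$strain[sel$tail == "high"], c("s10", "s02"))
  expect_equal(sel$strain[sel$tail == "low"], "s03")
  # permuting rows changes nothing
  perm <- rec[sample(10), ]
  expect_equal(primary_select(perm, 2, 1), sel)
  # ties resolved lexicographically
  tied <- tibble::tibble(strain = c("b", "a", "d", "c"), m = rep(1, 4))
  expect_equal(primary_select(tied, 3, 0)$strain, c("a", "b", "c"))
  expect_error(primary_select(rec, 11, 0), "exceeds")
  expect_error(primary_select(rbind(rec, rec), 1, 1), "one estimate")
})

test_that("enrichment test matches hypergeometric enumeration", {
  expect_equal(enrichment_test(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  t2 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(enrichment_test(t2)$p_value, fisher_p_enum(t2),
               tolerance = 1e-12)
  expect_equal(enrichment_test(t2)$p_value, 2 / choose(20, 10),
               tolerance = 1e-12)
  t3 <- matrix(c(2, 8, 8, 2), 2)
  expect_equal(enrichment_test(t3)$p_value, fisher_p_enum(t3),
               tolerance = 1e-12)
  # Haldane-corrected odds ratio when a cell is empty
  expect_equal(enrichment_test(t2)$odds_ratio,
               (10.5 * 10.5) / (0.5 * 0.5))
  expect_equal(enrichment_test(matrix(c(4, 2, 3, 6), 2))$odds_ratio,
               (4 * 6) / (2 * 3))
  expect_error(enrichment_test(matrix(0, 2, 2)), "all-zero")
  expect_error(enrichment_test(matrix(c(1, 2, 3, 4.5), 2)), "integers")
  expect_error(enrichment_test(matrix(1:6, 2)), "2x2")
})

test_that("manifest validation names missing columns and bad rows", {
  sc <- generate_screen(synthetic_screen_config(n_strains = 3,
                                                replicates = 2, seed = 2))
  expect_silent(validate_manifest(sc$manifest))
  expect_error(validate_manifest(sc$manifest[, -which(
    names(sc$manifest) == "od")]), "od")
  bad <- sc$manifest
  bad$gfp_pos[1] <- bad$total_events[1] + 1
  expect_error(validate_manifest(bad), "gfp_pos exceeds")
  expect_error(validate_manifest(sc$manifest[-1, ]), "two timepoint")
  # CSV round trip through the reader
  f <- tempfile(fileext = ".csv")
  utils::write.csv(sc$manifest, f, row.names = FALSE)
  rd <- read_screen_manifest(f)
  expect_equal(nrow(rd), nrow(sc$manifest))
  unlink(f)
})

test_that("run_screen validates, logs exclusions, and never drops rows silently", {
  sc <- generate_screen(synthetic_screen_config(n_strains = 6,
                                                replicates = 4, seed = 8))
  expect_error(run_screen(sc$manifest,
                          screen_config(control_strain = "nope")),
               "control strain")
  # break one replicate: all events positive at t1
  man <- sc$manifest
  i <- which(man$strain == "s0001" & man$replicate == "r1" &
               man$timepoint == "t1")
  man$gfp_pos[i] <- man$total_events[i]
  out <- run_screen(man, screen_config())
  expect_equal(out$exclusions$strain, "s0001")
  expect_equal(out$exclusions$replicate, "r1")
  expect_match(out$exclusions$reason, "no GFP-")
  expect_equal(out$results$n[out$results$strain == "s0001"], 3)
  # every non-excluded strain x replicate is accounted for
  expect_equal(sum(out$results$n) + nrow(out$exclusions), 7 * 4)
})

test_that("control versus itself is never a hit and planted effects are called", {
  cfg <- synthetic_screen_config(n_strains = 8, n_elevated = 2,
                                 n_suppressed = 2,
                                 elevated_palette = c(3, 5),
                                 suppressed_palette = 0.5,
                                 replicates = 8, strain_cv = 0,
                                 seed = 99)
  sc <- generate_screen(cfg)
  out <- run_screen(sc$manifest, screen_config())
  joined <- merge(out$results, sc$truth, by = "strain",
                  suffixes = c("", ".true"))
  expect_equal(joined$hit_class[joined$strain == "control"], "none")
  expect_true(all(joined$hit_class[joined$effect == "elevated"] ==
                    "elevated"))
  expect_true(all(joined$hit_class[joined$effect == "suppressed"] ==
                    "suppressed"))
  expect_true(all(joined$hit_class[joined$effect == "none"] == "none"))
  ctrl_fc <- joined$fold_change[joined$strain == "control"]
  expect_equal(ctrl_fc, 1)
  # per-strain fold changes reflect the planted ones
  expect_equal(joined$fold_change[joined$effect == "elevated"],
               joined$fold_change.true[joined$effect == "elevated"],
               tolerance = 0.15, ignore_attr = TRUE)
})

test_that("BH adjustment is available but off by default", {
  cfg <- screen_config(p_adjust = "BH")
  expect_equal(cfg$p_adjust, "BH")
  expect_equal(screen_config()$p_adjust, "none")
  sc <- generate_screen(synthetic_screen_config(n_strains = 5,
                                                replicates = 4, seed = 4))
  raw <- run_screen(sc$manifest, screen_config())
  adj <- run_screen(sc$manifest, cfg)
  idx <- raw$results$strain != "control"
  expect_true(all(adj$results$p_value[idx] >= raw$results$p_value[idx]))
})
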