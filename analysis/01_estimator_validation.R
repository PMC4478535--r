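#!/usr/bin/env Rscript
# Validates the loss-rate estimators against the forward population model:
# round trips of the general (fitness-corrected) solver, the beta = 1
# closed form, the accuracy envelope of the linearised formula, and the
# dependence of the inferred rate on the assumed fitness ratio.
#
# Usage: Rscript analysis/01_estimator_validation.R [seed]

suppressMessages(library(qctf))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1
dir.create("results", showWarnings = FALSE)

grid <- expand.grid(m = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2),
                    beta = c(0.8, 0.9, 1.0, 1.1, 1.25),
                    n = c(2, 5, 10, 20), R0 = c(0, 0.01, 0.05))
grid$Rn <- mapply(forward_ratio, grid$m, grid$beta, grid$n, grid$R0)
grid$m_hat <- mapply(function(m, beta, n, R0, Rn)
  estimate_m_general(R0, Rn, n, beta = beta, mode = "self_consistent")$m,
  grid$m, grid$beta, grid$n, grid$R0, grid$Rn)
grid$rel_error <- abs(grid$m_hat - grid$m) / grid$m
# the linearised formula is an equal-fitness approximation: score it on
# the beta = 1 slice only
grid$m_linear <- ifelse(grid$beta == 1,
                        mapply(function(R0, Rn, n)
                          estimate_m_linear(R0, Rn, n)$m,
                          grid$R0, grid$Rn, grid$n), NA)
grid$linear_rel_dev <- abs(grid$m_linear - grid$m) / grid$m
utils::write.csv(grid, "results/estimator_validation.csv",
                 row.names = FALSE)

cat(sprintf("general solver round trip: worst relative error %.3g over %d
parameter combinations (loss rates 1e-4..1e-2, fitness ratios 0.8..1.25).\n",
            max(grid$rel_error), nrow(grid)))
b1 <- grid[grid$beta == 1, ]
small <- b1$m * b1$n <= 0.05
cat(sprintf("linearised formula (beta = 1): worst deviation %.2f%% where
m*n <= 0.05 (%d cases), %.1f%% at the grid's largest cumulative loss.\n",
            100 * max(b1$linear_rel_dev[small]), sum(small),
            100 * max(b1$linear_rel_dev)))

# loss rate versus assumed fitness ratio for one observed ratio pair
rn <- forward_ratio(2e-3, 1, 8, 0.0025)
curve <- loss_rate_vs_beta(0.0025, rn, 8, seq(0.5, 2, by = 0.05))
curve$m_conventional <- loss_rate_vs_beta(0.0025, rn, 8, curve$beta,
                                     mode = "conventional")$m
utils::write.csv(curve, "results/loss_rate_vs_beta.csv", row.names = FALSE)
cat(sprintf("fitness-ratio sensitivity: for a pair generated at m = 2e-3,
assuming beta in [0.5, 2] moves the self-consistent estimate across
[%.3g, %.3g] (results/loss_rate_vs_beta.csv).\n",
            min(curve$m), max(curve$m)))
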