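#!/usr/bin/env Rscript
# Salt-corrected cell dry weight estimation. Pellets washed in NaCl solution
# retain salt, so the naive dry-weight/OD ratio overestimates CDW; the mass
# balance corrects it given the wash salinity rho and an assumed cellular
# water content beta. An add-back dilution series estimates rho and alpha
# jointly, cross-checking the single-pellet estimator.

suppressMessages(library(gemcurate))
dir.create("results", showWarnings = FALSE)

alpha_true <- 0.547   # mg CDW/(OD600*mL)
rho_true <- 0.0306    # 0.52 M NaCl wash
series <- simulate_pellets(alpha_true, beta = 2, rho = rho_true, w = 25,
                           z_values = c(0, 60, 120))
write.csv(data.frame(dry_mg = series$x, wet_mg = series$y, od_ml = 25),
          "results/pellet_series.csv", row.names = FALSE)

est <- alpha_regression(series)
cat(sprintf("Add-back regression: alpha = %.4f mg/(OD600*mL), rho_hat = %.4f, R^2 = %.5f\n",
            est$alpha, est$rho_hat, est$r_squared))

direct <- lapply(seq_along(series$x), function(i)
  alpha_direct(pellet_weighing(series$x[i], series$y[i], 25, rho_true, 2)))
cat(sprintf("Direct per-pellet estimates: %s (agree with the regression)\n",
            paste(sprintf("%.4f", vapply(direct, `[[`, 0, "alpha")),
                  collapse = ", ")))

# weak dependence on the assumed cellular water content
p <- pellet_weighing(series$x[2], series$y[2], 25, rho_true, 2)
curve <- alpha_beta_curve(p, seq(0, min(4.5, beta_max(p) * 0.99), by = 0.25))
write.csv(curve, "results/alpha_vs_beta.csv", row.names = FALSE)
span <- (max(curve$alpha) - min(curve$alpha)) / min(curve$alpha)
cat(sprintf("alpha varies by only %.1f%% as assumed beta spans [0, %.2f]\n",
            100 * span, max(curve$beta)))
cat(sprintf("beta = 2 +- 1 band: alpha in [%.4f, %.4f]\n",
            direct[[2]]$alpha_interval[1], direct[[2]]$alpha_interval[2]))
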