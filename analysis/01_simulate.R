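#!/usr/bin/env Rscript

# Step 1: generate the reference synthetic panel.
#
# The study conditions mirror the real-data setting the index methods are
# built for: 20 countries x 17 indicators x 10 years, one latent factor per
# country with sparse cross-country coupling, 5% gross outlier cells and 5%
# missing cells. The ground-truth factors are kept alongside so later steps
# can measure recovery.

suppressPackageStartupMessages(library(esrindex))

dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_countries = 20, n_variables = 17, n_years = 10,
                  k_factors = 1, outlier_fraction = 0.05,
                  missing_fraction = 0.05, seed = 42)
sim <- simulate_panel(cfg)

write_long_csv(sim$panel, "results/panel.csv")
truth <- data.frame(country = sim$panel$countries,
                    sim$truth$factors)
names(truth)[-1] <- paste0("y", sim$panel$years)
write.csv(truth, "results/true_factors.csv", row.names = FALSE)
write.csv(data.frame(variable = sim$panel$variables,
                     loading = sim$truth$loadings[, 1]),
          "results/true_loadings.csv", row.names = FALSE)

print(sim$panel)
cat(sprintf("outlier cells: %d, missing cells: %d\n",
            sum(sim$truth$outlier_mask), sum(sim$truth$missing_mask)))
cat("wrote results/panel.csv (+ true_factors.csv, true_loadings.csv)\n")
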