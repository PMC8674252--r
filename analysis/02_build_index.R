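#!/usr/bin/env Rscript

# Step 2: preprocess the panel and build the risk index with all four
# methods (per-year PCA, robust PCA, robust sparse PCA; whole-history DFM).
# Writes one long CSV per index plus the per-year loadings of the robust
# PCA index.

suppressPackageStartupMessages(library(esrindex))

panel <- read_long_csv("results/panel.csv")
prep <- preprocess_panel(panel, max_missing_fraction = 0.5)
cat(sprintf("imputed %d cells (%s); %d countries dropped\n",
            prep$reports$impute$n_cells_imputed,
            prep$reports$impute$imputation_method,
            nrow(prep$reports$drop$countries_dropped)))

std <- prep$panel
builds <- list(
  pca = pca_index(std, "pca"),
  robpca = pca_index(std, "robpca"),
  robsparpca = pca_index(std, "robsparpca"),
  dfm = suppressWarnings(dfm_index(std, alpha = 0.2,
                                   q_structure = "diagonal",
                                   with_interactions = FALSE))
)
for (m in names(builds)) {
  write_index_csv(builds[[m]]$index, sprintf("results/index_%s.csv", m))
}

# per-year aligned loadings of the robust PCA index
rob <- builds$robpca$fits
loads <- do.call(rbind, lapply(seq_along(rob), function(t)
  data.frame(year = std$years[t], variable = std$variables,
             loading = rob[[t]]$loadings_aligned[, 1])))
write.csv(loads, "results/loadings_robpca.csv", row.names = FALSE)

cat("wrote results/index_{pca,robpca,robsparpca,dfm}.csv and loadings_robpca.csv\n")
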