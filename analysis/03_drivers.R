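#!/usr/bin/env Rscript
# Stage 3: driver attribution.
#
# Reduces the environment to the nine driver terms (two PC axes per
# predictor group, HDT/HDP, river banks), ranks all 2^9 term subsets of the
# multinomial model of region membership by AICc, and partitions the best
# model's explained deviance into unique and shared fractions of climate
# (C), topography (T), rivers (R) and vegetation (V). Outputs:
# results/predictors.csv, results/pc_correlations.csv,
# results/model_ranking.csv, results/deviance_partition.csv.

suppressPackageStartupMessages(library(betaregion))

inc <- read_incidence("results/incidence.csv")
cells <- read.csv("results/cell_table.csv")
env <- read.csv("results/environment.csv", check.names = FALSE)
regions <- read.csv("results/region_labels.csv")

lat <- structure(list(cells = cells), class = "lattice")
pred <- build_predictor_table(env, lat, cell_ids = rownames(inc))
write.csv(pred, "results/predictors.csv", row.names = FALSE)

# which raw variables the PC axes represent
pcas <- attr(pred, "pca")
clim_cols <- c("AMAXTE", "AMINTE", "TESE", "APRE", "PRER", "PRSE")
corr <- rbind(
  cbind(group = "CURE", pc_variable_correlations(pcas$CURE$scores,
                                                 env[clim_cols])),
  cbind(group = "TOPO", pc_variable_correlations(pcas$TOPO$scores,
    env[c("TOPOMAX", "TOPOMIN", "TOPOSTD", "SLOPERAN", "SLOPESTD",
          "ASPECTSTD")])),
  cbind(group = "VEGE", pc_variable_correlations(pcas$VEGE$scores,
    env[grep("^VEG_", names(env), value = TRUE)])))
write.csv(corr, "results/pc_correlations.csv", row.names = FALSE)

y <- factor(regions$region[match(pred$cell_id, regions$cell_id)])
groups <- attr(pred, "groups")
terms_df <- pred[names(groups)]

ranking <- dredge_models(terms_df, y, ridge_lambda = 1e-6)
write.csv(ranking$table, "results/model_ranking.csv", row.names = FALSE)
cat("top of the model ranking:\n")
print(head(ranking$table[c("terms", "df", "delta_AICc", "wAICc", "pct_DE")],
           5), row.names = FALSE)

best <- ranking$best_terms
if (length(unique(groups[best])) < 2) best <- names(groups)
part <- partition_deviance(terms_df[best], groups[best], y,
                           ridge_lambda = 1e-6)
write.csv(part$fractions, "results/deviance_partition.csv", row.names = FALSE)

fr <- setNames(part$fractions$fraction, part$fractions$component)
cat(sprintf("\nfull model %%DE = %.1f; unexplained = %.1f\n",
            part$full_pct_DE, part$unexplained))
un <- fr[intersect(c("C", "T", "R", "V"), names(fr))]
cat("unique fractions (%DE points):\n")
print(round(un, 2))
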