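#!/usr/bin/env Rscript
# Stage 5: redundancy analysis of log10 k_pH7 on 10 environmental factors
# (TOC, TCC, EC, DO, pH, 1/T, clay, sand, longitude, latitude; silt dropped
# for collinearity). Global significance by 999 row permutations; per-
# variable envfit on the first two constrained axes.

suppressPackageStartupMessages(library(riverkin))

env <- read.csv("results/synthetic/site_env.csv")
rates <- read.csv("results/rates.csv")
f_dis <- read.csv("results/f_dis.csv")
props <- read.csv("results/synthetic/compound_properties.csv")
included <- readLines("results/included_compounds.txt")

rm_dense <- country_median_fill(correct_rate_matrix(
  gap_fill_chain(rate_matrix(rates)), f_dis, props, env))
dense_ok <- included[rowSums(!is.finite(
  subset_compounds(rm_dense, included)$values)) == 0]

resp <- ordination_response(rm_dense, dense_ok)
pred <- prepare_predictors(env)[rownames(resp), ]
rda <- run_rda(resp, pred, permutations = 999, seed = 1)

write_table_csv(rda$per_variable, "results/rda_per_variable.csv")
write_table_csv(data.frame(site = rownames(rda$site_scores), rda$site_scores),
                "results/rda_site_scores.csv")
write_table_csv(data.frame(variable = rownames(rda$biplot_arrows),
                           rda$biplot_arrows), "results/rda_arrows.csv")

message(sprintf("RDA on %d compounds x %d segments", ncol(resp), nrow(resp)))
message(sprintf("model explains %.0f%% of variance (%.0f%% unbiased), p = %.3g",
                100 * rda$r2_total, 100 * rda$r2_adjusted, rda$p_model))
message(sprintf("first two constrained axes: %.0f%% (RDA1 %.0f%%)",
                100 * sum(rda$axis_shares[1:2]), 100 * rda$axis_shares[1]))
top <- rda$per_variable[order(rda$per_variable$p_envfit), ][1:3, ]
message("strongest envfit variables: ",
        paste(sprintf("%s (R2=%.2f, p=%.3f)", top$name, top$r2_envfit,
                      top$p_envfit), collapse = ", "))
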