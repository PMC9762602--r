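#!/usr/bin/env Rscript

# Step 2 — compare the three imputation methods.
#
# Masks a known fraction of observed cells in a clean synthetic cohort,
# imputes with median/KNN/MICE, and reports the RMSE of each method on the
# masked numeric cells, in SD units. The cohort is generated with a strong
# health-consciousness confounder so diet/supplement/activity features are
# correlated -- the structure multivariate imputers exploit; on independent
# features all three methods tie at ~1 SD by construction.

suppressPackageStartupMessages(library(bcaisd))
set.seed(2)

n <- 1500
g <- generate_cohort(generator_config(
  n = n, seed = 2, target_event_rate = 0.10, confounder_strength = 1,
  block_missing_rates = c(BLINE = 0, HLQ = 0, CDHQ1 = 0, PYTPAQ = 0),
  item_missing_rate = 0))
schema <- attr(g$cohort, "schema")
feats <- schema$name
num_feats <- schema$name[schema$dtype == "numeric"]

full <- g$cohort[feats]
masked <- full
mask <- list()
for (nm in num_feats) {
  holes <- sample(n, round(0.05 * n))
  mask[[nm]] <- holes
  masked[[nm]][holes] <- NA
}

rmse_of <- function(completed) {
  errs <- unlist(lapply(num_feats, function(nm) {
    sc <- stats::sd(full[[nm]])
    if (sc == 0) return(NULL)
    (completed[[nm]][mask[[nm]]] - full[[nm]][mask[[nm]]]) / sc
  }))
  sqrt(mean(errs^2))
}

res <- data.frame(
  method = c("median", "knn", "mice"),
  rmse_sd_units = c(
    rmse_of(impute_median(masked)),
    rmse_of(impute_knn(masked, k = 2)),
    rmse_of(impute_mice(masked, iters = 10, seed = 2))))
print(res)
dir.create("results", showWarnings = FALSE)
write.csv(res, "results/imputation_comparison.csv", row.names = FALSE)
cat("Lower is better; the chained-equation imputer exploits the\n",
    "correlation that the shared confounder/risk structure induces.\n")
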