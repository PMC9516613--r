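#!/usr/bin/env Rscript
# Cross-cohort age trends: inverse-SE-weighted linear meta-regression
# of each cluster's cohort-level mean score on cohort mean age, over
# the simulated consortium.

library(cariesharm)

paths <- Sys.glob("results/sim/synth_*.csv")
stopifnot(length(paths) >= 3)
map <- default_cluster_map()

cohorts <- lapply(paths, read_surface_csv)
ages <- vapply(cohorts, function(co) mean(co$subjects$age), numeric(1))

fits <- do.call(rbind, lapply(1:5, function(c) {
  pts <- t(vapply(cohorts, function(co)
    standard_error_of_mean(cluster_scores(co, map)[, c]), numeric(2)))
  fit <- fit_meta_regression(pts[, "mean"], pts[, "se"], ages)
  data.frame(cluster = c,
             slope = fit$slope, slope_se = fit$slope_se,
             ci_lower = fit$slope_ci95[1], ci_upper = fit$slope_ci95[2])
}))
write.csv(fits, "results/meta_regression.csv", row.names = FALSE)
print(fits, row.names = FALSE)
if (all(fits$slope > 0)) {
  cat("every cluster's caries experience increases with cohort mean age\n")
}
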