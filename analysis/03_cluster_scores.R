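#!/usr/bin/env Rscript
# Tier 3: per-subject scores on the five predefined surface clusters
# and a cohort summary table (one row per cohort, as a consortium
# summary table would print it).  Also renders the cluster map as a
# plain-text odontogram.

library(cariesharm)

paths <- Sys.glob("results/sim/synth_*.csv")
stopifnot(length(paths) > 0)
dir.create("results/clusters", showWarnings = FALSE)
map <- default_cluster_map()

summaries <- do.call(rbind, lapply(paths, function(p) {
  co <- read_surface_csv(p)
  nm <- tools::file_path_sans_ext(basename(p))
  sc <- cluster_scores(co, map)
  write.csv(data.frame(subject_id = rownames(sc), sc),
            file.path("results/clusters", paste0("scores_", nm, ".csv")),
            row.names = FALSE)
  summarize_cohort(co, map, cohort_name = nm)
}))
write.csv(summaries, "results/clusters/cohort_summary.csv",
          row.names = FALSE)

print(summaries[, c("cohort", "n", "age_mean", "pct_cases",
                    paste0("c", 1:5, "_mean"))], row.names = FALSE)

ranks <- t(apply(-as.matrix(summaries[paste0("c", 1:5, "_mean")]), 1, rank))
cat("cluster rank order by cohort (1 = highest experience):\n")
print(ranks)

sink("results/clusters/odontogram.txt")
render_odontogram(map)
sink()
cat("odontogram written to results/clusters/odontogram.txt\n")
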