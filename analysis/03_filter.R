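#!/usr/bin/env Rscript
# Statistical outlier removal on the fused cloud from 02_reconstruct.R:
# each point's mean distance to its 64 nearest neighbours is compared with
# the cloud-wide mean + 1 SD of those distances. Writes the filtered cloud
# and the per-point report.

library(swardscan)

out <- "results/reconstruction"
in_ply <- file.path(out, "demo_canopy_fused.ply")
if (!file.exists(in_ply))
  stop("run analysis/02_reconstruct.R first (missing ", in_ply, ")")

cloud <- read_ply(in_ply)
res <- remove_outliers(cloud, k = 64, mode = "mean_plus_sd", multiplier = 1)
write_ply(res$cloud, file.path(out, "demo_canopy_filtered.ply"))
rep_df <- data.frame(index = seq_len(nrow(cloud)),
                     mean_knn_dist_m = res$report$mean_knn_dist,
                     removed = seq_len(nrow(cloud)) %in% res$report$removed)
write.csv(rep_df, file.path(out, "filter_report.csv"), row.names = FALSE)

cat(sprintf(
  "Filtered %d of %d points (%.2f%%) above the %.2f mm threshold\n",
  length(res$report$removed), nrow(cloud),
  100 * length(res$report$removed) / nrow(cloud),
  1000 * res$report$threshold))
cat("outputs in", out, "\n")
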