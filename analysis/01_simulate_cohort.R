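#!/usr/bin/env Rscript
# Stage 1: simulate the study-shaped cohort and build both connectomes.
#
# The cohort mirrors the study design this pipeline targets: 18 patients vs
# 25 controls, regional time series and regional grey-matter value samples
# on a 40-region atlas split over the eight intrinsic networks.  Three
# ground-truth effects are planted in the patient group so later stages
# have something to find:
#   * a DMN-FPN functional covariance increase,
#   * an LN-SN structural (distributional) separation,
#   * weaker LN coupling and stronger DMN coupling.
suppressPackageStartupMessages(library(netcouple))

out <- "scratch/cohort"
dir.create(file.path(out, "matrices"), recursive = TRUE, showWarnings = FALSE)

atlas <- make_atlas(40)
effects <- effect_spec(
  fc_block = list(list(networks = c("DMN", "FPN"), shift = 0.3)),
  sc_pair  = list(list(networks = c("LN", "SN"), shift = -0.6)),
  coupling = c(LN = "weaker", DMN = "stronger"))

cohort <- simulate_cohort(18, 25, atlas, effects, T_len = 150,
                          voxels_per_region = 80, seed = 20240901)
print(cohort)

write_atlas(atlas, file.path(out, "atlas.tsv"))
groups <- data.frame(id = vapply(cohort$subjects, `[[`, "", "id"),
                     group = vapply(cohort$subjects, `[[`, "", "group"))
write.table(groups, file.path(out, "groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

for (s in cohort$subjects) {
  fc <- build_fc(s$timeseries, atlas, q = 0.05)
  sc <- build_sc(s$voxel_samples, atlas, grid_size = 128)
  write_matrix(fc, file.path(out, "matrices", paste0(s$id, "_FC.tsv")))
  write_matrix(sc, file.path(out, "matrices", paste0(s$id, "_SC.tsv")))
}
cat("wrote", 2 * nrow(groups), "connectome matrices under", out, "\n")
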