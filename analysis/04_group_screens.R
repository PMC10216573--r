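#!/usr/bin/env Rscript
# Stage 4: permutation screens of coupling differences, scale by scale.
#
# Each feature (region or network) is tested with the two-sided
# mean-difference permutation test; features at p < 0.05 uncorrected are
# flagged, with the sign of the statistic saying which group couples more
# tightly.  Negative statistics = weaker coupling in patients.
suppressPackageStartupMessages(library(netcouple))

src <- "scratch/cohort"
atlas <- read_atlas(file.path(src, "atlas.tsv"))
groups <- read.table(file.path(src, "groups.tsv"), header = TRUE,
                     stringsAsFactors = FALSE)
profiles <- lapply(groups$id, function(id) {
  fc <- read_matrix(file.path(src, "matrices", paste0(id, "_FC.tsv")),
                    atlas = atlas, kind = "FC")
  sc <- read_matrix(file.path(src, "matrices", paste0(id, "_SC.tsv")),
                    atlas = atlas, kind = "SC")
  coupling_profile(sc, fc, atlas, id = id)
})
pa <- profiles[groups$group == "patient"]
pb <- profiles[groups$group == "control"]

dir.create("results/screens", showWarnings = FALSE, recursive = TRUE)
for (scale in c("node", "within", "between", "global")) {
  scr <- coupling_group_screen(pa, pb, scale = scale, n_perm = 2000, seed = 11)
  write.table(scr, sprintf("results/screens/%s.tsv", scale), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sig <- scr[scr$significant, ]
  cat(sprintf("\n%s scale: %d/%d features significant (p < 0.05, 2000 perms)\n",
              scale, nrow(sig), nrow(scr)))
  if (nrow(sig)) {
    sig$network <- if (scale == "global") sig$feature else
      atlas$network[match(sig$feature, atlas$region)]
    print(sig[order(sig$p), c("feature", "network", "statistic", "p")],
          row.names = FALSE, digits = 3)
  }
}
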