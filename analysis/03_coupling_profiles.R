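#!/usr/bin/env Rscript
# Stage 3: per-subject structure-function coupling at all five scales.
#
# For every subject the SC and FC matrices are correlated at the
# whole-brain scale (positive SC edges, rank-Gaussianized), per network,
# per node, and per node within/between its own network.  The table of
# group means gives a first look at where coupling separates the groups.
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
names(profiles) <- groups$id

node_tab <- do.call(rbind, lapply(profiles, function(p)
  data.frame(id = p$id, region = names(p$node), node = p$node,
             within = p$within_network, between = p$between_network,
             row.names = NULL)))
node_tab$group <- groups$group[match(node_tab$id, groups$id)]
dir.create("results/coupling", showWarnings = FALSE, recursive = TRUE)
# per-region group summary; the per-subject detail is recomputed on demand
summ <- do.call(rbind, lapply(split(node_tab, node_tab$region), function(d) {
  data.frame(region = d$region[1],
             node_patient = signif(mean(d$node[d$group == "patient"], na.rm = TRUE), 6),
             node_control = signif(mean(d$node[d$group == "control"], na.rm = TRUE), 6),
             within_patient = signif(mean(d$within[d$group == "patient"], na.rm = TRUE), 6),
             within_control = signif(mean(d$within[d$group == "control"], na.rm = TRUE), 6),
             between_patient = signif(mean(d$between[d$group == "patient"], na.rm = TRUE), 6),
             between_control = signif(mean(d$between[d$group == "control"], na.rm = TRUE), 6))
}))
summ <- summ[match(atlas$region, summ$region), ]
write.table(summ, "results/coupling/node_scales_group_means.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

wb <- data.frame(id = groups$id, group = groups$group,
                 whole_brain = vapply(profiles, `[[`, 0, "whole_brain"))
write.table(wb, "results/coupling/whole_brain.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("group-mean whole-brain coupling:\n")
print(tapply(wb$whole_brain, wb$group, mean))
cat("\ngroup-mean node coupling by network:\n")
node_tab$network <- atlas$network[match(node_tab$region, atlas$region)]
print(round(tapply(node_tab$node, list(node_tab$network, node_tab$group),
                   mean, na.rm = TRUE), 3))
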