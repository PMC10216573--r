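#!/usr/bin/env Rscript
# Stage 2: localize group differences with the network-based statistic.
#
# Each modality (FC, SC) is tested in both directions (patients > controls
# and patients < controls) as separate one-tailed contrasts at the p < 0.001
# primary threshold, with corrected p-values from the permutation null of
# the maximal component extent.  Significant components are tallied by
# network pair, the summary the study design reads its anatomy from.
suppressPackageStartupMessages(library(netcouple))

src <- "scratch/cohort"
atlas <- read_atlas(file.path(src, "atlas.tsv"))
groups <- read.table(file.path(src, "groups.tsv"), header = TRUE,
                     stringsAsFactors = FALSE)
read_stack <- function(ids, kind) {
  lapply(ids, function(id)
    read_matrix(file.path(src, "matrices", paste0(id, "_", kind, ".tsv")),
                atlas = atlas, kind = kind))
}
pat <- groups$id[groups$group == "patient"]
ctl <- groups$id[groups$group == "control"]

dir.create("results/nbs", showWarnings = FALSE, recursive = TRUE)
for (kind in c("FC", "SC")) {
  sa <- read_stack(pat, kind); sb <- read_stack(ctl, kind)
  for (dir_ in c("gt", "lt")) {
    res <- nbs_test(sa, sb, primary_p = 0.001, n_perm = 2000,
                    direction = dir_, seed = 7)
    label <- sprintf("%s, patients %s controls", kind,
                     if (dir_ == "gt") ">" else "<")
    cat("\n==", label, "==\n")
    print(res)
    rows <- lapply(res$components, function(cc) {
      tl <- tally_network_pairs(cc, atlas)
      data.frame(pair = names(tl$counts), edges = as.integer(tl$counts),
                 percent = round(unname(tl$percent), 2),
                 component_extent = cc$extent,
                 corrected_p = cc$corrected_p)
    })
    if (length(rows)) {
      tab <- do.call(rbind, rows)
      print(tab, row.names = FALSE)
      write.table(tab, sprintf("results/nbs/%s_%s_tally.tsv", kind, dir_),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      cat("  (nothing to tally)\n")
    }
  }
}
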