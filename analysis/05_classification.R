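#!/usr/bin/env Rscript
# Stage 5: can coupling features tell the groups apart?
#
# Features significant in the stage-4 screen feed a linear SVM evaluated by
# leave-one-out cross-validation, with label-permutation significance for
# the accuracy.  Selection on the full sample mirrors the classical
# workflow and is optimistic; the nested variant repeats the selection
# inside every training fold and is the honest number.
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

dir.create("results/classify", showWarnings = FALSE, recursive = TRUE)
for (scale in c("node", "within", "between")) {
  scr <- coupling_group_screen(pa, pb, scale = scale, n_perm = 2000, seed = 11)
  if (!any(scr$significant)) {
    cat(scale, "scale: no significant features, skipping\n"); next
  }
  feats <- select_features(pa, pb, scr, scale = scale)
  clf <- loocv_classify(feats$x, feats$y, backend = "svm", C = 1, seed = 13)
  pt <- permutation_test_classifier(feats$x, feats$y, n_perm = 500,
                                    seed = 13, observed = clf)
  # leakage-free comparison: selection redone inside every training fold
  nested_select <- function(xtr, ytr) {
    ps <- apply(xtr, 2, function(col) {
      permutation_mean_diff_test(col[ytr == "patient"],
                                 col[ytr == "control"],
                                 n_perm = 300, seed = 17)$p
    })
    which(ps < 0.05)
  }
  all_x <- rbind(
    t(vapply(pa, `[[`, pa[[1]][[if (scale == "node") "node" else
      paste0(scale, "_network")]], if (scale == "node") "node" else
      paste0(scale, "_network"))),
    t(vapply(pb, `[[`, pb[[1]][[if (scale == "node") "node" else
      paste0(scale, "_network")]], if (scale == "node") "node" else
      paste0(scale, "_network"))))
  clf_nested <- loocv_classify(all_x, feats$y, backend = "svm", C = 1,
                               seed = 13, nested = nested_select)
  cat(sprintf(
    "\n%s scale (%d features): accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%% (perm p = %.4g)\n",
    scale, length(feats$features), 100 * clf$accuracy, 100 * clf$sensitivity,
    100 * clf$specificity, pt$p))
  cat(sprintf("  nested selection: accuracy %.1f%%\n", 100 * clf_nested$accuracy))
  report <- data.frame(scale = scale, n_features = length(feats$features),
                       accuracy = clf$accuracy, sensitivity = clf$sensitivity,
                       specificity = clf$specificity, permutation_p = pt$p,
                       nested_accuracy = clf_nested$accuracy)
  write.table(report, sprintf("results/classify/%s.tsv", scale), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
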