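#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with the keys below;
#' unknown keys are rejected so typos fail loudly before any stage runs.
#'
#' \describe{
#'   \item{cohort}{`n_patient`, `n_control`, `n_regions`, `T_len`,
#'     `voxels_per_region`, `seed` for the synthetic generator, plus an
#'     optional `effects` block (`fc_block`, `sc_pair`, `coupling`).}
#'   \item{fc}{`q` — the FDR level for edge retention.}
#'   \item{sc}{`grid_size`, `variant`.}
#'   \item{nbs}{`primary_p`, `n_perm`, `directions`, `seed`, `modalities`.}
#'   \item{screen}{`scales`, `n_perm`, `seed`, `alpha`.}
#'   \item{classify}{`enabled`, `scale`, `backend`, `C`, `n_perm`, `seed`.}
#' }
#'
#' @param config named list or path to a YAML file.
#' @return the validated, default-filled config.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    cohort = list(n_patient = 18, n_control = 25, n_regions = 40,
                  T_len = 230, voxels_per_region = 100, seed = 1,
                  effects = list(fc_block = list(), sc_pair = list(),
                                 coupling = character())),
    fc = list(q = 0.05),
    sc = list(grid_size = 128, variant = "jsd_sqrt"),
    nbs = list(primary_p = 0.001, n_perm = 5000, directions = c("gt", "lt"),
               seed = 1, modalities = c("fc", "sc")),
    screen = list(scales = c("node", "within", "between", "global"),
                  n_perm = 5000, seed = 1, alpha = 0.05),
    classify = list(enabled = TRUE, scale = "node", backend = "svm", C = 1,
                    n_perm = 1000, seed = 1)
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config section(s): ",
                            paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad)) stop("unknown key(s) in '", sec, "': ",
                          paste(bad, collapse = ", "))
    defaults[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  defaults
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Sequences every stage end to end: simulate the cohort, build per-subject
#' functional and structural connectomes, run directional network-based
#' statistics per modality, compute coupling profiles, screen coupling
#' differences per scale, and (optionally) classify the groups.  All
#' artifacts — matrices as tab-separated text, results and the exact config
#' as JSON/YAML — are written under `out_dir`.  Reruns with an identical
#' config reproduce identical numbers.
#'
#' @param config see [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`cohort`, `fc`,
#'   `sc`, `nbs`, `profiles`, `screens`, `classifier`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("ncrun")) {
  cfg <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))

  co <- cfg$cohort
  eff <- effect_spec(fc_block = co$effects$fc_block,
                     sc_pair = co$effects$sc_pair,
                     coupling = unlist(co$effects$coupling) %||% character())
  atlas <- make_atlas(co$n_regions)
  cohort <- simulate_cohort(co$n_patient, co$n_control, atlas, eff,
                            T_len = co$T_len,
                            voxels_per_region = co$voxels_per_region,
                            seed = co$seed)
  write_atlas(atlas, file.path(out_dir, "atlas.tsv"))

  mat_dir <- file.path(out_dir, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  fc <- list(); sc <- list()
  for (s in cohort$subjects) {
    fc[[s$id]] <- build_fc(s$timeseries, atlas, q = cfg$fc$q)
    sc[[s$id]] <- build_sc(s$voxel_samples, atlas,
                           grid_size = cfg$sc$grid_size,
                           variant = cfg$sc$variant)
    write_matrix(fc[[s$id]], file.path(mat_dir, paste0(s$id, "_FC.tsv")))
    write_matrix(sc[[s$id]], file.path(mat_dir, paste0(s$id, "_SC.tsv")))
  }
  grp <- vapply(cohort$subjects, `[[`, "", "group")
  ids <- vapply(cohort$subjects, `[[`, "", "id")
  pat <- ids[grp == "patient"]; ctl <- ids[grp == "control"]

  nbs_res <- list()
  for (mod in cfg$nbs$modalities) {
    stacks <- if (mod == "fc") fc else sc
    for (dir_ in cfg$nbs$directions) {
      key <- paste(mod, dir_, sep = "_")
      res <- nbs_test(stacks[pat], stacks[ctl],
                      primary_p = cfg$nbs$primary_p,
                      n_perm = cfg$nbs$n_perm, direction = dir_,
                      seed = cfg$nbs$seed)
      tallies <- lapply(res$components, function(cc)
        unclass(tally_network_pairs(cc, atlas))[c("counts", "percent", "total")])
      nbs_res[[key]] <- res
      jz <- list(direction = dir_, modality = mod, t_crit = res$t_crit,
                 n_perm = res$n_perm,
                 components = lapply(seq_along(res$components), function(k) {
                   cc <- res$components[[k]]
                   list(nodes = atlas$region[cc$nodes], extent = cc$extent,
                        corrected_p = cc$corrected_p,
                        network_pairs = as.list(tallies[[k]]$counts))
                 }))
      jsonlite::write_json(jz, file.path(out_dir, paste0("nbs_", key, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  profiles <- lapply(cohort$subjects, function(s)
    coupling_profile(sc[[s$id]], fc[[s$id]], atlas, id = s$id))
  names(profiles) <- ids
  profA <- profiles[pat]; profB <- profiles[ctl]
  jsonlite::write_json(
    lapply(profiles, function(p) lapply(unclass(p), function(v)
      if (is.numeric(v)) as.list(v) else v)),
    file.path(out_dir, "coupling_profiles.json"), auto_unbox = TRUE,
    digits = NA)

  screens <- list()
  for (sca in cfg$screen$scales) {
    screens[[sca]] <- coupling_group_screen(profA, profB, scale = sca,
                                            n_perm = cfg$screen$n_perm,
                                            seed = cfg$screen$seed,
                                            alpha = cfg$screen$alpha)
    utils::write.table(screens[[sca]],
                       file.path(out_dir, paste0("screen_", sca, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  classifier <- NULL
  if (isTRUE(cfg$classify$enabled) &&
      any(screens[[cfg$classify$scale]]$significant)) {
    feats <- select_features(profA, profB, screens[[cfg$classify$scale]],
                             scale = cfg$classify$scale)
    clf <- loocv_classify(feats$x, feats$y, backend = cfg$classify$backend,
                          C = cfg$classify$C, seed = cfg$classify$seed)
    pt <- permutation_test_classifier(feats$x, feats$y,
                                      n_perm = cfg$classify$n_perm,
                                      seed = cfg$classify$seed,
                                      backend = cfg$classify$backend,
                                      C = cfg$classify$C, observed = clf)
    classifier <- list(report = clf, permutation = pt)
    jsonlite::write_json(
      list(scale = cfg$classify$scale, backend = cfg$classify$backend,
           features = feats$features, accuracy = clf$accuracy,
           sensitivity = clf$sensitivity, specificity = clf$specificity,
           permutation_p = pt$p, n_perm = pt$n_perm,
           predictions = clf$predictions),
      file.path(out_dir, "classifier.json"), auto_unbox = TRUE, digits = NA)
  }

  prov <- list(r_version = as.character(getRversion()),
               package_version = as.character(utils::packageVersion("netcouple")),
               timestamp = format(Sys.time(), tz = "UTC"),
               seeds = list(cohort = co$seed, nbs = cfg$nbs$seed,
                            screen = cfg$screen$seed,
                            classify = cfg$classify$seed))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(list(cohort = cohort, fc = fc, sc = sc, nbs = nbs_res,
                 profiles = profiles, screens = screens,
                 classifier = classifier, out_dir = out_dir))
}
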