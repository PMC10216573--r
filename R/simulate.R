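#' Plantable group-effect specification
#'
#' Encodes the ground truth a synthetic cohort carries, in three channels:
#'
#' * `fc_block` — additive shifts to the patient-group covariance on the
#'   block of edges joining two networks (use the same network twice for a
#'   within-network block).  A positive shift raises patient functional
#'   connectivity on that block, a negative shift lowers it.
#' * `sc_pair` — shifts of the regional grey-matter value locations of two
#'   networks in patients: a negative shift moves the two networks' value
#'   distributions apart (their pairwise similarity drops), a positive shift
#'   moves them together (similarity rises).
#' * `coupling` — per-network `"weaker"` or `"stronger"` structure-function
#'   coupling in patients, implemented by scaling the subject-specific edge
#'   noise on the covariance rows of the network's regions (more noise
#'   degrades the agreement between a subject's functional and structural
#'   profiles, less noise tightens it).
#'
#' @param fc_block list of `list(networks = c(A, B), shift = s)` entries;
#'   `shift` is signed.
#' @param sc_pair list of `list(networks = c(A, B), shift = s)` entries;
#'   `shift` is signed as described above.
#' @param coupling named character vector, e.g.
#'   `c(LN = "weaker", DMN = "stronger")`.
#' @return an object of class `nc_effects`.
#' @export
effect_spec <- function(fc_block = list(), sc_pair = list(), coupling = character()) {
  chk_pair <- function(e, what) {
    if (!is.list(e) || length(e$networks) != 2 || !is.numeric(e$shift) ||
        !is.finite(e$shift)) {
      stop(what, " effects must be list(networks = c(A, B), shift = finite)")
    }
    if (!all(e$networks %in% NETWORKS)) {
      stop("unknown network in ", what, " effect: ",
           paste(setdiff(e$networks, NETWORKS), collapse = ", "))
    }
    e
  }
  fc_block <- lapply(fc_block, chk_pair, what = "fc_block")
  sc_pair <- lapply(sc_pair, chk_pair, what = "sc_pair")
  if (length(coupling)) {
    if (is.null(names(coupling)) || !all(names(coupling) %in% NETWORKS)) {
      stop("coupling effects must be named by network")
    }
    if (!all(coupling %in% c("weaker", "stronger"))) {
      stop("coupling directions must be 'weaker' or 'stronger'")
    }
  }
  structure(list(fc_block = fc_block, sc_pair = sc_pair, coupling = coupling),
            class = "nc_effects")
}

# Generator constants.  The cohort emulates a resting-state study: regions
# carry a smooth grey-matter intensity gradient mu, structural similarity
# falls off with |mu_r - mu_s|, and the functional covariance combines a
# network block structure with a gradient-alignment term so that baseline
# structure-function coupling is positive.  Subject-specific symmetric edge
# noise (sd eta) is the handle the coupling effects scale.
.nc_gen <- list(
  rho_within   = 0.5,   # baseline within-network correlation
  rho_between  = 0.1,   # baseline between-network correlation
  gamma_align  = 0.3,   # weight of the gradient-alignment covariance term
  tau_align    = 0.6,   # length scale of the alignment kernel (mu units)
  eta_edge     = 0.1,   # sd of subject-specific edge noise on the covariance
  weaker_mult  = 3,     # edge-noise multiplier for "weaker"-coupled networks
  stronger_mult = 0.2,  # edge-noise multiplier for "stronger"-coupled networks
  mu_span      = 3,     # regional gradient runs over [0, mu_span]
  voxel_sd     = 0.35,  # within-region grey-matter value spread
  eig_floor    = 1e-6   # eigenvalue clip for positive definiteness
)

# smooth regional location gradient, with patient-group sc_pair shifts applied
region_mu <- function(atlas, group = "control", effects = effect_spec()) {
  R <- nrow(atlas)
  mu <- seq(0, .nc_gen$mu_span, length.out = R)
  if (group == "patient") {
    for (e in effects$sc_pair) {
      ia <- network_members(atlas, e$networks[1])
      ib <- network_members(atlas, e$networks[2])
      gap_sign <- if (mean(mu[ia]) >= mean(mu[ib])) 1 else -1
      # negative shift: apart (similarity down); positive: together
      d <- abs(e$shift) / 2 * gap_sign * (if (e$shift < 0) 1 else -1)
      mu[ia] <- mu[ia] + d
      mu[ib] <- mu[ib] - d
    }
  }
  mu
}

# nearest symmetric positive-definite projection by eigenvalue clipping,
# rescaled back to unit diagonal
project_spd <- function(S, floor = .nc_gen$eig_floor) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  S2 <- e$vectors %*% (vals * t(e$vectors))
  S2 <- (S2 + t(S2)) / 2
  if (any(diag(S2) <= 0)) stop("covariance projection failed: nonpositive diagonal")
  stats::cov2cor(S2)
}

# the group/subject covariance for the functional time series
fc_covariance <- function(atlas, group, effects, subject_noise_seed = NULL) {
  R <- nrow(atlas)
  same_net <- outer(atlas$network, atlas$network, "==")
  S <- matrix(.nc_gen$rho_between, R, R)
  S[same_net] <- .nc_gen$rho_within
  mu0 <- region_mu(atlas)  # alignment uses the unshifted gradient
  S <- S + .nc_gen$gamma_align *
    exp(-outer(mu0, mu0, "-")^2 / (2 * .nc_gen$tau_align^2))
  if (group == "patient") {
    for (e in effects$fc_block) {
      ia <- network_members(atlas, e$networks[1])
      ib <- network_members(atlas, e$networks[2])
      S[ia, ib] <- S[ia, ib] + e$shift
      S[ib, ia] <- t(S[ia, ib])
    }
  }
  # subject-specific symmetric edge noise; coupling effects scale it per row
  eta <- rep(.nc_gen$eta_edge, R)
  if (group == "patient" && length(effects$coupling)) {
    for (nw in names(effects$coupling)) {
      mult <- if (effects$coupling[[nw]] == "weaker") .nc_gen$weaker_mult
              else .nc_gen$stronger_mult
      eta[network_members(atlas, nw)] <- .nc_gen$eta_edge * mult
    }
  }
  if (!is.null(subject_noise_seed)) set.seed(subject_noise_seed)
  E <- matrix(stats::rnorm(R * R), R, R)
  E <- (E + t(E)) / sqrt(2)
  scale_edge <- sqrt(outer(eta, eta))  # geometric mean of row sds
  S <- S + E * scale_edge
  diag(S) <- 1
  project_spd(S)
}

#' Simulate a subject's regional time series
#'
#' Rows are drawn from a zero-mean multivariate normal whose covariance has
#' within-network blocks at a baseline correlation, a lower between-network
#' baseline, a gradient-alignment term that ties it to the structural
#' gradient, patient-group block shifts, and subject-specific edge noise.
#' The covariance is projected to the nearest symmetric positive-definite
#' correlation matrix (eigenvalues clipped at 1e-6) before sampling.
#'
#' @param atlas an `nc_atlas`.
#' @param group `"patient"` or `"control"`.
#' @param effects an [effect_spec()].
#' @param T_len number of timepoints (>= 20).
#' @param seed integer seed for this subject.
#' @return a `T_len` x R matrix with region labels as column names.
#' @export
simulate_timeseries <- function(atlas, group = c("control", "patient"),
                                effects = effect_spec(), T_len = 230,
                                seed = 1) {
  group <- match.arg(group)
  if (T_len < 20) stop("T_len must be >= 20")
  Sigma <- fc_covariance(atlas, group, effects, subject_noise_seed = seed)
  set.seed(seed + 1L)
  ts <- MASS::mvrnorm(n = T_len, mu = rep(0, nrow(atlas)), Sigma = Sigma)
  colnames(ts) <- atlas$region
  ts
}

#' Simulate a subject's regional grey-matter voxel samples
#'
#' Region r draws `voxels_per_region` values from a normal with a
#' region-specific location on a smooth gradient; `sc_pair` effects move the
#' locations of the named networks' regions apart (negative shift) or
#' together (positive shift) in patients, so their pairwise similarity
#' decreases or increases.
#'
#' @inheritParams simulate_timeseries
#' @param voxels_per_region values per region (>= 10).
#' @return named list of numeric vectors, one per region in atlas order.
#' @export
simulate_voxel_samples <- function(atlas, group = c("control", "patient"),
                                   effects = effect_spec(),
                                   voxels_per_region = 100, seed = 1) {
  group <- match.arg(group)
  if (voxels_per_region < 10) stop("voxels_per_region must be >= 10")
  mu <- region_mu(atlas, group, effects)
  set.seed(seed)
  out <- lapply(seq_len(nrow(atlas)), function(r) {
    stats::rnorm(voxels_per_region, mean = mu[r], sd = .nc_gen$voxel_sd)
  })
  names(out) <- atlas$region
  out
}

#' Simulate a two-group cohort
#'
#' @inheritParams simulate_timeseries
#' @param n_patient,n_control group sizes (each >= 2); defaults mirror an
#'   18-patient / 25-control study.
#' @param voxels_per_region values per region for the structural channel.
#' @param seed master seed; per-subject seeds are derived deterministically
#'   from it, so the cohort is reproducible and each subject individually
#'   re-simulable.
#' @return an object of class `nc_cohort`: list with `atlas`, `effects`,
#'   `seed` and `subjects`, each subject a list
#'   `(id, group, timeseries, voxel_samples)`.
#' @export
simulate_cohort <- function(n_patient = 18, n_control = 25,
                            atlas = make_atlas(40),
                            effects = effect_spec(), T_len = 230,
                            voxels_per_region = 100, seed = 1) {
  if (n_patient < 2 || n_control < 2) stop("both group sizes must be >= 2")
  groups <- c(rep("patient", n_patient), rep("control", n_control))
  ids <- c(sprintf("P%03d", seq_len(n_patient)),
           sprintf("C%03d", seq_len(n_control)))
  subjects <- lapply(seq_along(groups), function(i) {
    s_ts <- derive_seed(seed, 2L * i)
    s_vx <- derive_seed(seed, 2L * i + 1L)
    list(id = ids[i], group = groups[i],
         timeseries = simulate_timeseries(atlas, groups[i], effects,
                                          T_len = T_len, seed = s_ts),
         voxel_samples = simulate_voxel_samples(atlas, groups[i], effects,
                                                voxels_per_region = voxels_per_region,
                                                seed = s_vx))
  })
  structure(list(atlas = atlas, effects = effects, seed = seed,
                 subjects = subjects),
            class = "nc_cohort")
}

# deterministic child seeds below 2^31
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

#' @export
print.nc_cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, `[[`, "", "group"))
  cat("Synthetic cohort:", length(x$subjects), "subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), "),",
      nrow(x$atlas), "regions, T =", nrow(x$subjects[[1]]$timeseries),
      ", seed", x$seed, "\n")
  invisible(x)
}
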