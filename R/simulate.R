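#' Default inter-component FNC structure
#'
#' A modular correlation matrix emulating resting-state functional domains:
#' components are split into two blocks (e.g. sensory vs associative) with
#' strong within-block and weak between-block correlation. Positive definite
#' by construction.
#'
#' @param c_true Number of components.
#' @param within,between Within- and between-block correlations.
#' @return A `c_true` x `c_true` correlation matrix.
#' @export
default_sigma_fnc <- function(c_true, within = 0.65, between = 0.2) {
  half <- ceiling(c_true / 2)
  block <- rep(c(1L, 2L), c(half, c_true - half))
  S <- outer(block, block, function(a, b) ifelse(a == b, within, between))
  diag(S) <- 1
  S
}

# Random correlation matrix from a Wishart-type draw (off-diagonal sd ~
# 1/sqrt(df)); used as a generic SPD correlation sample in tests.
random_correlation <- function(c, df = 3L * c) {
  W <- matrix(rnorm(c * df), c, df)
  stats::cov2cor(tcrossprod(W))
}

# nearest-PD projection by eigenvalue clipping, rescaled to unit diagonal
make_pd_correlation <- function(M, eps = 1e-4) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) > eps) return(M)
  stats::cov2cor(e$vectors %*% diag(pmax(e$values, eps)) %*% t(e$vectors))
}

# A subject's aberrant connectivity state R_i, a random SPD correlation
# matrix centred near the cohort pattern. Two geometries:
#  * diffuse: every connection perturbed by symmetric Fisher-z noise — the
#    deviation has no cohort-common direction, which keeps the distance to
#    the cohort-mean reference monotone in the planted deviation weight.
#  * dysconnectivity: a random ~30% of connections are knocked down to
#    50-100% of their strength — deviation manifests as loss of (mostly
#    strong, within-module) connections, the clinical regime in which more
#    deviation entails lower weighted global efficiency.
aberrant_fnc_state <- function(sigma_fnc, mode = c("diffuse", "dysconnectivity"),
                               z_noise_sd = 0.75, knockout_prob = 0.3) {
  mode <- match.arg(mode)
  c <- nrow(sigma_fnc)
  ut <- upper.tri(sigma_fnc)
  R <- sigma_fnc
  if (mode == "diffuse") {
    Z <- matrix(0, c, c)
    Z[ut] <- rnorm(sum(ut), 0, z_noise_sd)
    Z <- Z + t(Z)
    sigz <- atanh(sigma_fnc * (1 - diag(c)))
    R <- tanh(sigz + Z)
  } else {
    U <- matrix(0, c, c)
    U[ut] <- rbinom(sum(ut), 1L, knockout_prob) * runif(sum(ut), 0.5, 1)
    U <- U + t(U)
    R <- sigma_fnc * (1 - U)
  }
  diag(R) <- 1
  make_pd_correlation(R)
}

# zero-mean Gaussian time courses with the given target correlation
draw_timecourses <- function(t_len, target) {
  ch <- chol(target)
  matrix(rnorm(t_len * nrow(target)), t_len) %*% ch
}

# separable 3D Gaussian smoothing via per-axis banded matrices
smooth_field <- function(arr, sigma) {
  d <- dim(arr)
  for (ax in 1:3) {
    M <- smooth_matrix(d[ax], sigma)
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    a <- array(M %*% matrix(a, d[ax]), d[perm])
    arr <- aperm(a, order(perm))
  }
  arr
}

smooth_matrix <- function(n, sigma) {
  M <- outer(seq_len(n), seq_len(n), function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  M / rowSums(M)
}

# Smooth blob maps over the spherical support, standardized over it. Each
# component is one main Gaussian bump plus a half-amplitude satellite; the
# main centers are placed by farthest-point sampling from a random candidate
# pool so that the components occupy distinct territories — spatial ICA
# assumes (near-)independent sources, and resting-state networks are largely
# non-overlapping parcellations of cortex.
make_group_maps <- function(grid, brain, c_true) {
  center <- (grid + 1) / 2
  rmax <- 0.38 * min(grid)
  coords <- arrayInd(brain, grid)
  pool <- matrix(runif(3L * 200L, -rmax, rmax), ncol = 3L)
  pool <- sweep(pool, 2L, center, `+`)
  centers <- matrix(NA_real_, c_true, 3L)
  centers[1, ] <- pool[1, ]
  for (j in seq_len(c_true)[-1]) {
    d2min <- apply(pool, 1L, function(p) {
      min(colSums((t(centers[seq_len(j - 1L), , drop = FALSE]) - p)^2))
    })
    centers[j, ] <- pool[which.max(d2min), ]
  }
  G <- matrix(0, c_true, length(brain))
  for (j in seq_len(c_true)) {
    sig <- runif(1, 1.2, 1.6)
    sat <- centers[j, ] + runif(3, -1.5, 1.5)
    d2m <- (coords[, 1] - centers[j, 1])^2 + (coords[, 2] - centers[j, 2])^2 +
      (coords[, 3] - centers[j, 3])^2
    d2s <- (coords[, 1] - sat[1])^2 + (coords[, 2] - sat[2])^2 +
      (coords[, 3] - sat[3])^2
    field <- exp(-d2m / (2 * sig^2)) + 0.5 * exp(-d2s / (2 * sig^2))
    G[j, ] <- standardize_vec(field, "group map")
  }
  # symmetric (Loewdin) orthogonalization: the networks are exactly mutually
  # uncorrelated over the support, matching the ICA generative model; the
  # residual overlaps are small, so each map is only minimally perturbed
  e <- eigen(tcrossprod(G) / ncol(G), symmetric = TRUE)
  G <- e$vectors %*% diag(1 / sqrt(e$values), c_true) %*% t(e$vectors) %*% G
  t(apply(G, 1L, standardize_vec, what = "group map"))
}

#' Simulate a multi-subject resting-fMRI cohort with known ground truth
#'
#' Generates N = `n_controls` + `n_patients` subjects (controls first) whose
#' 4D volumes are mixtures of shared smooth spatial maps with
#' subject-specific spatial perturbations, time courses with a controllable
#' inter-component correlation structure, a baseline intensity offset inside
#' a spherical "brain" support (so mean-activation masking is exercised),
#' and white measurement noise. Covariates, realignment motion parameters,
#' and SNP dosages with a planted causal effect on the spatial perturbation
#' are generated alongside.
#'
#' Ground truth per subject i: the spatial perturbation magnitude
#' `delta_i = delta0 * (1 + group_effect * diagnosis_i) * exp(eta_i) +
#' beta_g * dosage(causal SNP)` with `eta_i ~ N(0, delta_sd^2)`; subject
#' maps are `standardize(G_j + delta_i * E_ij)` with E a smoothed
#' unit-variance noise field. The connectivity perturbation
#' `gamma_i = min(0.9, gamma0 * (1 + group_effect * diagnosis_i) *
#' exp(nu_i))` mixes the cohort structure with a subject-specific random
#' correlation matrix: time courses are drawn with correlation
#' `(1 - gamma_i) * Sigma + gamma_i * R_i`. Patients receive
#' multiplicatively larger perturbations (default 1.5x), matching the
#' direction in which patients deviate more from the cohort-common pattern.
#'
#' @param n_controls,n_patients Group sizes (default 30/30).
#' @param grid 3-vector of volume dimensions (default `c(15, 15, 15)`).
#' @param t_len Number of volumes per subject (default 120).
#' @param c_true Number of ground-truth components (default 8).
#' @param tr Repetition time in seconds (default 2).
#' @param delta0 Baseline spatial perturbation magnitude, in units of the
#'   standardized map SD (default 0.4).
#' @param delta_sd SD of the log-normal subject heterogeneity in delta.
#' @param gamma0 Baseline FNC perturbation weight in `[0, 1)` (default 0.35).
#' @param gamma_sd SD of the log-normal subject heterogeneity in gamma.
#' @param group_effect Multiplicative patient excess: patients' delta and
#'   gamma are scaled by `1 + group_effect` (default 0.5, i.e. 1.5x).
#' @param beta_g Additive effect of one effect allele of the causal SNP on
#'   delta (default 0.05).
#' @param snr Signal-to-noise variance ratio of the mixed signal to the
#'   white noise; `Inf` for noiseless data (default 10).
#' @param sigma_fnc Cohort inter-component correlation matrix; defaults to
#'   [default_sigma_fnc()].
#' @param fnc_deviation Geometry of the subject-specific aberrant
#'   connectivity state R_i. `"diffuse"` (default) perturbs every connection
#'   with symmetric Fisher-z noise, leaving no cohort-common deviation
#'   direction — the regime in which the planted deviation weight gamma is
#'   maximally identifiable from the FNC variability feature.
#'   `"dysconnectivity"` knocks a random subset of connections down towards
#'   zero, emulating loss of (mostly within-module) connection strength —
#'   in this regime larger deviation entails lower weighted global
#'   efficiency, as observed clinically.
#' @param n_snps Number of simulated SNPs (default 100).
#' @param maf_range Minor-allele-frequency range (default `c(0.05, 0.5)`).
#' @param n_sites Number of (balanced, randomly assigned) sites.
#' @param baseline Baseline intensity added inside the brain support.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param dir Optional directory: when given, NIfTI volumes, motion/
#'   covariate/genotype/weight TSVs, a manifest and a JSON truth file are
#'   written there and their paths recorded in the result.
#' @return An `rsn_simulation` list: `cohort` (an `rsn_cohort`), `truth`
#'   (a `simulation_truth`), `genotypes` (N x S dosage matrix),
#'   `snp_weights` (tibble), and `paths` (when `dir` was given).
#' @export
simulate_cohort <- function(n_controls = 30L, n_patients = 30L,
                            grid = c(15L, 15L, 15L), t_len = 120L,
                            c_true = 8L, tr = 2,
                            delta0 = 0.4, delta_sd = 0.3,
                            gamma0 = 0.35, gamma_sd = 0.8,
                            group_effect = 0.5, beta_g = 0.05,
                            snr = 10, sigma_fnc = NULL,
                            fnc_deviation = c("diffuse", "dysconnectivity"),
                            n_snps = 100L, maf_range = c(0.05, 0.5),
                            n_sites = 2L, baseline = 100, seed = 1L,
                            dir = NULL) {
  fnc_deviation <- match.arg(fnc_deviation)
  if (c_true > t_len / 2) abort("c_true must be at most t_len / 2")
  n <- n_controls + n_patients
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  ids <- sprintf("sub%03d", seq_len(n))
  diagnosis <- rep(c(0L, 1L), c(n_controls, n_patients))

  # spherical brain support, comfortably above the feasibility floor
  center <- (grid + 1) / 2
  radius <- 0.45 * min(grid)
  vox <- arrayInd(seq_len(prod(grid)), grid)
  dist2 <- (vox[, 1] - center[1])^2 + (vox[, 2] - center[2])^2 +
    (vox[, 3] - center[3])^2
  brain <- which(dist2 <= radius^2)
  if (length(brain) < 500L) {
    abort(sprintf("grid yields only %d brain voxels (< 500)", length(brain)))
  }

  G <- make_group_maps(grid, brain, c_true)

  maf <- runif(n_snps, maf_range[1], maf_range[2])
  dosage <- matrix(rbinom(n * n_snps, 2L, rep(maf, each = n)), n, n_snps,
                   dimnames = list(ids, sprintf("rs%05d", seq_len(n_snps))))
  causal <- sample.int(n_snps, 1L)
  or <- exp(rnorm(n_snps, 0, 0.05))
  or[causal] <- 1.2
  snp_weights <- tibble::tibble(
    snp_id = colnames(dosage),
    effect_allele = sample(c("A", "C", "G", "T"), n_snps, replace = TRUE),
    odds_ratio = or
  )

  eta <- rnorm(n, 0, delta_sd)
  delta <- delta0 * (1 + group_effect * diagnosis) * exp(eta) +
    beta_g * dosage[, causal]
  nu <- rnorm(n, 0, gamma_sd)
  gamma <- pmin(0.9, gamma0 * (1 + group_effect * diagnosis) * exp(nu))

  if (is.null(sigma_fnc)) sigma_fnc <- default_sigma_fnc(c_true)
  stopifnot(nrow(sigma_fnc) == c_true, isSymmetric(sigma_fnc))

  affine <- diag(c(3, 3, 3, 1))
  scans <- vector("list", n)
  subject_maps <- vector("list", n)
  subject_fnc <- vector("list", n)
  subject_tc <- vector("list", n)
  for (i in seq_len(n)) {
    E <- matrix(0, c_true, length(brain))
    for (j in seq_len(c_true)) {
      field <- smooth_field(array(rnorm(prod(grid)), grid), 1.5)
      E[j, ] <- standardize_vec(field[brain], "perturbation field")
    }
    # project the perturbation fields off the group-map span: the planted
    # spatial deviation then shifts each network into novel territory
    # without bleeding into the other components' recovered time courses,
    # keeping the delta and gamma ground truths separable downstream
    E <- E - (E %*% t(G)) %*% solve(tcrossprod(G)) %*% G
    E <- t(apply(E, 1L, standardize_vec, what = "perturbation field"))
    Si <- t(apply(G + delta[i] * E, 1L, standardize_vec, what = "subject map"))
    Ri <- aberrant_fnc_state(sigma_fnc, fnc_deviation)
    target <- make_pd_correlation((1 - gamma[i]) * sigma_fnc + gamma[i] * Ri)
    A <- draw_timecourses(t_len, target)
    sig <- A %*% Si
    noise_sd <- if (is.finite(snr)) {
      v <- colMeans(sig^2) - colMeans(sig)^2
      sqrt(mean(v) / snr)
    } else 0
    mat <- if (noise_sd > 0) {
      matrix(rnorm(prod(grid) * t_len, sd = noise_sd), prod(grid), t_len)
    } else {
      matrix(0, prod(grid), t_len)
    }
    mat[brain, ] <- mat[brain, ] + baseline + t(sig)
    motion <- apply(matrix(rnorm(t_len * 6L,
                                 sd = rep(c(0.02, 0.002), each = 3L * t_len)),
                           t_len, 6L), 2L, cumsum)
    scans[[i]] <- subject_scan(ids[i], array(mat, c(grid, t_len)),
                               affine = affine, tr = tr, motion = motion)
    subject_maps[[i]] <- Si
    subject_fnc[[i]] <- target
    subject_tc[[i]] <- A
  }

  covariates <- tibble::tibble(
    subject_id = ids,
    diagnosis = diagnosis,
    age = round(runif(n, 18, 65)),
    sex = rbinom(n, 1L, 0.5),
    site = sample(rep_len(sprintf("site%d", seq_len(n_sites)), n))
  )

  truth <- structure(
    list(group_maps = G, subject_maps = subject_maps,
         subject_fnc = subject_fnc, subject_timecourses = subject_tc,
         brain_index = brain,
         delta = setNames(delta, ids), gamma = setNames(gamma, ids),
         sigma_fnc = sigma_fnc,
         causal_snp = list(index = causal, snp_id = colnames(dosage)[causal],
                           beta = beta_g),
         group_effect = group_effect, fnc_deviation = fnc_deviation,
         grid = grid, seed = as.integer(seed)),
    class = "simulation_truth"
  )
  sim <- structure(
    list(cohort = new_rsn_cohort(scans, covariates), truth = truth,
         genotypes = dosage, snp_weights = snp_weights, paths = NULL),
    class = "rsn_simulation"
  )
  rsn_log("simulate", "N=%d grid=%s T=%d c_true=%d snr=%s seed=%d",
          n, paste(grid, collapse = "x"), t_len, c_true, format(snr), seed)
  if (!is.null(dir)) sim <- write_simulation(sim, dir)
  sim
}

#' Simulate a genotype dosage matrix
#'
#' Binomial(2, MAF) dosages with per-SNP allele frequencies drawn uniformly
#' from `maf_range`. Used standalone for association-scale experiments where
#' no imaging is needed.
#'
#' @param n Number of subjects.
#' @param n_snps Number of SNPs.
#' @param maf_range Allele-frequency range.
#' @return An `n` x `n_snps` integer dosage matrix with SNP-id column names
#'   and a `"maf"` attribute.
#' @export
simulate_genotypes <- function(n, n_snps, maf_range = c(0.05, 0.5)) {
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  d <- matrix(rbinom(n * n_snps, 2L, rep(maf, each = n)), n, n_snps,
              dimnames = list(sprintf("S%d", seq_len(n)),
                              sprintf("rs%05d", seq_len(n_snps))))
  attr(d, "maf") <- maf
  d
}

#' @export
print.rsn_simulation <- function(x, ...) {
  cat(sprintf("<rsn_simulation> %d subjects (%d patients), %d ground-truth components, causal SNP %s\n",
              length(x$cohort$scans), sum(x$cohort$covariates$diagnosis),
              nrow(x$truth$group_maps), x$truth$causal_snp$snp_id))
  invisible(x)
}

#' Recovery metrics of a pipeline run against the simulation truth
#'
#' Compares pipeline outputs with the generator's ground truth: greedy
#' |correlation| matching of group maps, per-subject map recovery, Spearman
#' correlation of the planted spatial perturbation `delta` with the mean
#' Euclidean RSN variability, Spearman correlation of the planted
#' connectivity perturbation `gamma` with the Euclidean FNC variability,
#' the direction and significance of the diagnosis effect, and the rank of
#' the causal SNP in an association scan. Sections whose inputs are not
#' supplied are skipped.
#'
#' @param truth A `simulation_truth`.
#' @param dec Optional `group_decomposition` fitted on the simulated cohort.
#' @param rsn_var Optional [rsn_variability()] table.
#' @param fnc_var Optional [fnc_variability()] table.
#' @param group_scan Optional [group_difference_scan()] result.
#' @param snp Optional [snp_scan()] result.
#' @return Tibble with `quantity`, `value`, `detail`.
#' @export
truth_report <- function(truth, dec = NULL, rsn_var = NULL, fnc_var = NULL,
                         group_scan = NULL, snp = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  rows <- list()
  matching <- NULL
  if (!is.null(dec)) {
    if (!setequal(dec$subject_ids, names(truth$delta))) {
      abort("decomposition subjects do not match the simulated cohort")
    }
    common <- intersect(dec$mask$voxel_index, truth$brain_index)
    gt <- truth$group_maps[, match(common, truth$brain_index), drop = FALSE]
    est <- dec$s_agg[, match(common, dec$mask$voxel_index), drop = FALSE]
    matching <- match_components(est, gt)
    rows$map <- tibble::tibble(
      quantity = "group_map_recovery", value = mean(matching$abs_cor),
      detail = "mean |cor| of greedily matched group maps over shared voxels")
    subj_cor <- vapply(seq_along(dec$maps), function(i) {
      sm <- dec$maps[[i]][, match(common, dec$mask$voxel_index), drop = FALSE]
      st <- truth$subject_maps[[i]][, match(common, truth$brain_index), drop = FALSE]
      mean(vapply(seq_len(nrow(matching)), function(k)
        abs(cor(sm[matching$est[k], ], st[matching$truth[k], ])), 1.0))
    }, 1.0)
    rows$subj <- tibble::tibble(
      quantity = "subject_map_recovery", value = mean(subj_cor),
      detail = "mean |cor| of subject maps against their own truth")
  }
  if (!is.null(rsn_var)) {
    vm <- variability_matrix(rsn_var, "euclidean")
    mv <- rowMeans(as.matrix(vm[, -1]))
    ord <- match(vm$subject_id, names(truth$delta))
    rows$delta <- tibble::tibble(
      quantity = "delta_recovery_spearman",
      value = cor(truth$delta[ord], mv, method = "spearman"),
      detail = "Spearman(planted delta, mean Euclidean RSN variability)")
  }
  if (!is.null(fnc_var)) {
    fv <- dplyr::filter(fnc_var, .data$metric == "euclidean")
    ord <- match(fv$subject_id, names(truth$gamma))
    rows$gamma <- tibble::tibble(
      quantity = "gamma_recovery_spearman",
      value = cor(truth$gamma[ord], fv$value, method = "spearman"),
      detail = "Spearman(planted gamma, Euclidean FNC variability)")
  }
  if (!is.null(group_scan)) {
    eu <- dplyr::filter(group_scan, .data$metric == "euclidean")
    top <- eu[which.min(eu$p), ]
    rows$gd <- tibble::tibble(
      quantity = c("group_difference_n_significant", "group_difference_top_t"),
      value = c(sum(eu$significant), top$t),
      detail = c("Bonferroni-significant Euclidean components",
                 paste("direction:", top$direction)))
  }
  if (!is.null(snp)) {
    r <- which(snp$term == truth$causal_snp$snp_id)
    rows$snp <- tibble::tibble(
      quantity = c("causal_snp_rank", "causal_snp_p_adjusted"),
      value = c(if (length(r)) r else NA_real_,
                if (length(r)) snp$p_adjusted[r] else NA_real_),
      detail = paste("causal SNP", truth$causal_snp$snp_id))
  }
  dplyr::bind_rows(rows)
}
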