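# Shared simulated cohorts and pipeline runs, built once per test session.
# Heavy objects are memoised so several test files can reuse the same run.

options(rsnvar.quiet = TRUE)

.rsn_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .rsn_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .rsn_cache)
  }
  get(key, envir = .rsn_cache, inherits = FALSE)
}

# small cohort for fast structural tests
small_sim <- function(seed = 7) {
  cached(paste0("small", seed), simulate_cohort(
    n_controls = 4L, n_patients = 4L, grid = c(12L, 12L, 12L),
    t_len = 60L, c_true = 4L, seed = seed))
}

# run every pipeline stage on a simulation and return all products
full_pipeline <- function(sim, seed, n_components = nrow(sim$truth$group_maps)) {
  dec <- group_ica(sim$cohort, n_components = n_components, seed = seed)
  rv <- rsn_variability(dec)
  cs <- fnc_cohort(dec)
  zs <- lapply(cs, normalize_fnc)
  ref <- mean_fnc(zs)
  fv <- fnc_variability(zs, ref)
  eff <- efficiency_table(cs)
  gd <- group_difference_scan(rv, sim$cohort$covariates)
  list(sim = sim, dec = dec, rsn_var = rv, fnc_raw = cs, fnc_z = zs,
       fnc_ref = ref, fnc_var = fv, efficiency = eff, group_scan = gd)
}

# the desk-scale study cohort (diffuse deviation, SNR 10) plus pipeline run
preset_run <- function() {
  cached("preset", full_pipeline(simulate_cohort(seed = 101L), seed = 101L))
}

# longer scans for the connectivity-side studies (see methods vignette)
gamma_run <- function() {
  cached("gamma", full_pipeline(
    simulate_cohort(seed = 202L, t_len = 300L), seed = 202L))
}

dysconnectivity_run <- function() {
  cached("dysco", full_pipeline(
    simulate_cohort(seed = 303L, t_len = 600L,
                    fnc_deviation = "dysconnectivity"), seed = 303L))
}

# exhaustive shortest-path oracle: enumerate all simple paths by DFS
enumerate_shortest_paths <- function(L) {
  J <- nrow(L)
  best <- matrix(Inf, J, J)
  diag(best) <- 0
  dfs <- function(node, target, visited, len) {
    if (len >= best[visited[1], target]) return(invisible(NULL))
    if (node == target) {
      best[visited[1], target] <<- len
      return(invisible(NULL))
    }
    for (nxt in seq_len(J)) {
      if (!(nxt %in% visited) && is.finite(L[node, nxt])) {
        dfs(nxt, target, c(visited, nxt), len + L[node, nxt])
      }
    }
  }
  for (a in seq_len(J)) {
    for (b in seq_len(J)) {
      if (a != b) dfs(a, b, a, 0)
    }
  }
  best
}

# reference efficiency from the exhaustive oracle
oracle_efficiency <- function(W) {
  J <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- Inf
  d <- enumerate_shortest_paths(L)
  inv <- 1 / d
  diag(inv) <- 0
  nodal <- rowSums(inv) / (J - 1)
  list(nodal = nodal, global = mean(nodal))
}

random_symmetric_weights <- function(J, zero_frac = 0.2) {
  W <- matrix(0, J, J)
  ut <- upper.tri(W)
  w <- runif(sum(ut))
  w[runif(sum(ut)) < zero_frac] <- 0
  W[ut] <- w
  W + t(W)
}
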