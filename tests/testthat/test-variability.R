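test_that("Euclidean deviation matches its definition and simple geometry", {
  x <- rnorm(50)
  expect_identical(euclidean_variability(x, x), 0)
  expect_equal(euclidean_variability(c(0, 0), c(3, 4)), 5)
  expect_error(euclidean_variability(1:3, 1:4), "length")
})

test_that("Pearson deviation hits its closed-form anchors and matches cor()", {
  set.seed(31)
  x <- rnorm(100)
  expect_equal(pearson_variability(x, x), 1, tolerance = 1e-12)
  expect_equal(pearson_variability(x, -x), -1, tolerance = 1e-12)
  y <- rnorm(100)
  expect_equal(pearson_variability(x, y), cor(x, y), tolerance = 1e-12)
  expect_error(pearson_variability(rep(1, 10), rnorm(10)), "constant")
})

test_that("metric oracles: loop implementations agree to 1e-10 on random pairs", {
  set.seed(32)
  loop_euclid <- function(x, r) {
    acc <- 0
    for (k in seq_along(x)) acc <- acc + (x[k] - r[k])^2
    sqrt(acc)
  }
  loop_pearson <- function(x, r) {
    mx <- mean(x); mr <- mean(r)
    num <- den1 <- den2 <- 0
    for (k in seq_along(x)) {
      num <- num + (x[k] - mx) * (r[k] - mr)
      den1 <- den1 + (x[k] - mx)^2
      den2 <- den2 + (r[k] - mr)^2
    }
    num / (sqrt(den1) * sqrt(den2))
  }
  for (rep in 1:25) {
    x <- rnorm(1000); r <- rnorm(1000)
    expect_equal(euclidean_variability(x, r), loop_euclid(x, r), tolerance = 1e-10)
    expect_equal(pearson_variability(x, r), loop_pearson(x, r), tolerance = 1e-10)
  }
})

test_that("KL deviation matches a hand-computed two-bin case", {
  # shared edges over pooled range [0.1, 0.8]; bin split at 0.45
  x <- c(0.1, 0.2, 0.3, 0.6, 0.7, 0.8)           # counts (3,3) +1 -> (.5,.5)
  ref <- c(0.3, 0.6, 0.62, 0.65, 0.7, 0.75)      # counts (1,5) +1 -> (.25,.75)
  expect_equal(kl_variability(x, ref, bins = 2, pseudocount = 1),
               0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
})

test_that("KL deviation is zero at identity, nonnegative, asymmetric, affine-invariant", {
  set.seed(33)
  x <- rnorm(500)
  expect_equal(kl_variability(x, x), 0, tolerance = 1e-12)
  for (rep in 1:10) {
    a <- rnorm(300); b <- rnorm(300, mean = 0.5)
    kab <- kl_variability(a, b)
    expect_gte(kab, 0)
    expect_false(isTRUE(all.equal(kab, kl_variability(b, a))))
    # common affine rescaling moves the shared edges with the data
    expect_equal(kab, kl_variability(3 * a + 10, 3 * b + 10), tolerance = 1e-10)
  }
  expect_error(kl_variability(rep(2, 10), rep(2, 10)), "degenerate")
})

test_that("KL deviation agrees with a histogram-loop oracle", {
  set.seed(34)
  for (rep in 1:10) {
    x <- rnorm(400); r <- rnorm(400, sd = 1.4)
    bins <- 20
    edges <- seq(min(c(x, r)), max(c(x, r)), length.out = bins + 1)
    count_loop <- function(v) {
      n <- rep(0, bins)
      for (val in v) {
        b <- bins
        for (m in seq_len(bins - 1)) {
          if (val >= edges[m] && val < edges[m + 1]) { b <- m; break }
        }
        n[b] <- n[b] + 1
      }
      n
    }
    p <- count_loop(x) + 1; p <- p / sum(p)
    q <- count_loop(r) + 1; q <- q / sum(q)
    expect_equal(kl_variability(x, r, bins = bins),
                 sum(p * log(p / q)), tolerance = 1e-10)
  }
})

test_that("Euclidean deviation is a metric on random triples", {
  set.seed(35)
  for (rep in 1:20) {
    a <- rnorm(50); b <- rnorm(50); c <- rnorm(50)
    expect_equal(euclidean_variability(a, b), euclidean_variability(b, a))
    expect_lte(euclidean_variability(a, c),
               euclidean_variability(a, b) + euclidean_variability(b, c) + 1e-12)
  }
})

fake_decomposition <- function(maps_list, s_agg) {
  mask <- rsnvar:::new_brain_mask(array(TRUE, c(ncol(s_agg), 1, 1)))
  structure(list(s_agg = s_agg, maps = maps_list,
                 timecourses = NULL, mask = mask,
                 subject_ids = sprintf("sub%02d", seq_along(maps_list)),
                 tr = 2, n_components = nrow(s_agg), subject_order = 0L,
                 algorithm = "infomax", iterations = 0L, seed = 1L),
            class = "group_decomposition")
}

test_that("RSN variability is zero/one when subject maps equal the group maps", {
  set.seed(36)
  s_agg <- matrix(rnorm(3 * 120), 3)
  dec <- fake_decomposition(list(s_agg, s_agg), s_agg)
  tbl <- rsn_variability(dec, metrics = c("euclidean", "pearson"))
  expect_equal(tbl$value[tbl$metric == "euclidean"], rep(0, 6), tolerance = 1e-8)
  expect_equal(tbl$value[tbl$metric == "pearson"], rep(1, 6), tolerance = 1e-8)
})

test_that("on standardized maps the Euclidean-Pearson law holds elementwise", {
  set.seed(37)
  K <- 500
  s_agg <- matrix(rnorm(4 * K), 4)
  maps <- replicate(3, s_agg + 0.5 * matrix(rnorm(4 * K), 4), simplify = FALSE)
  tbl <- rsn_variability(fake_decomposition(maps, s_agg))
  wide <- tidyr::pivot_wider(tbl, names_from = "metric", values_from = "value")
  expect_equal(wide$euclidean, sqrt(2 * K * (1 - wide$pearson)), tolerance = 1e-8)
})

test_that("FNC variability vectorizes the strict upper triangle", {
  set.seed(38)
  J <- 50
  mk <- function(id) {
    z <- matrix(rnorm(J * J, sd = 0.3), J)
    z <- (z + t(z)) / 2
    diag(z) <- 0
    connectivity_matrix(z, normalized = TRUE, subject_id = id)
  }
  cms <- list(mk("a"), mk("b"))
  ref <- mk("ref")
  tbl <- fnc_variability(cms, ref, metrics = "euclidean")
  expect_equal(attr(tbl, "n_connections"), 50L * 49L / 2L)  # D = 1225

  # loop oracle over distinct connections
  acc <- 0
  for (j2 in 2:J) for (j1 in seq_len(j2 - 1)) {
    acc <- acc + (cms[[1]]$values[j1, j2] - ref$values[j1, j2])^2
  }
  expect_equal(tbl$value[tbl$subject_id == "a"], sqrt(acc), tolerance = 1e-10)
})

test_that("FNC variability is zero when every subject equals the reference", {
  set.seed(39)
  v <- random_correlation(6)
  cm <- connectivity_matrix(v, subject_id = "s1")
  tbl <- fnc_variability(list(cm, cm), cm, metrics = "euclidean")
  expect_equal(tbl$value, c(0, 0))
})

test_that("variability_matrix widens to one row per subject", {
  run <- preset_run()
  vm <- variability_matrix(run$rsn_var, "euclidean")
  expect_equal(nrow(vm), 60L)
  expect_equal(ncol(vm), run$dec$n_components + 1L)
  expect_true(all(vm$subject_id == run$dec$subject_ids))
})
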