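test_that("a feature identical across groups gives t = 0, p = 1", {
  y <- rep(c(1, 2, 3, 4), 2)
  x <- rep(c(0, 1), each = 4)
  r <- adjusted_regression(y, x)
  expect_equal(r$t, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-12)
})

test_that("with no covariates and binary x the fit is the pooled two-sample t-test", {
  set.seed(61)
  for (rep in 1:10) {
    n0 <- 12; n1 <- 15
    y <- c(rnorm(n0, 0), rnorm(n1, 0.8))
    x <- rep(c(0, 1), c(n0, n1))
    r <- adjusted_regression(y, x)
    # closed-form pooled-variance t
    m0 <- mean(y[x == 0]); m1 <- mean(y[x == 1])
    sp2 <- (sum((y[x == 0] - m0)^2) + sum((y[x == 1] - m1)^2)) / (n0 + n1 - 2)
    t_ref <- (m1 - m0) / sqrt(sp2 * (1 / n0 + 1 / n1))
    p_ref <- 2 * pt(-abs(t_ref), n0 + n1 - 2)
    expect_equal(r$t, t_ref, tolerance = 1e-10)
    expect_equal(r$p, p_ref, tolerance = 1e-10)
  }
})

test_that("covariate-adjusted fit matches a from-scratch normal-equations oracle", {
  set.seed(62)
  n <- 200
  cov <- tibble::tibble(age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
                        site = sample(c("siteA", "siteB", "siteC"), n, TRUE))
  x <- rnorm(n)
  y <- 0.4 * x + 0.02 * cov$age - 0.3 * cov$sex +
    0.5 * (cov$site == "siteB") + rnorm(n)
  r <- adjusted_regression(y, x, covariates = cov)

  X <- cbind(1, x, cov$age, cov$sex, cov$site == "siteB", cov$site == "siteC")
  beta <- solve(crossprod(X), crossprod(X, y))
  resid <- y - X %*% beta
  df <- n - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * solve(crossprod(X))[2, 2])
  t_ref <- beta[2] / se
  expect_equal(r$estimate, beta[2], tolerance = 1e-8)
  expect_equal(r$t, unname(t_ref), tolerance = 1e-8)
  expect_equal(r$p, unname(2 * pt(-abs(t_ref), df)), tolerance = 1e-8)
  expect_equal(r$pve, unname(100 * t_ref^2 / (t_ref^2 + df)), tolerance = 1e-8)
})

test_that("pve saturates for a perfect fit and is affine-invariant", {
  set.seed(63)
  x <- rnorm(60)
  r <- adjusted_regression(x + 1e-10 * rnorm(60), x)
  expect_gt(r$pve, 99.99)

  y <- 0.5 * x + rnorm(60)
  a <- adjusted_regression(y, x)
  b <- adjusted_regression(3 * y - 7, 0.2 * x + 4)
  expect_equal(a$pve, b$pve, tolerance = 1e-8)
  expect_equal(a$p, b$p, tolerance = 1e-10)
})

test_that("collinear designs are fatal", {
  set.seed(64)
  x <- rnorm(30)
  cov <- tibble::tibble(age = 2 * x + 1)  # age aliased with x
  expect_error(adjusted_regression(rnorm(30), x, covariates = cov), "collinear")
})

test_that("group-difference scan Bonferroni-adjusts within each metric family", {
  set.seed(65)
  n <- 40
  covariates <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:n),
    diagnosis = rep(0:1, each = n / 2),
    age = runif(n, 20, 60), sex = rbinom(n, 1, 0.5),
    site = rep(c("a", "b"), n / 2))
  tbl <- tidyr::expand_grid(subject_id = covariates$subject_id,
                            component = 1:5, metric = "euclidean")
  dx <- covariates$diagnosis[match(tbl$subject_id, covariates$subject_id)]
  tbl$value <- rnorm(nrow(tbl)) + ifelse(tbl$component == 3, 1.5 * dx, 0)
  res <- group_difference_scan(tbl, covariates)
  expect_equal(nrow(res), 5L)
  expect_equal(res$p_adjusted, pmin(1, res$p * 5), tolerance = 1e-12)
  top <- res[res$component == 3, ]
  expect_true(top$significant)
  expect_equal(top$direction, "patients higher")
})

test_that("Bonferroni arithmetic matches the 75-component case", {
  expect_equal(min(1, 0.0005 * 75), 0.0375)
})

test_that("efficiency correlation hits its anchors and matches a residual oracle", {
  set.seed(66)
  n <- 80
  eff <- rnorm(n)
  r <- efficiency_correlation(-eff, eff)
  expect_equal(r$r, -1, tolerance = 1e-12)

  covariates <- tibble::tibble(diagnosis = rbinom(n, 1, 0.5),
                               age = runif(n, 20, 60))
  feat <- 0.5 * covariates$diagnosis + rnorm(n)
  effv <- -0.3 * covariates$diagnosis + rnorm(n)
  pc <- efficiency_correlation(feat, effv, covariates, control_diagnosis = TRUE)
  # oracle: explicit projection residuals
  X <- cbind(1, covariates$diagnosis, covariates$age)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  rf <- feat - H %*% feat
  re <- effv - H %*% effv
  expect_equal(pc$r, cor(rf, re)[1, 1], tolerance = 1e-10)
  expect_true(pc$partial)
  expect_error(efficiency_correlation(rep(1, n), effv), "constant")
})

test_that("a null feature is uncorrelated with efficiency across seeds", {
  set.seed(67)
  rs <- replicate(30, {
    f <- rnorm(500); e <- rnorm(500)
    efficiency_correlation(f, e)$r
  })
  expect_lt(max(abs(rs)), 0.15)
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("PRS scoring matches hand and loop oracles and is linear in dosage", {
  w1 <- tibble::tibble(snp_id = "rs1", odds_ratio = 1)
  d1 <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "rs1"))
  expect_equal(compute_prs(d1, w1)$prs, c(0, 0, 0))

  w2 <- tibble::tibble(snp_id = "rs1", odds_ratio = 2)
  expect_equal(compute_prs(d1, w2)$prs, c(0, log(2), 2 * log(2)))

  set.seed(68)
  d <- simulate_genotypes(25, 12)
  w <- tibble::tibble(snp_id = colnames(d),
                      odds_ratio = exp(rnorm(12, 0, 0.1)))
  prs <- compute_prs(d, w)$prs
  loop <- numeric(25)
  for (i in 1:25) {
    for (s in 1:12) loop[i] <- loop[i] + d[i, s] * log(w$odds_ratio[s])
  }
  expect_equal(prs, loop, tolerance = 1e-12)
  expect_equal(compute_prs(d * 0.5, w)$prs, 0.5 * prs, tolerance = 1e-12)

  expect_error(compute_prs(d, tibble::tibble(snp_id = colnames(d)[1],
                                             odds_ratio = -1)), "rs00001")
})

test_that("snp_scan skips monomorphic SNPs and adjusts over the tested count", {
  set.seed(69)
  d <- simulate_genotypes(50, 5)
  d[, 2] <- 1  # monomorphic
  feat <- 0.8 * d[, 4] + rnorm(50)
  expect_warning(res <- snp_scan(feat, d), "monomorphic")
  expect_equal(nrow(res), 4L)
  expect_false("rs00002" %in% res$term)
  expect_equal(res$p_adjusted, pmin(1, res$p * 4), tolerance = 1e-12)
  expect_equal(res$term[1], "rs00004")  # sorted by p, causal first

  single <- snp_scan(feat, d[, 4, drop = FALSE])
  expect_equal(single$p_adjusted, single$p)
})
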