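#' Covariate-adjusted regression of a feature on a predictor
#'
#' Ordinary least squares of `y` on `x` controlling for age, sex and
#' dummy-coded site (reference = first site in lexicographic order) when a
#' covariate table is supplied. Returns the t statistic and two-sided p for
#' `x`, and the percentage of variance explained,
#' `pve = 100 t^2 / (t^2 + residual df)` (the squared partial correlation).
#' With no covariates and a binary `x` this reduces exactly to the
#' pooled-variance two-sample t-test.
#'
#' @param y Numeric response (a variability feature), length N.
#' @param x Numeric predictor (diagnosis, SNP dosage, PRS, ...), length N.
#' @param covariates Optional data frame with any of the columns `age`,
#'   `sex`, `site` (rows aligned with `y`). Other columns are ignored.
#' @param term Label stored in the result's `term` column.
#' @return One-row tibble: `term`, `estimate`, `t`, `p`, `p_adjusted`
#'   (`NA`, filled by the scan functions), `pve`, `n`.
#' @export
adjusted_regression <- function(y, x, covariates = NULL, term = "x") {
  n <- length(y)
  if (length(x) != n) abort("y and x differ in length")
  df <- data.frame(.y = y, .x = x)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) abort("covariates do not match y in rows")
    for (v in intersect(c("age", "sex"), names(covariates))) {
      df[[v]] <- as.numeric(covariates[[v]])
    }
    if ("site" %in% names(covariates)) {
      site <- factor(covariates$site)  # first lexicographic level = reference
      if (nlevels(site) > 1L) df$site <- site
    }
  }
  if (n <= ncol(df) + 1L) abort("too few observations for the design")
  fit <- lm(.y ~ ., data = df)
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    abort(sprintf("collinear design: %s",
                  paste(names(aliased)[aliased], collapse = ", ")))
  }
  sm <- summary(fit)$coefficients
  est <- sm[".x", "Estimate"]
  tval <- sm[".x", "t value"]
  pval <- sm[".x", "Pr(>|t|)"]
  dfres <- fit$df.residual
  tibble::tibble(
    term = term,
    estimate = est,
    t = tval,
    p = pval,
    p_adjusted = NA_real_,
    pve = 100 * tval^2 / (tval^2 + dfres),
    n = n
  )
}

#' Scan variability features for diagnosis differences
#'
#' Runs [adjusted_regression()] with diagnosis as predictor for every
#' (metric, component) cell of an RSN variability table — or per metric for
#' a per-subject FNC variability table — controlling for age, sex and site.
#' P-values are Bonferroni-adjusted over the number of components within
#' each metric family.
#'
#' @param tbl An `rsn_variability` tibble ([rsn_variability()] or
#'   [fnc_variability()]).
#' @param covariates Data frame with `subject_id`, `diagnosis` (0 control /
#'   1 patient) and optionally `age`, `sex`, `site`.
#' @param alpha Family-wise significance level (default 0.05).
#' @return Tibble with one row per test: `metric`, `component` (when
#'   present), the [adjusted_regression()] columns, `significant`, and
#'   `direction` (sign of the diagnosis effect on the feature).
#' @export
group_difference_scan <- function(tbl, covariates, alpha = 0.05) {
  stopifnot(is.data.frame(tbl), all(c("subject_id", "metric", "value") %in% names(tbl)))
  if (!all(c("subject_id", "diagnosis") %in% names(covariates))) {
    abort("covariates need subject_id and diagnosis columns")
  }
  has_comp <- "component" %in% names(tbl)
  keys <- if (has_comp) c("metric", "component") else "metric"
  cells <- dplyr::group_split(dplyr::group_by(tbl, dplyr::across(dplyr::all_of(keys))))
  res <- purrr::map_dfr(cells, function(cell) {
    cov <- covariates[match(cell$subject_id, covariates$subject_id), ]
    if (any(is.na(cov$diagnosis))) abort("covariates missing for some subjects")
    r <- adjusted_regression(cell$value, as.numeric(cov$diagnosis),
                             covariates = cov, term = "diagnosis")
    r$metric <- cell$metric[1]
    if (has_comp) r$component <- cell$component[1]
    r
  })
  res <- res |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(p_adjusted = pmin(1, .data$p * dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      significant = .data$p_adjusted < alpha,
      direction = ifelse(.data$estimate > 0, "patients higher", "patients lower")
    )
  front <- intersect(c("metric", "component"), names(res))
  dplyr::select(res, dplyr::all_of(front), dplyr::everything())
}

#' Correlation between a variability feature and global efficiency
#'
#' Pearson correlation of the two per-subject vectors; with
#' `control_diagnosis = TRUE`, both are first residualized on diagnosis
#' (plus age/sex/site when supplied), giving a partial correlation.
#'
#' @param feature,efficiency Numeric vectors of length N.
#' @param covariates Optional data frame with `diagnosis` and optionally
#'   `age`, `sex`, `site`; required when `control_diagnosis = TRUE`.
#' @param control_diagnosis Residualize before correlating.
#' @return One-row tibble: `r`, `p`, `n`, `partial`.
#' @export
efficiency_correlation <- function(feature, efficiency, covariates = NULL,
                                   control_diagnosis = FALSE) {
  n <- length(feature)
  if (length(efficiency) != n) abort("vectors differ in length")
  if (n < 4L) abort("need at least 4 subjects")
  if (sd(feature) == 0 || sd(efficiency) == 0) {
    abort("constant vector: correlation undefined")
  }
  if (control_diagnosis) {
    if (is.null(covariates) || !"diagnosis" %in% names(covariates)) {
      abort("control_diagnosis requires covariates with a diagnosis column")
    }
    feature <- residualize(feature, covariates)
    efficiency <- residualize(efficiency, covariates)
  }
  ct <- cor.test(feature, efficiency, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n,
                 partial = control_diagnosis)
}

residualize <- function(y, covariates) {
  df <- data.frame(.y = y, diagnosis = as.numeric(covariates$diagnosis))
  for (v in intersect(c("age", "sex"), names(covariates))) {
    df[[v]] <- as.numeric(covariates[[v]])
  }
  if ("site" %in% names(covariates)) {
    site <- factor(covariates$site)
    if (nlevels(site) > 1L) df$site <- site
  }
  unname(stats::residuals(lm(.y ~ ., data = df)))
}

#' Polygenic risk score from odds-ratio weights
#'
#' Purcell-style additive scoring: each subject's score is the sum over SNPs
#' of the effect-allele dosage times the natural-log odds ratio.
#'
#' @param dosage N x S numeric matrix of effect-allele dosages in `[0, 2]`
#'   (fractional values from imputation allowed); column names are SNP ids.
#' @param weights Data frame with `snp_id` and `odds_ratio` columns (all
#'   odds ratios > 0); every `snp_id` must be a column of `dosage`.
#' @return Tibble with `subject_id` (dosage row names, or `S1..SN`) and
#'   `prs`.
#' @export
compute_prs <- function(dosage, weights) {
  dosage <- as.matrix(dosage)
  if (any(dosage < 0 | dosage > 2)) abort("dosages must lie in [0, 2]")
  if (!all(c("snp_id", "odds_ratio") %in% names(weights))) {
    abort("weights need snp_id and odds_ratio columns")
  }
  bad <- weights$odds_ratio <= 0
  if (any(bad)) {
    abort(sprintf("odds ratio <= 0 for SNP %s", weights$snp_id[which(bad)[1]]))
  }
  missing <- setdiff(weights$snp_id, colnames(dosage))
  if (length(missing)) {
    abort(sprintf("SNPs absent from dosage matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  w <- log(weights$odds_ratio)
  prs <- drop(dosage[, weights$snp_id, drop = FALSE] %*% w)
  ids <- rownames(dosage)
  if (is.null(ids)) ids <- paste0("S", seq_len(nrow(dosage)))
  tibble::tibble(subject_id = ids, prs = unname(prs))
}

#' Per-SNP association scan against a variability feature
#'
#' Regresses the feature on each SNP's dosage with [adjusted_regression()]
#' (same age/sex/site covariates as the group-difference model; disable with
#' `covariates = NULL`). Monomorphic SNPs (zero dosage variance) are skipped
#' with a warning and excluded from the Bonferroni count.
#'
#' @param feature Numeric per-subject feature, length N.
#' @param dosage N x S dosage matrix with SNP ids as column names.
#' @param covariates Optional covariate data frame (`age`, `sex`, `site`).
#' @param alpha Family-wise significance level.
#' @return Tibble with one row per tested SNP, Bonferroni-adjusted over the
#'   number of tested SNPs, sorted by p.
#' @export
snp_scan <- function(feature, dosage, covariates = NULL, alpha = 0.05) {
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != length(feature)) {
    abort("dosage rows do not match feature length")
  }
  ids <- colnames(dosage)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(dosage)))
  mono <- apply(dosage, 2L, var) == 0
  if (any(mono)) {
    warn(sprintf("skipping %d monomorphic SNP(s): %s", sum(mono),
                 paste(head(ids[mono], 5), collapse = ", ")))
  }
  tested <- which(!mono)
  if (!length(tested)) abort("no polymorphic SNPs to test")
  res <- purrr::map_dfr(tested, function(s) {
    adjusted_regression(feature, dosage[, s], covariates = covariates,
                        term = ids[s])
  })
  res$p_adjusted <- pmin(1, res$p * length(tested))
  res$significant <- res$p_adjusted < alpha
  dplyr::arrange(res, .data$p)
}
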