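new_rsn_cohort <- function(scans, covariates) {
  check_shared_grid(scans)
  ids <- vapply(scans, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) abort("duplicate subject ids in cohort")
  if (anyDuplicated(covariates$subject_id)) {
    abort("duplicate subject ids in covariate table")
  }
  missing <- setdiff(ids, covariates$subject_id)
  if (length(missing)) {
    abort(sprintf("covariates missing for subject(s): %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  # covariates follow scan (manifest) order everywhere downstream
  covariates <- covariates[match(ids, covariates$subject_id), ]
  structure(list(scans = scans, covariates = tibble::as_tibble(covariates)),
            class = "rsn_cohort")
}

#' @export
print.rsn_cohort <- function(x, ...) {
  d <- dim(x$scans[[1]]$data)
  cat(sprintf("<rsn_cohort> %d subjects on a %s grid (%d patients, %d controls)\n",
              length(x$scans), paste(d[1:3], collapse = "x"),
              sum(x$covariates$diagnosis == 1),
              sum(x$covariates$diagnosis == 0)))
  invisible(x)
}

#' Load a cohort from a manifest
#'
#' The manifest is a TSV with columns `subject_id`, `scan` and optionally
#' `motion`; paths are resolved relative to the manifest's directory. The
#' covariate table (TSV: `subject_id`, `diagnosis`, `age`, `sex`, `site`)
#' defaults to `covariates.tsv` next to the manifest. Scans are validated on
#' load: at least two volumes, no non-finite values, and a grid shared by
#' the whole cohort. Subject order is manifest order and is preserved in
#' every downstream output.
#'
#' @param manifest_path Path to the manifest TSV.
#' @param covariates_path Optional explicit covariate TSV path.
#' @return An `rsn_cohort`: list of [subject_scan()]s plus the covariate
#'   tibble.
#' @export
load_cohort <- function(manifest_path, covariates_path = NULL) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest not found: %s", manifest_path))
  }
  base <- dirname(manifest_path)
  man <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                         progress = FALSE)
  if (!all(c("subject_id", "scan") %in% names(man))) {
    abort("manifest needs subject_id and scan columns")
  }
  if (is.null(covariates_path)) {
    covariates_path <- file.path(base, "covariates.tsv")
  }
  if (!file.exists(covariates_path)) {
    abort(sprintf("covariate table not found: %s", covariates_path))
  }
  covariates <- readr::read_tsv(covariates_path, show_col_types = FALSE,
                                progress = FALSE)
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  scans <- purrr::pmap(man, function(subject_id, scan, motion = NA, ...) {
    path <- resolve(scan)
    if (!file.exists(path)) {
      abort(sprintf("scan file not found: %s", path))
    }
    img <- RNifti::readNifti(path)
    data <- array(as.numeric(img), dim(img))
    pd <- RNifti::pixdim(img)
    tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
    mot <- NULL
    if (!is.na(motion) && nzchar(motion)) {
      mpath <- resolve(motion)
      if (!file.exists(mpath)) {
        abort(sprintf("motion file not found: %s", mpath))
      }
      mot <- as.matrix(readr::read_tsv(mpath, show_col_types = FALSE,
                                       progress = FALSE))
    }
    subject_scan(subject_id, data, affine = RNifti::xform(img), tr = tr,
                 motion = mot)
  })
  rsn_log("load_cohort", "N=%d from %s", length(scans), manifest_path)
  new_rsn_cohort(scans, covariates)
}

# write a simulated cohort to disk in the on-disk layout load_cohort reads
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- sim$cohort
  rows <- purrr::map(cohort$scans, function(s) {
    scan_file <- paste0(s$subject_id, ".nii.gz")
    img <- RNifti::asNifti(s$data)
    RNifti::pixdim(img) <- c(3, 3, 3, s$tr)
    RNifti::writeNifti(img, file.path(dir, scan_file))
    motion_file <- ""
    if (!is.null(s$motion)) {
      motion_file <- paste0(s$subject_id, "_motion.tsv")
      mot_df <- as.data.frame(s$motion)
      names(mot_df) <- c("trans_x", "trans_y", "trans_z",
                         "rot_x", "rot_y", "rot_z")
      readr::write_tsv(mot_df, file.path(dir, motion_file), progress = FALSE)
    }
    tibble::tibble(subject_id = s$subject_id, scan = scan_file,
                   motion = motion_file)
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  readr::write_tsv(cohort$covariates, file.path(dir, "covariates.tsv"),
                   progress = FALSE)
  geno <- tibble::as_tibble(sim$genotypes, rownames = "subject_id")
  readr::write_tsv(geno, file.path(dir, "genotypes.tsv"), progress = FALSE)
  readr::write_tsv(sim$snp_weights, file.path(dir, "snp_weights.tsv"),
                   progress = FALSE)
  truth <- sim$truth
  jsonlite::write_json(
    list(delta = unclass(truth$delta), gamma = unclass(truth$gamma),
         sigma_fnc = truth$sigma_fnc, causal_snp = truth$causal_snp,
         group_effect = truth$group_effect, grid = truth$grid,
         brain_index = truth$brain_index, seed = truth$seed),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  sim$paths <- list(dir = dir, manifest = file.path(dir, "manifest.tsv"))
  rsn_log("simulate", "wrote cohort to %s", dir)
  sim
}

#' Write result tables as CSV files
#'
#' Each named element becomes `<name>.csv` under `out_dir`, written with
#' full floating-point precision so a write-then-read round trip preserves
#' values to at least 12 significant digits.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables),
            all(nzchar(names(tables))))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create %s", out_dir))
  paths <- purrr::imap_chr(tables, function(tbl, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(tibble::as_tibble(tbl), p, progress = FALSE)
    p
  })
  rsn_log("write_results", "%d table(s) to %s", length(paths), out_dir)
  invisible(paths)
}

#' Default run configuration
#'
#' The analysis settings used at full scale: a 75-component decomposition,
#' 100 histogram bins for the KL metric, a 0.01-0.08 Hz pass band, all
#' three deviation metrics, and an unbalanced mean-FNC reference.
#'
#' @return A named list of settings.
#' @export
default_run_config <- function() {
  list(
    n_components = 75L,
    subject_pca_order = NA_integer_,  # min(T - 1, 1.5 C) when unset
    kl_bins = 100L,
    fnc_component_indices = integer(),  # empty = all components
    bandpass_low = 0.01,
    bandpass_high = 0.08,
    metrics = c("euclidean", "pearson", "kl"),
    algorithm = "infomax",
    seed = 1L,
    balance_groups = FALSE
  )
}

#' Read a run configuration file
#'
#' Flat `key = value` text format (`#` comments allowed); unset keys take
#' the [default_run_config()] values. List-valued keys (`metrics`,
#' `fnc_component_indices`) are comma-separated. The resolved configuration
#' is echoed to the log.
#'
#' @param path Path to the configuration file, or `NULL` for pure defaults.
#' @param tr Optional repetition time used to validate the pass band
#'   against the Nyquist frequency.
#' @return The resolved configuration list.
#' @export
read_run_config <- function(path = NULL, tr = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config not found: %s", path))
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) abort(sprintf("malformed config line: '%s'", ln))
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) abort(sprintf("unknown config key: '%s'", key))
      cfg[[key]] <- parse_config_value(key, val, cfg[[key]])
    }
  }
  if (cfg$kl_bins < 2L) abort("kl_bins must be >= 2")
  if (!(cfg$bandpass_low > 0 && cfg$bandpass_low < cfg$bandpass_high)) {
    abort("bandpass must satisfy 0 < low < high")
  }
  if (!is.null(tr) && cfg$bandpass_high >= 1 / (2 * tr)) {
    abort(sprintf("bandpass high %g Hz is at or above Nyquist for TR %g s",
                  cfg$bandpass_high, tr))
  }
  if (length(cfg$fnc_component_indices) &&
      any(cfg$fnc_component_indices < 1 |
          cfg$fnc_component_indices > cfg$n_components)) {
    abort("fnc_component_indices outside 1..n_components")
  }
  resolve_metrics(cfg$metrics)
  rsn_log("config", paste(
    vapply(names(cfg), function(k) paste0(k, "=", paste(cfg[[k]], collapse = ",")),
           ""), collapse = " "))
  cfg
}

parse_config_value <- function(key, val, default) {
  if (key %in% c("metrics")) {
    return(trimws(strsplit(val, ",", fixed = TRUE)[[1]]))
  }
  if (key == "fnc_component_indices") {
    if (!nzchar(val)) return(integer())
    return(as.integer(trimws(strsplit(val, ",", fixed = TRUE)[[1]])))
  }
  if (key == "algorithm") return(val)
  if (key == "balance_groups") return(toupper(val) %in% c("TRUE", "1", "YES"))
  if (is.integer(default)) return(as.integer(val))
  as.numeric(val)
}
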