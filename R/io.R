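# On-disk formats: NIfTI-1 volumes and masks, cohort CSV, YAML specs.

#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param mask If `TRUE`, validate the volume as a binary 0/1 mask and
#'   return a logical array.
#' @return Numeric (or logical) array with attributes `spacing_mm` and the
#'   original NIfTI image as attribute `nifti` (affine retained for
#'   round-trips).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("malformed NIfTI file '", path, "': ",
                         conditionMessage(e)))
  arr <- as.array(img)
  if (mask) {
    u <- unique(as.numeric(arr))
    if (!all(u %in% c(0, 1)))
      stop("mask '", path, "' contains values other than 0/1")
    arr <- array(arr == 1, dim(arr))
  }
  attr(arr, "spacing_mm") <- RNifti::pixdim(img)[seq_len(min(3L,
    length(dim(arr))))]
  attr(arr, "nifti") <- img
  arr
}

#' Write an array or parametric map as NIfTI-1
#'
#' @param x Numeric/logical array or a [parametric_map()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing_mm Voxel spacing (taken from a parametric map if given).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing_mm = c(1, 1, 1)) {
  if (inherits(x, "parametric_map")) {
    spacing_mm <- x$spacing_mm
    x <- x$values
  }
  if (is.logical(x)) x <- array(as.numeric(x), dim(x))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

# column dictionary for cohort CSV files
cohort_dictionary <- function() {
  list(required = c("patient_id", "pcr"),
       binary = c("pcr", "er_positive", "pr_positive", "her2_positive",
                  "ki67_high", "node_positive", "hg3", "postmenopausal"),
       factors = list(subtype = c("luminal_a", "luminal_b",
                                  "her2_enriched", "tn")))
}

#' Read and validate a cohort CSV
#'
#' One row per patient. Required columns: `patient_id`, `pcr` (0/1). Known
#' binary columns must be 0/1; `subtype` must use the documented level set.
#' Unknown columns are kept with a warning (documented leniency: extra
#' covariates pass through to the pipeline as-is).
#'
#' @param path CSV path (UTF-8, comma separated, `.` decimal).
#' @return `data.frame` with validated types.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dict <- cohort_dictionary()
  missing_cols <- setdiff(dict$required, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (cn in intersect(dict$binary, names(df))) {
    bad <- which(!(df[[cn]] %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("column '%s' must be 0/1; offending row(s): %s",
                   cn, paste(utils::head(bad, 5), collapse = ", ")))
  }
  for (cn in intersect(names(dict$factors), names(df))) {
    lv <- dict$factors[[cn]]
    bad <- which(!(df[[cn]] %in% lv))
    if (length(bad))
      stop(sprintf("column '%s' has unknown level(s) in row(s) %s (allowed: %s)",
                   cn, paste(utils::head(bad, 5), collapse = ", "),
                   paste(lv, collapse = ", ")))
    df[[cn]] <- factor(df[[cn]], levels = lv)
  }
  known <- c(dict$required, dict$binary, names(dict$factors))
  extra <- setdiff(names(df), c(known, grep("^(mtr|adc|enh)_",
                                            names(df), value = TRUE)))
  if (length(extra))
    warning("unknown column(s) kept as-is: ", paste(extra, collapse = ", "))
  df
}

#' Write a cohort table to CSV
#' @param cohort Cohort `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort generator spec from YAML
#'
#' The YAML mirrors the [cohort_spec()] arguments; the shipped default is
#' at `system.file("extdata", "cohort_spec.yaml", package = "aptnac")`.
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  allowed <- c("n_patients", "prevalence", "categorical", "features",
               "rho", "logistic", "seed")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop("unknown spec key(s): ", paste(unknown, collapse = ", "))
  cat_spec <- default_categorical_spec()
  if (!is.null(y$categorical)) {
    for (nm in names(y$categorical)) {
      cc <- y$categorical[[nm]]
      if (length(cc$p_pcr) > 1L) {
        cc$p_pcr <- unlist(cc$p_pcr); cc$p_nonpcr <- unlist(cc$p_nonpcr)
      }
      cat_spec[[nm]] <- cc
    }
  }
  feat_spec <- default_feature_spec()
  if (!is.null(y$features))
    for (nm in names(y$features)) feat_spec[[nm]] <- y$features[[nm]]
  logistic <- if (!is.null(y$logistic)) unlist(y$logistic) else NULL
  cohort_spec(
    n_patients = y$n_patients %||% 108,
    prevalence = y$prevalence %||% (43 / 108),
    categorical = cat_spec, features = feat_spec,
    rho = y$rho %||% 0.8, logistic = logistic,
    seed = seed %||% y$seed %||% 1L)
}

#' Read a quantification config from YAML
#'
#' Acquisition schedule for the map computation stage: `offsets_ppm`,
#' `echo_times` (s), `b_values` (s/mm^2), `field_mhz`. Unknown keys are
#' rejected.
#'
#' @param path YAML file path.
#' @return Validated list.
#' @export
read_quant_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  allowed <- c("offsets_ppm", "echo_times", "b_values", "field_mhz",
               "percentiles", "alpha_normality", "p_enter", "p_remove",
               "seed")
  unknown <- setdiff(names(y), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  y$offsets_ppm <- as.numeric(y$offsets_ppm %||%
                                c(-4.3, -3.5, -2.7, 2.7, 3.5, 4.3))
  if (any(diff(y$offsets_ppm) <= 0))
    stop("offsets_ppm must be strictly increasing")
  y$echo_times <- as.numeric(y$echo_times %||% (c(2, 3, 4) * 1e-3))
  y$b_values <- as.numeric(y$b_values %||% c(0, 800))
  y$field_mhz <- y$field_mhz %||% 127.728
  y
}
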