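#' Fit a calibration curve for one analyte
#'
#' Ordinary least-squares line of peak area against standard concentration,
#' used to convert sample peak areas into concentrations. Optional 1/x
#' weighting down-weights high standards.
#'
#' @param standards A data frame with columns `conc` (uM) and `area`; at
#'   least 3 points and at least 2 distinct concentrations.
#' @param analyte Analyte label stored on the curve.
#' @param lod Limit of detection (uM); quantified values below it are
#'   reported censored.
#' @param weighting `"none"` (default) or `"1/x"` (zero-concentration points
#'   get the smallest nonzero weight).
#' @return A `kynu_calibration` list: `analyte`, `slope` (area per uM),
#'   `intercept` (area), `r_squared`, `lod`, and the underlying `lm` fit.
#'   Warns when r-squared falls below 0.99.
#' @examples
#' fit_calibration(data.frame(conc = 0:2, area = c(0, 10, 20)))
#' @export
fit_calibration <- function(standards, analyte = "analyte", lod = 0,
                            weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  standards <- as_tibble(standards)
  if (nrow(standards) < 3) {
    abort("need at least 3 standard points", class = "kynu_error_too_few_points")
  }
  if (length(unique(standards$conc)) < 2) {
    abort("standards need at least 2 distinct concentrations",
          class = "kynu_error_no_spread")
  }
  w <- if (weighting == "1/x") {
    cx <- standards$conc
    cx[cx == 0] <- min(cx[cx > 0])
    1 / cx
  } else NULL
  fit <- lm(area ~ conc, data = standards, weights = w)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits trip summary.lm
  if (r2 < 0.99) {
    warn(sprintf("calibration r-squared %.4f below 0.99 for %s", r2, analyte),
         class = "kynu_warning_poor_calibration")
  }
  structure(list(
    analyte = analyte,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    lod = lod,
    fit = fit
  ), class = "kynu_calibration")
}

#' @export
print.kynu_calibration <- function(x, ...) {
  cat(sprintf(
    "<kynu_calibration> %s: area = %.4g * conc + %.4g (r2 = %.4f, LOD %g uM)\n",
    x$analyte, x$slope, x$intercept, x$r_squared, x$lod))
  invisible(x)
}

#' Quantify peak areas against a calibration curve
#'
#' Inverts the calibration line, `(area - intercept) / slope`. Values below
#' the analyte's limit of detection are censored: the concentration is
#' reported as the LOD with `censored = TRUE` (never as zero, and never as
#' the sub-LOD estimate).
#'
#' @param areas Numeric vector of peak areas (finite).
#' @param curve A `kynu_calibration`.
#' @return A tibble: `area`, `conc` (uM; LOD value where censored),
#'   `censored`.
#' @export
quantify <- function(areas, curve) {
  if (any(!is.finite(areas))) {
    abort("non-finite peak area", class = "kynu_error_bad_area")
  }
  conc <- (areas - curve$intercept) / curve$slope
  censored <- conc < curve$lod
  tibble(area = areas,
         conc = ifelse(censored, curve$lod, conc),
         censored = censored)
}

#' Read sample peak-area and standards tables
#'
#' @param path CSV with header. Samples: columns `sample`, `analyte`,
#'   `fraction` (`extracellular` / `intracellular`), `replicate`,
#'   `peak_area`. Standards: columns `analyte`, `conc`, `area`.
#' @return A tibble.
#' @name quant_io
#' @export
read_samples_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, col_types = "ccccn") |>
    mutate(replicate = as.character(.data$replicate))
}

#' @rdname quant_io
#' @export
read_standards_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, col_types = "cnn")
}

#' Quantify a sample table and summarize replicates
#'
#' Converts per-fraction peak areas to concentrations with the analyte's
#' calibration curve, forms the per-replicate total (extracellular +
#' intracellular, a censored fraction contributing 0 with its censoring
#' counted), and reports mean and sample standard deviation (n - 1) across
#' replicates for each sample x analyte.
#'
#' @param samples Sample tibble (see [read_samples_csv()]).
#' @param curves Named list of `kynu_calibration` objects, one per analyte
#'   present in `samples`.
#' @return A `kynu_quant` tibble: `sample`, `analyte`, `n`, `mean_uM`,
#'   `sd_uM` (`NA` for a single replicate), `n_censored_fractions`,
#'   `all_censored` (TRUE when every fraction of every replicate was below
#'   the LOD, i.e. the analyte is reported "below detection limit").
#' @export
quantify_samples <- function(samples, curves) {
  missing_curves <- setdiff(unique(samples$analyte), names(curves))
  if (length(missing_curves)) {
    abort(paste0("no calibration curve for: ",
                 paste(missing_curves, collapse = ", ")),
          class = "kynu_error_missing_curve")
  }
  per_fraction <- samples |>
    group_by(.data$analyte) |>
    dplyr::group_modify(function(df, key) {
      q <- quantify(df$peak_area, curves[[key$analyte]])
      mutate(df, conc = ifelse(q$censored, 0, q$conc), censored = q$censored)
    }) |>
    ungroup()
  totals <- per_fraction |>
    group_by(.data$sample, .data$analyte, .data$replicate) |>
    summarise(total = sum(.data$conc),
              n_censored = sum(.data$censored),
              n_fractions = n(), .groups = "drop")
  out <- totals |>
    group_by(.data$sample, .data$analyte) |>
    summarise(
      n = n(),
      mean_uM = mean(.data$total),
      sd_uM = if (n() > 1) sd(.data$total) else NA_real_,
      n_censored_fractions = sum(.data$n_censored),
      all_censored = sum(.data$n_censored) == sum(.data$n_fractions),
      .groups = "drop"
    )
  class(out) <- c("kynu_quant", class(out))
  out
}

#' Mean and sample SD of replicate totals
#'
#' Replicate summarization for already-totalled concentrations: arithmetic
#' mean and sample standard deviation (n - 1 denominator); a single
#' replicate has no SD and is reported `NA`.
#'
#' @param values Numeric vector of per-replicate total concentrations (uM).
#' @return A tibble with `n`, `mean_uM`, `sd_uM`.
#' @examples
#' summarize_replicates(c(10, 20, 30))  # mean 20, sd 10
#' @export
summarize_replicates <- function(values) {
  if (length(values) == 0) {
    abort("no replicates", class = "kynu_error_empty_input")
  }
  tibble(n = length(values), mean_uM = mean(values),
         sd_uM = if (length(values) > 1) sd(values) else NA_real_)
}

#' Write a replicate-summary table as CSV
#'
#' @param quant A `kynu_quant` tibble.
#' @param path Output CSV path (means and SDs rounded to 2 d.p., the
#'   reporting precision).
#' @return `path`, invisibly.
#' @export
write_quant_csv <- function(quant, path) {
  readr::write_csv(
    mutate(quant, mean_uM = round(.data$mean_uM, 2),
           sd_uM = round(.data$sd_uM, 2)),
    path
  )
  invisible(path)
}
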