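#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a superposition result
#'
#' @param x A `kynu_superposition`.
#' @param ... Unused.
#' @return One row per atom pair: `pair`, `distance` (Angstrom).
#' @export
tidy.kynu_superposition <- function(x, ...) {
  tibble(pair = seq_len(x$n_pairs), distance = x$per_pair_distance)
}

#' @rdname tidy.kynu_superposition
#' @return `glance()`: one row with `n_pairs`, `rmsd`, `rmsd_nm`.
#' @export
glance.kynu_superposition <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, rmsd = x$rmsd, rmsd_nm = x$rmsd_nm)
}

#' Tidy a TM-score result
#'
#' @param x A `kynu_tm`.
#' @param ... Unused.
#' @return One row with the score, its normalization, both RMSD flavours and
#'   the classification calls.
#' @export
tidy.kynu_tm <- function(x, ...) {
  tibble(
    label_a = x$label_a %||% NA_character_,
    label_b = x$label_b %||% NA_character_,
    tm = x$tm, L = x$L, L_aligned = x$L_aligned, d0 = x$d0,
    rmsd_kabsch_nm = x$rmsd_kabsch_nm, rmsd_tm_frame_nm = x$rmsd_tm_frame_nm,
    fold_call = x$fold_call, rmsd_call = x$rmsd_call
  )
}

#' @rdname tidy.kynu_tm
#' @export
glance.kynu_tm <- function(x, ...) tidy(x)

#' Tidy a calibration curve
#'
#' @param x A `kynu_calibration`.
#' @param ... Unused.
#' @return `tidy()`: the underlying linear-model coefficients (term,
#'   estimate, std.error). `glance()`: one row with `analyte`, `slope`,
#'   `intercept`, `r_squared`, `lod`.
#' @export
tidy.kynu_calibration <- function(x, ...) {
  cf <- suppressWarnings(summary(x$fit)$coefficients)
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2])
}

#' @rdname tidy.kynu_calibration
#' @export
glance.kynu_calibration <- function(x, ...) {
  tibble(analyte = x$analyte, slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, lod = x$lod)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
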