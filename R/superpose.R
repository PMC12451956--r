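#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation superposing `coords_b` onto
#' `coords_a` with minimal RMSD over the supplied residue pairing, by SVD of
#' the cross-covariance matrix with determinant correction (so a reflection
#' is never returned). RMSD is the root of the mean squared distance over the
#' paired atoms after the fit.
#'
#' @param coords_a,coords_b n x 3 matrices of paired CA coordinates
#'   (Angstrom), same n, matched row order. For different-length proteins
#'   derive the pairing with [global_align()] and [paired_coords()].
#' @return A `kynu_superposition` list: `rotation` (3 x 3), `translation`
#'   (length 3; `b` maps onto `a` as `b %*% t(rotation) + translation`),
#'   `n_pairs`, `per_pair_distance` (Angstrom), `rmsd` (Angstrom) and
#'   `rmsd_nm`.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' kabsch(a, sweep(a, 2, c(-5, 0, 0)))$rmsd
#' @export
kabsch <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  n <- nrow(coords_a)
  if (!identical(dim(coords_a), dim(coords_b)) || ncol(coords_a) != 3) {
    abort("coordinate sets must be matched n x 3 matrices",
          class = "kynu_error_dim_mismatch")
  }
  if (n < 3) {
    abort("need at least 3 paired atoms", class = "kynu_error_too_few_pairs")
  }
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  # collinearity makes the rotation about the common axis unidentifiable
  if (svd(A)$d[2] < 1e-8 * max(svd(A)$d[1], 1)) {
    warn("near-collinear point set: superposition may be unstable",
         class = "kynu_warning_degenerate")
  }
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(ca - R %*% cb)
  transform <- rigid_transform(R, tr)
  di <- pair_distances(coords_a, coords_b, transform)
  new_superposition(transform, di)
}

new_superposition <- function(transform, di) {
  rmsd <- sqrt(mean(di^2))
  structure(list(
    rotation = transform$rotation,
    translation = transform$translation,
    n_pairs = length(di),
    per_pair_distance = di,
    rmsd = rmsd,
    rmsd_nm = rmsd / 10
  ), class = c("kynu_superposition", "kynu_transform"))
}

pair_distances <- function(coords_a, coords_b, transform) {
  bt <- apply_transform(coords_b, transform)
  sqrt(rowSums((coords_a - bt)^2))
}

#' @export
print.kynu_superposition <- function(x, ...) {
  cat(sprintf("<kynu_superposition> %d pairs, RMSD %.3f A (%.3f nm)\n",
              x$n_pairs, x$rmsd, x$rmsd_nm))
  invisible(x)
}

#' RMSD under a fixed transform (no re-fitting)
#'
#' The TM-score-optimal frame generally differs from the RMSD-optimal frame;
#' this evaluates the RMSD of a pairing under a given transform without
#' re-superposing.
#'
#' @inheritParams kabsch
#' @param transform A `kynu_transform` applied to `coords_b`.
#' @return RMSD in Angstrom.
#' @export
rmsd_fixed_frame <- function(coords_a, coords_b, transform) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!identical(dim(coords_a), dim(coords_b))) {
    abort("coordinate sets must have matching dimensions",
          class = "kynu_error_dim_mismatch")
  }
  sqrt(mean(pair_distances(coords_a, coords_b, transform)^2))
}

#' Extract paired coordinates from two traces via an alignment
#'
#' @param trace_a,trace_b `kynu_trace` objects.
#' @param alignment A `kynu_alignment` between `trace_sequence(trace_a)` and
#'   `trace_sequence(trace_b)`; if `NULL` one is computed. Alternatively pass
#'   `mode = "residue_number"` to pair residues sharing a residue number, the
#'   convention of some structure-comparison servers.
#' @param mode `"alignment"` (default) or `"residue_number"`.
#' @return A list with matrices `a`, `b` (matched rows) and the pair tibble.
#' @export
paired_coords <- function(trace_a, trace_b, alignment = NULL,
                          mode = c("alignment", "residue_number")) {
  mode <- match.arg(mode)
  if (mode == "residue_number") {
    common <- intersect(trace_a$residue_number, trace_b$residue_number)
    pairs <- tibble(
      index_a = match(common, trace_a$residue_number),
      index_b = match(common, trace_b$residue_number)
    )
  } else {
    if (is.null(alignment)) {
      alignment <- global_align(trace_sequence(trace_a), trace_sequence(trace_b))
    }
    pairs <- alignment$pairs
  }
  list(
    a = trace_coords(trace_a)[pairs$index_a, , drop = FALSE],
    b = trace_coords(trace_b)[pairs$index_b, , drop = FALSE],
    pairs = pairs
  )
}

#' Serialize a rigid transform to JSON
#'
#' Row-major rotation plus translation vector, in Angstrom.
#' @param transform A `kynu_transform`.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @export
transform_to_json <- function(transform, path = NULL) {
  obj <- list(rotation = as.numeric(t(transform$rotation)),
              translation = transform$translation, units = "angstrom")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' @rdname transform_to_json
#' @param json JSON string or path produced by [transform_to_json()].
#' @export
transform_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE), obj$translation)
}
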