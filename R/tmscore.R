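#' Length-dependent TM-score distance scale d0
#'
#' `d0(L) = 1.24 * (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom, the
#' standard scale that makes TM-score approximately length-independent.
#' Monotone non-decreasing in `L`.
#'
#' @param L Normalization length (residues), `L >= 1`.
#' @return d0 in Angstrom.
#' @examples
#' d0(153)  # 4.61
#' @export
d0 <- function(L) {
  stopifnot(all(L >= 1))
  raw <- ifelse(L > 15, 1.24 * (pmax(L - 15, 0))^(1 / 3) - 1.8, 0.5)
  pmax(raw, 0.5)
}

#' TM-score parameters
#'
#' @param normalization Which length `L` normalizes the score:
#'   `"reference"` (length of the first-named structure, the default),
#'   `"target"` (second structure), `"shorter"` or `"longer"`.
#' @param fragment_min Minimum seed fragment length (residues).
#' @param max_iter Maximum refinement iterations per seed.
#' @param cutoff_step Cutoff growth (Angstrom) applied when the inclusion set
#'   falls below 3 pairs.
#' @return A `kynu_tm_params` list.
#' @export
tm_params <- function(normalization = c("reference", "target", "shorter", "longer"),
                      fragment_min = 4L, max_iter = 20L, cutoff_step = 0.5) {
  normalization <- match.arg(normalization)
  stopifnot(fragment_min >= 3, max_iter >= 1, cutoff_step > 0)
  structure(list(normalization = normalization, fragment_min = as.integer(fragment_min),
                 max_iter = as.integer(max_iter), cutoff_step = cutoff_step),
            class = "kynu_tm_params")
}

tm_norm_length <- function(normalization, len_a, len_b) {
  switch(normalization,
    reference = len_a,
    target = len_b,
    shorter = min(len_a, len_b),
    longer = max(len_a, len_b)
  )
}

#' TM-score under a fixed superposition
#'
#' `(1/L) * sum_i 1 / (1 + d_i^2 / d0(L)^2)` over the aligned pairs, with no
#' optimization over frames.
#'
#' @param coords_a,coords_b Paired n x 3 coordinate matrices (Angstrom).
#' @param transform A `kynu_transform` applied to `coords_b`.
#' @param L Normalization length (residues).
#' @return TM-score in (0, 1].
#' @export
tm_fixed <- function(coords_a, coords_b, transform, L) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (nrow(coords_a) == 0) {
    abort("empty pairing", class = "kynu_error_empty_mapping")
  }
  di <- pair_distances(coords_a, coords_b, transform)
  sum(1 / (1 + (di / d0(L))^2)) / L
}

#' Maximize the TM-score over superpositions
#'
#' Deterministic heuristic search for the superposition maximizing the
#' TM-score of two CA traces under a fixed residue pairing. Seeds are Kabsch
#' fits of contiguous aligned fragments (lengths `n`, `n/2`, `n/4`, down to
#' `fragment_min`, slid across the alignment); each seed is refined by
#' iterating superposition on the current inclusion set, recomputing pair
#' distances, and keeping pairs closer than a cutoff that starts at `d0` and
#' grows by `cutoff_step` whenever fewer than 3 pairs survive. The
#' full-alignment Kabsch frame is always among the seeds, so the result is
#' never below the TM-score of the RMSD-optimal frame. No randomness is used.
#'
#' @param trace_a,trace_b `kynu_trace` objects (`trace_a` is the reference).
#' @param alignment Optional `kynu_alignment`; computed from the trace
#'   sequences when `NULL`.
#' @param params A [tm_params()] list.
#' @param mode Residue pairing mode, see [paired_coords()].
#' @return A `kynu_tm` list: `tm`, `L`, `L_aligned`, `d0`, `transform`,
#'   `rmsd_tm_frame`, `rmsd_kabsch` (both Angstrom, with `_nm` variants),
#'   `fold_call` and `rmsd_call` per [classify_structure()].
#' @examples
#' tr <- make_trace(synth_spec(n_residues = 30, seed = 7))
#' tm_optimize(tr, tr)$tm
#' @export
tm_optimize <- function(trace_a, trace_b, alignment = NULL,
                        params = tm_params(), mode = "alignment") {
  pc <- paired_coords(trace_a, trace_b, alignment, mode = mode)
  n <- nrow(pc$a)
  if (n < 3) {
    abort("need at least 3 aligned pairs", class = "kynu_error_too_few_pairs")
  }
  L <- tm_norm_length(params$normalization, nrow(trace_a), nrow(trace_b))
  d0L <- d0(L)

  kb <- kabsch(pc$a, pc$b)
  best_tm <- tm_fixed(pc$a, pc$b, kb, L)
  best_transform <- rigid_transform(kb$rotation, kb$translation)

  frag_lengths <- unique(pmax(params$fragment_min,
                              c(n, floor(n / 2), floor(n / 4))))
  seeds <- list()
  for (fl in frag_lengths) {
    starts <- unique(c(seq(1L, n - fl + 1L, by = max(1L, floor(fl / 2))),
                       n - fl + 1L))
    for (s in starts) seeds[[length(seeds) + 1L]] <- s:(s + fl - 1L)
  }

  consider <- function(transform) {
    tm <- tm_fixed(pc$a, pc$b, transform, L)
    if (tm > best_tm + 1e-12) {
      best_tm <<- tm
      best_transform <<- rigid_transform(transform$rotation, transform$translation)
    }
  }

  for (idx in seeds) {
    if (length(idx) < 3) next
    tr <- suppressWarnings(kabsch(pc$a[idx, , drop = FALSE],
                                  pc$b[idx, , drop = FALSE]))
    consider(tr)
    subset_prev <- idx
    for (it in seq_len(params$max_iter)) {
      di <- pair_distances(pc$a, pc$b, tr)
      cutoff <- d0L
      repeat {
        subset <- which(di < cutoff)
        if (length(subset) >= 3) break
        cutoff <- cutoff + params$cutoff_step
      }
      if (identical(subset, subset_prev)) break
      subset_prev <- subset
      tr <- suppressWarnings(kabsch(pc$a[subset, , drop = FALSE],
                                    pc$b[subset, , drop = FALSE]))
      consider(tr)
    }
  }

  rmsd_tm <- rmsd_fixed_frame(pc$a, pc$b, best_transform)
  calls <- classify_structure(best_tm, rmsd_nm = kb$rmsd_nm)
  structure(list(
    tm = best_tm, L = L, L_aligned = n, d0 = d0L,
    transform = best_transform,
    rmsd_tm_frame = rmsd_tm, rmsd_tm_frame_nm = rmsd_tm / 10,
    rmsd_kabsch = kb$rmsd, rmsd_kabsch_nm = kb$rmsd_nm,
    fold_call = calls$fold_call, rmsd_call = calls$rmsd_call,
    label_a = attr(trace_a, "label"), label_b = attr(trace_b, "label")
  ), class = "kynu_tm")
}

#' @export
print.kynu_tm <- function(x, ...) {
  cat(sprintf(
    "<kynu_tm> %s vs %s: TM = %.3f (L = %d, d0 = %.2f A), RMSD = %.3f nm [%s, %s]\n",
    x$label_a, x$label_b, x$tm, x$L, x$d0, x$rmsd_kabsch_nm,
    x$fold_call, x$rmsd_call))
  invisible(x)
}

#' Fold-similarity and structural-difference calls
#'
#' A TM-score strictly above 0.5 is called a shared overall fold; an RMSD
#' strictly above 0.3 nm is called a structural difference. Boundary values
#' (TM = 0.5, RMSD = 0.3 nm) therefore fall on the negative side of each
#' call.
#'
#' @param tm TM-score in (0, 1].
#' @param rmsd_nm RMSD in nm (>= 0).
#' @param tm_threshold,rmsd_threshold_nm Thresholds (strict inequalities).
#' @return A list with `fold_call` (`"similar_fold"` / `"different_fold"`)
#'   and `rmsd_call` (`"structural_difference"` / `"consistent"`).
#' @examples
#' classify_structure(0.99, 0.03)
#' classify_structure(0.5, 0.3)   # both boundaries: negative side
#' @export
classify_structure <- function(tm, rmsd_nm,
                               tm_threshold = kynu_defaults$tm_threshold,
                               rmsd_threshold_nm = kynu_defaults$rmsd_threshold_nm) {
  stopifnot(tm > 0, tm <= 1 + 1e-9, rmsd_nm >= 0)
  list(
    fold_call = if (tm > tm_threshold) "similar_fold" else "different_fold",
    rmsd_call = if (rmsd_nm > rmsd_threshold_nm) "structural_difference" else "consistent"
  )
}

#' Batch structural comparison of PDB pairs
#'
#' Runs [tm_optimize()] in both normalization directions for each pair of
#' structure files and tabulates scores and calls. A pair whose model file is
#' missing is reported with status `"not_applicable"` rather than failing the
#' batch (some candidates lack a fully predicted model).
#'
#' @param pairs A data frame with columns `label_a`, `path_a`, `label_b`,
#'   `path_b`.
#' @param params A [tm_params()] list; the `normalization` field is ignored
#'   (both directions are always reported).
#' @param mode Residue pairing mode, see [paired_coords()].
#' @return A tibble with one row per pair: `tm_ab` (normalized by A's
#'   length), `tm_ba`, `d0_a`, `d0_b`, `rmsd_kabsch_nm`, `rmsd_tm_frame_nm`,
#'   `fold_call` (from `tm_ab`), `rmsd_call`, `status`.
#' @export
compare_structures <- function(pairs, params = tm_params(), mode = "alignment") {
  purrr::pmap_dfr(pairs, function(label_a, path_a, label_b, path_b, ...) {
    na_row <- tibble(
      label_a = label_a, label_b = label_b,
      tm_ab = NA_real_, tm_ba = NA_real_, d0_a = NA_real_, d0_b = NA_real_,
      rmsd_kabsch_nm = NA_real_, rmsd_tm_frame_nm = NA_real_,
      fold_call = NA_character_, rmsd_call = NA_character_,
      status = "not_applicable"
    )
    if (!file.exists(path_a) || !file.exists(path_b)) return(na_row)
    ta <- read_pdb(path_a, label = label_a)
    tb <- read_pdb(path_b, label = label_b)
    al <- global_align(trace_sequence(ta), trace_sequence(tb))
    p_ref <- tm_params(normalization = "reference",
                       fragment_min = params$fragment_min,
                       max_iter = params$max_iter,
                       cutoff_step = params$cutoff_step)
    p_tgt <- tm_params(normalization = "target",
                       fragment_min = params$fragment_min,
                       max_iter = params$max_iter,
                       cutoff_step = params$cutoff_step)
    ab <- tm_optimize(ta, tb, al, params = p_ref, mode = mode)
    ba <- tm_optimize(ta, tb, al, params = p_tgt, mode = mode)
    tibble(
      label_a = label_a, label_b = label_b,
      tm_ab = ab$tm, tm_ba = ba$tm,
      d0_a = ab$d0, d0_b = ba$d0,
      rmsd_kabsch_nm = ab$rmsd_kabsch_nm,
      rmsd_tm_frame_nm = ab$rmsd_tm_frame_nm,
      fold_call = ab$fold_call, rmsd_call = ab$rmsd_call,
      status = "ok"
    )
  })
}
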