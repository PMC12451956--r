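#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, used to pair
#' residues between two kynureninase sequences before identity calculation or
#' structural superposition. Scoring defaults to BLOSUM62 with gap opening 10
#' and extension 0.5.
#'
#' @param seq_a,seq_b Protein sequences (single strings, 20 standard amino
#'   acids plus `X`).
#' @param substitution Name of the substitution matrix (any matrix shipped
#'   with Biostrings, e.g. `"BLOSUM62"`), or a matrix.
#' @param gap_opening,gap_extension Affine gap penalties (positive costs).
#'
#' @return A `kynu_alignment` list: `pairs` (tibble of `index_a`, `index_b`,
#'   1-based positions of aligned non-gap columns), `aligned_length` (total
#'   alignment columns including gaps), `matches` (identical aligned
#'   residues), `score`, and the two gapped alignment strings.
#' @examples
#' global_align("ACDE", "ACDE")$matches
#' @export
global_align <- function(seq_a, seq_b,
                         substitution = kynu_defaults$substitution,
                         gap_opening = kynu_defaults$gap_opening,
                         gap_extension = kynu_defaults$gap_extension) {
  check_protein(seq_a, "seq_a")
  check_protein(seq_b, "seq_b")
  submat <- if (is.matrix(substitution)) substitution else
    get(data(list = substitution, package = "Biostrings", envir = environment()))
  pa <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "global", substitutionMatrix = submat,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ia <- cumsum(al_a != "-")
  ib <- cumsum(al_b != "-")
  keep <- al_a != "-" & al_b != "-"
  pairs <- tibble(index_a = ia[keep], index_b = ib[keep])
  structure(list(
    pairs = pairs,
    aligned_length = length(al_a),
    matches = sum(keep & al_a == al_b),
    score = Biostrings::score(pa),
    aligned_a = paste(al_a, collapse = ""),
    aligned_b = paste(al_b, collapse = "")
  ), class = "kynu_alignment")
}

#' @export
print.kynu_alignment <- function(x, ...) {
  cat(sprintf(
    "<kynu_alignment> %d columns, %d aligned pairs, %d matches, score %.1f\n",
    x$aligned_length, nrow(x$pairs), x$matches, x$score))
  invisible(x)
}

check_protein <- function(seq, arg) {
  if (length(seq) != 1 || !nzchar(seq)) {
    abort(paste0(arg, " must be a non-empty protein string"),
          class = "kynu_error_empty_sequence")
  }
  bad <- setdiff(strsplit(toupper(seq), "")[[1]], c(names(AA1TO3), "X"))
  if (length(bad)) {
    abort(sprintf("illegal residue character(s) in %s: %s", arg,
                  paste(unique(bad), collapse = "")),
          class = "kynu_error_bad_alphabet")
  }
  invisible(seq)
}

#' Percent identity of an alignment
#'
#' @param alignment A `kynu_alignment`.
#' @param denominator Length used as the denominator: `"alignment_length"`
#'   (all columns, including gap columns; the default), `"shorter_seq"` or
#'   `"longer_seq"`.
#' @return Percent identity (0-100).
#' @export
identity_percent <- function(alignment,
                             denominator = c("alignment_length", "shorter_seq",
                                             "longer_seq")) {
  denominator <- match.arg(denominator)
  la <- max(alignment$pairs$index_a, 0)
  lb <- max(alignment$pairs$index_b, 0)
  # recover full sequence lengths from the gapped strings
  na <- sum(strsplit(alignment$aligned_a, "")[[1]] != "-")
  nb <- sum(strsplit(alignment$aligned_b, "")[[1]] != "-")
  den <- switch(denominator,
    alignment_length = alignment$aligned_length,
    shorter_seq = min(na, nb),
    longer_seq = max(na, nb)
  )
  100 * alignment$matches / den
}

#' Pairwise percent-identity matrix for a labelled sequence set
#'
#' Runs [global_align()] on every pair and tabulates percent identity, the
#' all-against-all comparison used to profile candidate kynureninases against
#' reference enzymes.
#'
#' @param seqs Named character vector of protein sequences (labels must be
#'   unique).
#' @param denominator Passed to [identity_percent()].
#' @inheritParams global_align
#' @return A tibble in long form with columns `label_a`, `label_b`,
#'   `identity`; symmetric, diagonal 100. Use [identity_matrix_wide()] for the
#'   square matrix.
#' @export
identity_matrix <- function(seqs,
                            denominator = "alignment_length",
                            substitution = kynu_defaults$substitution,
                            gap_opening = kynu_defaults$gap_opening,
                            gap_extension = kynu_defaults$gap_extension) {
  if (length(seqs) < 2) {
    abort("need at least 2 sequences", class = "kynu_error_too_few_sequences")
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("sequences must have unique non-empty labels",
          class = "kynu_error_duplicate_labels")
  }
  labs <- names(seqs)
  combos <- utils::combn(seq_along(seqs), 2)
  off <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    al <- global_align(seqs[[i]], seqs[[j]], substitution = substitution,
                       gap_opening = gap_opening, gap_extension = gap_extension)
    tibble(label_a = labs[i], label_b = labs[j],
           identity = identity_percent(al, denominator))
  })
  bind_rows(
    off,
    rename(off, label_a = "label_b", label_b = "label_a"),
    tibble(label_a = labs, label_b = labs, identity = 100)
  ) |>
    mutate(
      label_a = factor(.data$label_a, levels = labs),
      label_b = factor(.data$label_b, levels = labs)
    ) |>
    arrange(.data$label_a, .data$label_b) |>
    mutate(across(c("label_a", "label_b"), as.character))
}

#' Square percent-identity matrix
#'
#' @param identity_tbl Long-form output of [identity_matrix()].
#' @return A symmetric numeric matrix with sequence labels on both dimensions.
#' @export
identity_matrix_wide <- function(identity_tbl) {
  labs <- unique(identity_tbl$label_a)
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  m[cbind(identity_tbl$label_a, identity_tbl$label_b)] <- identity_tbl$identity
  m
}

#' Write an identity matrix as TSV
#'
#' @param identity_tbl Long-form output of [identity_matrix()].
#' @param path Output TSV path (labels in the first column).
#' @return `path`, invisibly.
#' @export
write_identity_tsv <- function(identity_tbl, path) {
  m <- identity_matrix_wide(identity_tbl)
  df <- tibble::rownames_to_column(as.data.frame(m), "label")
  readr::write_tsv(df, path)
  invisible(path)
}
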