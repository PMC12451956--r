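#' Read an alpha-carbon trace from a PDB file
#'
#' Parses a PDB file and extracts one CA atom per residue for a single chain,
#' returning an ordered trace suitable for superposition and TM-score
#' computation. Where a CA has alternate locations, the highest-occupancy
#' altloc is kept (ties broken by altloc letter). HETATM records and waters
#' are ignored; selenomethionine (MSE) is read as methionine.
#'
#' @param path Path to a PDB file.
#' @param chain Chain identifier. Default: first chain containing CA atoms.
#' @param model Model index (1-based) for multi-model files. Default 1.
#' @param label Label stored on the trace; defaults to the file name.
#'
#' @return A `kynu_trace`: a tibble with columns `residue_number` (as in the
#'   file, 1-based), `aa` (one-letter code, `X` for non-standard residues),
#'   and `x`, `y`, `z` (Angstrom). The label is kept in attribute `label`.
#'
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' write_trace_pdb(make_trace(synth_spec(n_residues = 8, seed = 1)), pdb)
#' read_pdb(pdb)
#' @export
read_pdb <- function(path, chain = NULL, model = 1L, label = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path), class = "kynu_error_missing_file")
  }
  multi <- !is.null(model) && model > 1L
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = multi))
  atoms <- as_tibble(pdb$atom)
  atoms <- filter(atoms, .data$type == "ATOM", .data$elety == "CA",
                  !(.data$resid %in% c("HOH", "WAT")))
  if (nrow(atoms) == 0) {
    abort("no CA atoms found in PDB file", class = "kynu_error_no_ca")
  }
  if (multi) {
    if (model > nrow(pdb$xyz)) {
      abort(sprintf("model %d absent (file has %d)", model, nrow(pdb$xyz)),
            class = "kynu_error_model_absent")
    }
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    idx <- which(pdb$atom$type == "ATOM" & pdb$atom$elety == "CA" &
                   !(pdb$atom$resid %in% c("HOH", "WAT")))
    atoms$x <- xyz[idx, 1]; atoms$y <- xyz[idx, 2]; atoms$z <- xyz[idx, 3]
  }
  if (is.null(chain)) {
    chain <- atoms$chain[1]
  } else if (!chain %in% atoms$chain) {
    abort(sprintf("chain '%s' absent from %s", chain, path),
          class = "kynu_error_chain_absent")
  }
  atoms <- filter(atoms, .data$chain == !!chain)
  # altloc: keep highest occupancy, tie -> lexicographically first altloc
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms <- atoms |>
    arrange(.data$resno, dplyr::desc(.data$o), .data$alt) |>
    distinct(.data$resno, .keep_all = TRUE)
  trace <- tibble(
    residue_number = as.integer(atoms$resno),
    aa = aa_three_to_one(atoms$resid),
    x = atoms$x, y = atoms$y, z = atoms$z
  )
  new_trace(trace, label = label)
}

new_trace <- function(df, label = "trace") {
  stopifnot(all(c("residue_number", "aa", "x", "y", "z") %in% names(df)))
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    abort("non-finite coordinates in trace", class = "kynu_error_coords")
  }
  if (is.unsorted(df$residue_number, strictly = TRUE)) {
    abort("residue numbers must be strictly increasing",
          class = "kynu_error_numbering")
  }
  out <- as_tibble(df[, c("residue_number", "aa", "x", "y", "z")])
  attr(out, "label") <- label
  class(out) <- c("kynu_trace", class(out))
  check_ca_spacing(out)
  out
}

# Consecutive CA-CA distances outside 2.5-4.5 A are physically implausible for
# a real chain (trans peptide ~3.8 A); warn but keep, since synthetic decoys
# legitimately violate this.
check_ca_spacing <- function(trace) {
  if (nrow(trace) < 2) return(invisible(trace))
  xyz <- trace_coords(trace)
  d <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
  gap <- diff(trace$residue_number) == 1L
  bad <- gap & (d < 2.5 | d > 4.5)
  if (any(bad)) {
    warn(sprintf("%d consecutive CA-CA distances outside 2.5-4.5 A", sum(bad)),
         class = "kynu_warning_ca_spacing")
  }
  invisible(trace)
}

#' @export
print.kynu_trace <- function(x, ...) {
  cat(sprintf("<kynu_trace> %s: %d residues\n", attr(x, "label"), nrow(x)))
  NextMethod()
}

#' Extract the coordinate matrix of a trace
#'
#' @param trace A `kynu_trace`.
#' @return An n x 3 numeric matrix of CA coordinates in Angstrom.
#' @export
trace_coords <- function(trace) {
  as.matrix(trace[, c("x", "y", "z")])
}

#' One-letter sequence of a trace
#'
#' @param trace A `kynu_trace`.
#' @return A single string of one-letter amino-acid codes.
#' @export
trace_sequence <- function(trace) {
  paste(trace$aa, collapse = "")
}

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M"
)

aa_three_to_one <- function(res3) {
  out <- unname(AA3TO1[toupper(res3)])
  out[is.na(out)] <- "X"
  out
}

AA1TO3 <- setNames(names(AA3TO1)[1:20], unname(AA3TO1)[1:20])

#' Write a trace to a PDB file, optionally after a rigid transform
#'
#' @param trace A `kynu_trace`.
#' @param path Output path.
#' @param transform Optional rigid transform as returned by [kabsch()] or
#'   [rigid_transform()]; applied before writing. Must be a proper rotation.
#' @return `path`, invisibly.
#' @export
write_trace_pdb <- function(trace, path, transform = NULL) {
  xyz <- trace_coords(trace)
  if (!is.null(transform)) {
    check_rotation(transform$rotation)
    xyz <- apply_transform(xyz, transform)
  }
  res3 <- unname(AA1TO3[trace$aa])
  res3[is.na(res3)] <- "UNK"
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    resno = trace$residue_number,
    resid = res3,
    elety = rep("CA", nrow(trace)),
    chain = rep("A", nrow(trace))
  )
  invisible(path)
}

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 proper rotation matrix (orthonormal, det = +1).
#' @param translation Length-3 translation vector (Angstrom).
#' @return A `kynu_transform` list with elements `rotation` and `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  check_rotation(rotation)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "kynu_transform")
}

check_rotation <- function(R) {
  if (!all(dim(R) == c(3, 3)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6 ||
      abs(det(R) - 1) > 1e-6) {
    abort("not a proper rotation matrix (orthonormal, det = +1)",
          class = "kynu_error_not_rotation")
  }
  invisible(R)
}

# y = x R^T + t, row-vector convention
apply_transform <- function(xyz, transform) {
  sweep(xyz %*% t(transform$rotation), 2, -transform$translation)
}

#' Export trace sequences as FASTA
#'
#' @param traces A list of `kynu_trace` objects (names used as labels when
#'   present, else each trace's own label).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_trace_fasta <- function(traces, path) {
  if (inherits(traces, "kynu_trace")) traces <- list(traces)
  labels <- names(traces)
  if (is.null(labels)) labels <- rep(NA_character_, length(traces))
  seqs <- vapply(traces, trace_sequence, character(1))
  labels <- ifelse(is.na(labels) | labels == "",
                   vapply(traces, function(t) attr(t, "label"), character(1)),
                   labels)
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- labels
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA path.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "kynu_error_missing_file")
  }
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa), names(aa))
}
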