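#' Translate a coding sequence
#'
#' Standard-table translation of a cloned CDS. A single trailing stop codon
#' is trimmed; an internal stop is an error (the insert would be truncated).
#'
#' @param cds Nucleotide string (A/C/G/T), length a multiple of 3.
#' @return Amino-acid string.
#' @examples
#' translate_cds("ATGGGTTAA")
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) {
    abort("CDS must contain only A/C/G/T", class = "kynu_error_bad_alphabet")
  }
  if (nchar(cds) == 0 || nchar(cds) %% 3 != 0) {
    abort("CDS length must be a positive multiple of 3",
          class = "kynu_error_cds_length")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1)
  if (grepl("\\*", aa)) {
    abort("internal stop codon in CDS", class = "kynu_error_internal_stop")
  }
  aa
}

# Average residue (i.e. water-free) masses in Da; protein mass adds one water.
AA_AVG_MASS <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
WATER_MASS <- 18.02

#' Average molecular mass of a protein
#'
#' Sum of average (not monoisotopic) residue masses plus one water, the
#' quantity an SDS-PAGE band size estimates.
#'
#' @param protein Amino-acid string (20 standard residues).
#' @return Mass in kDa.
#' @examples
#' average_mass_kda("G") * 1000  # 75.07 Da
#' @export
average_mass_kda <- function(protein) {
  res <- strsplit(toupper(protein), "")[[1]]
  if (length(res) == 0) {
    abort("empty protein", class = "kynu_error_empty_sequence")
  }
  bad <- setdiff(res, names(AA_AVG_MASS))
  if (length(bad)) {
    abort(sprintf("unknown residue(s): %s", paste(unique(bad), collapse = "")),
          class = "kynu_error_bad_alphabet")
  }
  (sum(AA_AVG_MASS[res]) + WATER_MASS) / 1000
}

#' Expected masses of His-tagged expression constructs
#'
#' Translates each cloned CDS and adds the expression-tag mass (0.84 kDa
#' His-tag by default) to give the band size expected on an immunoblot.
#'
#' @param constructs A data frame (or named character vector of CDS strings)
#'   with columns `name` and `cds`.
#' @param tag_kda Tag mass added to each construct, kDa.
#' @return A tibble: `name`, `protein`, `length_aa`, `protein_kda`,
#'   `tag_kda`, `expected_kda` (2 d.p. is the reporting precision; full
#'   precision is returned).
#' @export
construct_masses <- function(constructs, tag_kda = kynu_defaults$his_tag_kda) {
  if (is.character(constructs)) {
    constructs <- tibble(name = names(constructs), cds = unname(constructs))
  }
  purrr::pmap_dfr(constructs[, c("name", "cds")], function(name, cds) {
    protein <- translate_cds(cds)
    pk <- average_mass_kda(protein)
    tibble(name = name, protein = protein, length_aa = nchar(protein),
           protein_kda = pk, tag_kda = tag_kda, expected_kda = pk + tag_kda)
  })
}

#' Write a construct-mass table as TSV
#'
#' @param masses Output of [construct_masses()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_masses_tsv <- function(masses, path) {
  readr::write_tsv(
    mutate(select(masses, "name", "length_aa", "expected_kda"),
           expected_kda = round(.data$expected_kda, 2)),
    path
  )
  invisible(path)
}
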