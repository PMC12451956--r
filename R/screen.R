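#' Read a BLAST tabular (outfmt 6) hit file
#'
#' @param path TSV with the 12 standard columns (qseqid, sseqid, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#'   bitscore). No header.
#' @return A tibble with those columns; zero rows for an empty file.
#' @export
read_blast_tab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (!file.exists(path)) {
    abort(paste0("BLAST file not found: ", path), class = "kynu_error_missing_file")
  }
  if (file.size(path) == 0) {
    return(as_tibble(setNames(
      c(rep(list(character()), 2), rep(list(numeric()), 10)), cols)))
  }
  hits <- suppressWarnings(
    readr::read_tsv(path, col_names = cols, show_col_types = FALSE,
                    col_types = "ccnnnnnnnnnn")
  )
  if (!all(cols %in% names(hits)) ||
      any(is.na(hits$sseqid) | is.na(hits$evalue))) {
    abort("malformed BLAST tabular row", class = "kynu_error_malformed_row")
  }
  hits
}

#' Filter BLAST hits by e-value and collapse to per-taxon evidence
#'
#' Retains hits with e-value less than or equal to the cutoff (inclusive, per
#' the screen's "e-value cutoff <= 0.001" rule), keeps the best (smallest)
#' e-value per taxon, and emits gene-presence records with evidence class
#' `"blast"`.
#'
#' @param hits BLAST tabular tibble from [read_blast_tab()]; the subject id
#'   is taken as the taxon label.
#' @param gene Gene the query probes for (default `"kynU"`).
#' @param max_evalue Inclusive e-value cutoff.
#' @return A tibble of records: `taxon`, `gene`, `evidence`, `evalue`,
#'   `source_id`.
#' @export
filter_blast <- function(hits, gene = "kynU",
                         max_evalue = kynu_defaults$evalue_cutoff) {
  hits |>
    filter(.data$evalue <= max_evalue) |>
    mutate(taxon = normalize_taxon(.data$sseqid)) |>
    group_by(.data$taxon) |>
    slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
    ungroup() |>
    mutate(gene = gene, evidence = "blast", source_id = .data$qseqid) |>
    select("taxon", "gene", "evidence", "evalue", "source_id")
}

#' Read an ortholog-annotation table
#'
#' @param path TSV with header and columns `taxon`, `gene`, `ec`, `source`
#'   (a snapshot of an EC/KO ortholog export, one row per taxon-gene).
#' @return A tibble of records: `taxon`, `gene`, `evidence = "annotation"`,
#'   `evalue = NA`, `source_id`.
#' @export
read_ortholog_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, col_types = "cccc")
  tibble(
    taxon = normalize_taxon(tab$taxon),
    gene = tab$gene,
    evidence = "annotation",
    evalue = NA_real_,
    source_id = tab$ec
  )
}

#' Read an oral-taxon whitelist
#'
#' @param path Plain-text file, one taxon per line.
#' @return Character vector of normalized taxon names.
#' @export
read_oral_taxa <- function(path) {
  normalize_taxon(readLines(path, warn = FALSE)) |> setdiff("")
}

normalize_taxon <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  x <- gsub("_", " ", x)
  tolower(x)
}

#' Build the candidate table from gene-presence records
#'
#' One row per observed taxon with presence flags for the pathway-entry
#' genes (tdo, ido) and kynU, an oral flag from the whitelist, and the
#' candidate rule: a candidate is an oral taxon carrying kynU together with
#' at least one pathway entry (tdo or ido).
#'
#' @param records Gene-presence tibble (rows with `taxon`, `gene`,
#'   `evidence`), e.g. from [read_ortholog_table()] and [filter_blast()]
#'   combined with [dplyr::bind_rows()].
#' @param oral_taxa Character vector of oral taxon names.
#' @return A `kynu_candidates` tibble: `taxon`, `has_tdo`, `has_ido`,
#'   `has_kynU`, `kynU_evidence` (comma-joined evidence classes), `is_oral`,
#'   `candidate_flag`; summary counts in attribute `summary`.
#' @export
build_candidates <- function(records, oral_taxa) {
  oral <- normalize_taxon(oral_taxa)
  out <- records |>
    mutate(taxon = normalize_taxon(.data$taxon)) |>
    group_by(.data$taxon) |>
    summarise(
      has_tdo = any(.data$gene == "tdo"),
      has_ido = any(.data$gene == "ido"),
      has_kynU = any(.data$gene == "kynU"),
      kynU_evidence = paste(sort(unique(.data$evidence[.data$gene == "kynU"])),
                            collapse = ","),
      .groups = "drop"
    ) |>
    mutate(
      is_oral = .data$taxon %in% oral,
      candidate_flag = .data$is_oral & .data$has_kynU &
        (.data$has_tdo | .data$has_ido)
    ) |>
    arrange(.data$taxon)
  attr(out, "summary") <- list(
    n_taxa = nrow(out),
    n_tdo = sum(out$has_tdo),
    n_ido = sum(out$has_ido),
    n_kynU = sum(out$has_kynU),
    n_oral = sum(out$is_oral),
    n_candidates = sum(out$candidate_flag)
  )
  class(out) <- c("kynu_candidates", class(out))
  out
}

#' @export
print.kynu_candidates <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "<kynu_candidates> %d taxa: %d tdo, %d ido, %d kynU, %d oral, %d candidates\n",
    s$n_taxa, s$n_tdo, s$n_ido, s$n_kynU, s$n_oral, s$n_candidates))
  NextMethod()
}

#' Write the candidate table (TSV) and its summary (JSON)
#'
#' @param candidates Output of [build_candidates()].
#' @param tsv_path,json_path Output paths; either may be `NULL` to skip.
#' @return `tsv_path`, invisibly.
#' @export
write_candidates <- function(candidates, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) readr::write_tsv(as_tibble(candidates), tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(attr(candidates, "summary"), json_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
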