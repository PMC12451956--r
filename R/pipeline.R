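#' Pipeline configuration
#'
#' Collects paths, stage toggles and thresholds for [run_pipeline()].
#' Thresholds default to the screen's reference values (TM > 0.5 for fold
#' similarity, RMSD > 0.3 nm for structural difference, BLAST e-value <=
#' 0.001); all are surfaced here rather than hard-coded.
#'
#' @param ortholog_tsv,oral_txt,blast_tsv Screening inputs (see
#'   [read_ortholog_table()], [read_oral_taxa()], [read_blast_tab()]).
#' @param fasta Protein FASTA for the identity-matrix stage.
#' @param model_paths Named character vector/list of PDB paths; all pairs
#'   against the first entry (the reference) are compared. Missing files are
#'   tolerated and reported `not_applicable`.
#' @param constructs_csv CSV with `name`, `cds` for the mass stage.
#' @param standards_csv,samples_csv Quantification inputs.
#' @param lods Named LOD vector (uM per analyte) for the quant stage.
#' @param stages Character vector of stages to run, a subset of
#'   `c("screen", "align", "struct", "props", "quant")`.
#' @param out_dir Output directory for stage TSV/CSV files, the JSON
#'   summary and the run log.
#' @param tm_threshold,rmsd_threshold_nm,evalue_cutoff Decision thresholds.
#' @param identity_denominator Passed to [identity_percent()].
#' @param normalization TM-score normalization for the reported direction.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return A `kynu_config` list.
#' @export
pipeline_config <- function(ortholog_tsv = NULL, oral_txt = NULL,
                            blast_tsv = NULL, fasta = NULL,
                            model_paths = NULL, constructs_csv = NULL,
                            standards_csv = NULL, samples_csv = NULL,
                            lods = NULL,
                            stages = c("screen", "align", "struct", "props", "quant"),
                            out_dir = tempfile("kynu_run_"),
                            tm_threshold = kynu_defaults$tm_threshold,
                            rmsd_threshold_nm = kynu_defaults$rmsd_threshold_nm,
                            evalue_cutoff = kynu_defaults$evalue_cutoff,
                            identity_denominator = "alignment_length",
                            normalization = "reference",
                            seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "kynu_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A `kynu_config`.
#' @param path JSON path.
#' @return `config_from_json()` returns the restored `kynu_config`.
#' @export
config_to_json <- function(config, path) {
  obj <- unclass(config)
  # named vectors must serialize as JSON objects, not bare arrays
  for (field in c("lods", "model_paths")) {
    if (!is.null(obj[[field]])) obj[[field]] <- as.list(obj[[field]])
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$model_paths <- unlist(obj$model_paths)
  obj$lods <- unlist(obj$lods)
  structure(obj, class = "kynu_config")
}

#' Run the screening pipeline
#'
#' Orchestrates the stages: gene-presence screening, sequence-identity
#' matrix, structural comparison (TM-score and RMSD with fold calls),
#' expected construct masses, and metabolite quantification. Each stage
#' writes a TSV/CSV under `out_dir`; a versioned JSON summary and a plain
#' log (recording every default applied: the d0 formula, normalization
#' direction and identity denominator) are always written. A stage whose
#' inputs are absent, or that fails, is reported with status
#' `"not_applicable"`/`"failed"` and downstream stages still run.
#'
#' @param config A [pipeline_config()].
#' @return A `kynu_report` list with one element per stage (each holding
#'   `status` and the stage result), plus `summary_json` and `log_path`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    "kynuscreen pipeline run",
    sprintf("seed: %d", config$seed),
    "d0 formula: 1.24*(L-15)^(1/3) - 1.8, floored at 0.5 A",
    sprintf("TM normalization: %s (both directions tabulated)", config$normalization),
    sprintf("identity denominator: %s", config$identity_denominator),
    sprintf("thresholds: tm > %g, rmsd > %g nm, evalue <= %g",
            config$tm_threshold, config$rmsd_threshold_nm, config$evalue_cutoff)
  )
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  run_stage <- function(name, inputs, fn) {
    if (!name %in% config$stages) {
      return(list(status = "skipped", result = NULL))
    }
    if (any(vapply(inputs, is.null, logical(1))) ||
        !all(file.exists(unlist(inputs)))) {
      note("stage %s: inputs missing -> not_applicable", name)
      return(list(status = "not_applicable", result = NULL))
    }
    res <- tryCatch(list(status = "ok", result = fn()),
                    error = function(e) {
                      note("stage %s failed: %s", name, conditionMessage(e))
                      list(status = "failed", result = conditionMessage(e))
                    })
    note("stage %s: %s", name, res$status)
    res
  }

  screen <- run_stage("screen",
    list(config$ortholog_tsv, config$oral_txt, config$blast_tsv), function() {
      records <- bind_rows(
        read_ortholog_table(config$ortholog_tsv),
        filter_blast(read_blast_tab(config$blast_tsv),
                     max_evalue = config$evalue_cutoff)
      )
      cand <- build_candidates(records, read_oral_taxa(config$oral_txt))
      write_candidates(cand, file.path(config$out_dir, "candidates.tsv"),
                       file.path(config$out_dir, "screen_summary.json"))
      cand
    })

  align <- run_stage("align", list(config$fasta), function() {
    seqs <- read_fasta(config$fasta)
    idm <- identity_matrix(seqs, denominator = config$identity_denominator)
    write_identity_tsv(idm, file.path(config$out_dir, "identity_matrix.tsv"))
    idm
  })

  struct <- run_stage("struct", list(config$model_paths[1]), function() {
    mp <- unlist(config$model_paths)
    labs <- names(mp)
    pairs <- tibble(
      label_a = labs[1], path_a = mp[[1]],
      label_b = labs[-1], path_b = unname(mp[-1])
    )
    res <- compare_structures(pairs)
    res <- mutate(res,
      fold_call = ifelse(.data$status == "ok", .data$fold_call, NA),
      rmsd_call = ifelse(.data$status == "ok", .data$rmsd_call, NA))
    readr::write_tsv(res, file.path(config$out_dir, "structure_comparison.tsv"))
    res
  })

  props <- run_stage("props", list(config$constructs_csv), function() {
    masses <- construct_masses(readr::read_csv(config$constructs_csv,
                                               show_col_types = FALSE))
    write_masses_tsv(masses, file.path(config$out_dir, "construct_masses.tsv"))
    masses
  })

  quant <- run_stage("quant",
    list(config$standards_csv, config$samples_csv), function() {
      standards <- read_standards_csv(config$standards_csv)
      samples <- read_samples_csv(config$samples_csv)
      curves <- standards |>
        split(standards$analyte) |>
        purrr::imap(function(df, an) {
          fit_calibration(df, analyte = an,
                          lod = if (an %in% names(config$lods)) config$lods[[an]] else 0)
        })
      q <- quantify_samples(samples, curves)
      write_quant_csv(q, file.path(config$out_dir, "metabolite_summary.csv"))
      q
    })

  report <- list(
    schema_version = "1.0",
    seed = config$seed,
    stages = list(screen = screen, align = align, struct = struct,
                  props = props, quant = quant)
  )
  summary <- list(
    schema_version = report$schema_version,
    seed = config$seed,
    screen = if (screen$status == "ok") attr(screen$result, "summary") else screen$status,
    identity = if (align$status == "ok") as.data.frame(align$result) else align$status,
    structure = if (struct$status == "ok") as.data.frame(struct$result) else struct$status,
    construct_masses = if (props$status == "ok")
      as.data.frame(select(props$result, -"protein")) else props$status,
    metabolites = if (quant$status == "ok") as.data.frame(quant$result) else quant$status
  )
  summary_json <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_json, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  log_path <- file.path(config$out_dir, "run.log")
  writeLines(log_lines, log_path)
  structure(c(report, list(summary_json = summary_json, log_path = log_path,
                           out_dir = config$out_dir)),
            class = "kynu_report")
}

#' @export
print.kynu_report <- function(x, ...) {
  cat("<kynu_report> stages:\n")
  for (nm in names(x$stages)) {
    cat(sprintf("  %-7s %s\n", nm, x$stages[[nm]]$status))
  }
  cat("summary:", x$summary_json, "\n")
  invisible(x)
}
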