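#' Specification for a synthetic CA trace
#'
#' @param n_residues Number of residues (>= 3).
#' @param noise_sigma Gaussian coordinate noise, Angstrom per axis.
#' @param topology `"helix"` (ideal alpha-helix: 1.5 A rise, 100 degrees per
#'   residue, 2.3 A radius, giving ~3.8 A CA-CA spacing), `"zigzag"` or
#'   `"random_walk"` (decoy folds for the different-fold branch of the
#'   classifier).
#' @param seed RNG seed; the same spec always yields identical coordinates.
#' @return A `kynu_synth_spec` list.
#' @export
synth_spec <- function(n_residues = 100L, noise_sigma = 0,
                       topology = c("helix", "zigzag", "random_walk"),
                       seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_residues >= 3, noise_sigma >= 0)
  structure(list(n_residues = as.integer(n_residues),
                 noise_sigma = noise_sigma, topology = topology,
                 seed = as.integer(seed)),
            class = "kynu_synth_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic CA trace
#'
#' Stands in for a predicted protein model: a parametrized backbone with a
#' random amino-acid sequence and optional per-axis Gaussian coordinate
#' noise. Deterministic for a fixed spec.
#'
#' @param spec A [synth_spec()].
#' @param label Trace label.
#' @return A `kynu_trace`.
#' @examples
#' make_trace(synth_spec(n_residues = 50, seed = 2))
#' @export
make_trace <- function(spec, label = paste0("synthetic_", spec$topology)) {
  n <- spec$n_residues
  with_seed(spec$seed, {
    xyz <- switch(spec$topology,
      helix = {
        i <- seq_len(n) - 1
        theta <- i * 100 * pi / 180
        cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i)
      },
      zigzag = {
        i <- seq_len(n) - 1
        cbind(3.6 * i, rep(c(0, 1.2), length.out = n), rep(0, n))
      },
      random_walk = {
        steps <- matrix(rnorm(3 * (n - 1)), ncol = 3)
        steps <- 3.8 * steps / sqrt(rowSums(steps^2))
        rbind(c(0, 0, 0), apply(steps, 2, cumsum))
      }
    )
    aa <- sample(names(AA1TO3), n, replace = TRUE)
    if (spec$noise_sigma > 0) {
      xyz <- xyz + matrix(rnorm(3 * n, sd = spec$noise_sigma), ncol = 3)
    }
    suppressWarnings(new_trace(
      tibble(residue_number = seq_len(n), aa = aa,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
      label = label
    ))
  })
}

#' Uniform random proper rotation
#'
#' Sampled via unit quaternions to avoid axis bias.
#' @param seed Optional seed (uses the current RNG stream when `NULL`).
#' @return A 3 x 3 rotation matrix, det +1.
#' @export
random_rotation <- function(seed = NULL) {
  draw <- function() {
    q <- rnorm(4)
    q <- q / sqrt(sum(q^2))
    quat_to_rotation(q)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

quat_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Rigidly perturb a trace with known ground truth
#'
#' Applies a uniform-random proper rotation and translation, then i.i.d.
#' Gaussian coordinate noise, and returns both the perturbed trace and the
#' ground-truth transform for recovery tests.
#'
#' @param trace A `kynu_trace`.
#' @param noise_sigma Noise after the rigid motion, Angstrom per axis.
#' @param seed RNG seed.
#' @param max_translation Translations drawn uniformly in
#'   `[-max_translation, max_translation]` per axis (Angstrom).
#' @return A list: `trace` (perturbed copy), `transform` (the applied
#'   `kynu_transform`), `noise_sigma`.
#' @export
perturb_trace <- function(trace, noise_sigma = 0, seed = 1L,
                          max_translation = 20) {
  with_seed(seed, {
    R <- random_rotation()
    tr <- runif(3, -max_translation, max_translation)
    transform <- rigid_transform(R, tr)
    xyz <- apply_transform(trace_coords(trace), transform)
    if (noise_sigma > 0) {
      xyz <- xyz + matrix(rnorm(length(xyz), sd = noise_sigma), ncol = 3)
    }
    out <- trace
    out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
    attr(out, "label") <- paste0(attr(trace, "label"), "_perturbed")
    list(trace = out, transform = transform, noise_sigma = noise_sigma)
  })
}

#' Generate a gene-presence screening fixture
#'
#' Writes an ortholog-annotation TSV, an oral-taxon list and a BLAST
#' outfmt-6 TSV in which a chosen set of oral taxa carries tdo + kynU (so
#' [build_candidates()] on the fixture recovers exactly the planted set).
#' Non-candidate taxa carry tdo or ido only, some are non-oral, and the
#' BLAST file includes above-cutoff decoy hits.
#'
#' @param dir Output directory (created if needed).
#' @param n_taxa Total number of taxa carrying a pathway-entry gene.
#' @param n_planted Number of planted oral tdo + kynU candidates.
#' @param seed RNG seed.
#' @return A list of paths: `ortholog_tsv`, `oral_txt`, `blast_tsv`, plus
#'   `planted` (taxon names).
#' @export
make_screen_fixture <- function(dir, n_taxa = 71L, n_planted = 7L, seed = 1L) {
  stopifnot(n_planted <= n_taxa)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    taxa <- sprintf("taxon %03d", seq_len(n_taxa))
    planted <- taxa[seq_len(n_planted)]
    # some extra oral taxa that lack kynU, and non-oral kynU carriers
    oral_extra <- taxa[n_planted + seq_len(min(3L, n_taxa - n_planted))]
    nonoral_kynu <- tail(taxa, 2)
    ann <- bind_rows(
      tibble(taxon = taxa, gene = "tdo", ec = "1.13.11.11", source = "ortholog_db"),
      tibble(taxon = sample(taxa, max(1L, n_taxa %/% 3)), gene = "ido",
             ec = "1.13.11.52", source = "ortholog_db"),
      tibble(taxon = c(planted, nonoral_kynu), gene = "kynU", ec = "3.7.1.3",
             source = "ortholog_db")
    )
    oral <- c(planted, oral_extra)
    blast <- tibble(
      qseqid = "kynU_probe_PAO1",
      sseqid = gsub(" ", "_", c(planted, oral_extra)),
      pident = round(runif(n_planted + length(oral_extra), 30, 95), 1),
      length = 420L, mismatch = 10L, gapopen = 1L,
      qstart = 1L, qend = 420L, sstart = 1L, send = 420L,
      evalue = c(10^runif(n_planted, -60, -10),       # real hits, well under cutoff
                 10^runif(length(oral_extra), -2, 0)), # decoys above cutoff
      bitscore = 500
    )
    paths <- list(
      ortholog_tsv = file.path(dir, "orthologs.tsv"),
      oral_txt = file.path(dir, "oral_taxa.txt"),
      blast_tsv = file.path(dir, "kynu_blast.tsv"),
      planted = planted
    )
    readr::write_tsv(ann, paths$ortholog_tsv)
    writeLines(oral, paths$oral_txt)
    readr::write_tsv(blast, paths$blast_tsv, col_names = FALSE)
    paths
  })
}

#' Generate a metabolite-quantification fixture
#'
#' Writes a standards CSV (known line, optional multiplicative Gaussian area
#' noise) and a samples CSV whose peak areas encode known per-fraction true
#' concentrations, so the quantification pipeline can be checked against
#' planted truth.
#'
#' @param dir Output directory.
#' @param truth A data frame with columns `sample`, `analyte`, `fraction`,
#'   `replicate`, `conc` (true uM; values below the analyte LOD exercise
#'   censoring).
#' @param lods Named numeric vector of LODs (uM) per analyte.
#' @param slopes,intercepts Named numeric vectors per analyte (defaults:
#'   slope 1000 area/uM, intercept 50).
#' @param noise_pct Multiplicative area noise, percent (0 = exact).
#' @param n_std Standard points per analyte.
#' @param seed RNG seed.
#' @return A list: `standards_csv`, `samples_csv`, `truth`, `lods`.
#' @export
make_quant_fixture <- function(dir, truth, lods, slopes = NULL,
                               intercepts = NULL, noise_pct = 0,
                               n_std = 6L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  analytes <- sort(unique(truth$analyte))
  if (is.null(slopes)) slopes <- setNames(rep(1000, length(analytes)), analytes)
  if (is.null(intercepts)) intercepts <- setNames(rep(50, length(analytes)), analytes)
  with_seed(seed, {
    noisy <- function(x) x * (1 + rnorm(length(x), sd = noise_pct / 100))
    standards <- purrr::map_dfr(analytes, function(an) {
      conc <- seq(0, 100, length.out = n_std)
      tibble(analyte = an, conc = conc,
             area = noisy(slopes[[an]] * conc + intercepts[[an]]))
    })
    samples <- truth |>
      mutate(peak_area = noisy(slopes[as.character(.data$analyte)] * .data$conc +
                                 intercepts[as.character(.data$analyte)])) |>
      mutate(replicate = as.character(.data$replicate)) |>
      select("sample", "analyte", "fraction", "replicate", "peak_area")
    paths <- list(standards_csv = file.path(dir, "standards.csv"),
                  samples_csv = file.path(dir, "samples.csv"),
                  truth = truth, lods = lods)
    readr::write_csv(standards, paths$standards_csv)
    readr::write_csv(samples, paths$samples_csv)
    paths
  })
}

#' Generate the full synthetic fixture tree for a pipeline run
#'
#' Builds structures (a reference helix, a rigid noisy homolog, a zigzag
#' decoy, and a deliberately missing model entry), construct CDS FASTA,
#' screening tables and quantification CSVs under one directory, mirroring
#' the inputs of a full screening study.
#'
#' @param dir Output directory.
#' @param seed RNG seed.
#' @param n_residues Residues per synthetic structure.
#' @return A list of paths and planted ground truths, suitable for
#'   [pipeline_config()].
#' @export
make_pipeline_fixture <- function(dir, seed = 1L, n_residues = 120L) {
  dir.create(file.path(dir, "models"), showWarnings = FALSE, recursive = TRUE)
  ref <- make_trace(synth_spec(n_residues, seed = seed), label = "ref")
  hom <- perturb_trace(ref, noise_sigma = 0.5, seed = seed + 1L)$trace
  attr(hom, "label") <- "homolog"
  hom$aa <- mutate_sequence(ref$aa, prop = 0.3, seed = seed + 2L)
  decoy <- make_trace(synth_spec(n_residues, topology = "zigzag",
                                 seed = seed + 3L), label = "decoy")
  models <- list(ref = ref, homolog = hom, decoy = decoy)
  model_paths <- purrr::imap(models, function(tr, nm) {
    p <- file.path(dir, "models", paste0(nm, ".pdb"))
    write_trace_pdb(tr, p)
    p
  })
  model_paths$missing <- file.path(dir, "models", "missing.pdb")  # never written
  fasta <- file.path(dir, "sequences.fasta")
  write_trace_fasta(models, fasta)
  constructs <- synth_constructs(seed = seed)
  constructs_csv <- file.path(dir, "constructs.csv")
  readr::write_csv(constructs, constructs_csv)
  screen <- make_screen_fixture(file.path(dir, "screen"), seed = seed)
  truth <- tidyr::expand_grid(
    sample = c("candA", "candB"), analyte = c("AA", "KYNA"),
    fraction = c("extracellular", "intracellular"), replicate = 1:3
  ) |>
    mutate(conc = with_seed(seed + 4L, round(runif(n(), 5, 60), 2)))
  quant <- make_quant_fixture(file.path(dir, "quant"), truth,
                              lods = c(AA = 0.001, KYNA = 0.1),
                              noise_pct = 0, seed = seed + 5L)
  list(dir = dir, models = model_paths, fasta = fasta,
       constructs_csv = constructs_csv, screen = screen, quant = quant,
       traces = models)
}

mutate_sequence <- function(aa, prop, seed) {
  with_seed(seed, {
    idx <- sample(length(aa), round(prop * length(aa)))
    aa[idx] <- sample(names(AA1TO3), length(idx), replace = TRUE)
    aa
  })
}

#' Synthetic expression constructs
#'
#' Random CDS sequences (no internal stop) at kynureninase scale, for
#' exercising translation and mass prediction. Deterministic per seed.
#'
#' @param lengths_aa Named integer vector: protein length per construct.
#' @param seed RNG seed.
#' @return A tibble with `name` and `cds`.
#' @export
synth_constructs <- function(lengths_aa = c(synthA = 420L, synthB = 250L),
                             seed = 1L) {
  codons <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA")
  )
  with_seed(seed, {
    purrr::imap_dfr(lengths_aa, function(len, nm) {
      tibble(name = nm,
             cds = paste(c(sample(codons, len, replace = TRUE), "TAA"),
                         collapse = ""))
    })
  })
}
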