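write_blast_fixture <- function(rows) {
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(rows, path, col_names = FALSE)
  path
}

blast_row <- function(taxon, evalue) {
  tibble::tibble(qseqid = "kynU_probe", sseqid = taxon, pident = 70,
                 length = 400L, mismatch = 5L, gapopen = 0L, qstart = 1L,
                 qend = 400L, sstart = 1L, send = 400L, evalue = evalue,
                 bitscore = 600)
}

test_that("e-value filtering is inclusive at the cutoff", {
  hits <- read_blast_tab(write_blast_fixture(dplyr::bind_rows(
    blast_row("t1", 1e-50), blast_row("t2", 0.001), blast_row("t3", 0.01)
  )))
  rec <- filter_blast(hits, max_evalue = 0.001)
  expect_equal(sort(rec$taxon), c("t1", "t2"))
  expect_true(all(rec$evidence == "blast"))
})

test_that("an empty BLAST file yields no records", {
  path <- tempfile(); file.create(path)
  rec <- filter_blast(read_blast_tab(path))
  expect_equal(nrow(rec), 0)
})

test_that("per-taxon deduplication keeps the best e-value", {
  hits <- read_blast_tab(write_blast_fixture(dplyr::bind_rows(
    blast_row("tax", 1e-5), blast_row("tax", 1e-20)
  )))
  rec <- filter_blast(hits)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$evalue, 1e-20)
})

test_that("malformed BLAST rows are rejected", {
  path <- tempfile(fileext = ".tsv")
  writeLines("only\ttwo", path)
  expect_error(read_blast_tab(path), class = "kynu_error_malformed_row")
})

candidate_fixture <- function() {
  dplyr::bind_rows(
    tibble::tibble(taxon = "Oral bug", gene = c("tdo", "kynU"),
                   evidence = "annotation", evalue = NA_real_, source_id = "ec"),
    tibble::tibble(taxon = "ido bug", gene = c("ido", "kynU"),
                   evidence = "annotation", evalue = NA_real_, source_id = "ec"),
    tibble::tibble(taxon = "envbug", gene = c("tdo", "ido", "kynU"),
                   evidence = "annotation", evalue = NA_real_, source_id = "ec"),
    tibble::tibble(taxon = "plainbug", gene = "tdo",
                   evidence = "annotation", evalue = NA_real_, source_id = "ec")
  )
}

test_that("the candidate rule needs oral + kynU + a pathway entry", {
  cand <- build_candidates(candidate_fixture(), c("oral bug", "ido bug", "plainbug"))
  flagged <- cand$taxon[cand$candidate_flag]
  # tdo+kynU oral -> candidate; ido+kynU oral -> candidate (IDO entry counts);
  # all genes but non-oral -> not; tdo only -> not
  expect_setequal(flagged, c("oral bug", "ido bug"))
  expect_false(cand$candidate_flag[cand$taxon == "envbug"])
  s <- attr(cand, "summary")
  expect_equal(s$n_taxa, 4)
  expect_equal(s$n_candidates, 2)
})

test_that("taxon names are normalized before matching", {
  rec <- tibble::tibble(taxon = "  Oral_Bug ", gene = c("tdo", "kynU"),
                        evidence = "annotation", evalue = NA_real_,
                        source_id = "ec")
  cand <- build_candidates(rec, "oral bug")
  expect_true(cand$candidate_flag)
})

test_that("adding records never removes a candidate (monotonicity)", {
  base <- candidate_fixture()
  oral <- c("oral bug", "ido bug")
  before <- build_candidates(base, oral)
  set.seed(12)
  extra <- tibble::tibble(
    taxon = sample(c("newbug", "oral bug", "ido bug"), 6, replace = TRUE),
    gene = sample(c("tdo", "ido", "kynU"), 6, replace = TRUE),
    evidence = "blast", evalue = 1e-10, source_id = "probe"
  )
  after <- build_candidates(dplyr::bind_rows(base, extra), oral)
  was <- before$taxon[before$candidate_flag]
  now <- after$taxon[after$candidate_flag]
  expect_true(all(was %in% now))
})

test_that("tdo counts partition the taxon set", {
  cand <- build_candidates(candidate_fixture(), "oral bug")
  expect_equal(sum(cand$has_tdo) + sum(!cand$has_tdo), nrow(cand))
})

test_that("candidate table and summary serialize", {
  cand <- build_candidates(candidate_fixture(), "oral bug")
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_candidates(cand, tsv, js)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(cand))
  expect_equal(jsonlite::fromJSON(js)$n_candidates,
               attr(cand, "summary")$n_candidates)
})
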