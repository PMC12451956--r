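test_that("a perfect line is fitted exactly", {
  curve <- fit_calibration(data.frame(conc = c(0, 1, 2), area = c(0, 10, 20)))
  expect_equal(curve$slope, 10)
  expect_equal(curve$intercept, 0, tolerance = 1e-12)
  expect_equal(curve$r_squared, 1)
})

test_that("the slope is recovered within 3% under 1% area noise (n = 6)", {
  set.seed(33)
  conc <- seq(2, 100, length.out = 6)
  truth_slope <- 850
  area <- (truth_slope * conc + 120) * (1 + rnorm(6, sd = 0.01))
  curve <- fit_calibration(data.frame(conc = conc, area = area))
  expect_equal(curve$slope, truth_slope, tolerance = 0.03)
})

test_that("degenerate standards are rejected and poor fits warned", {
  expect_error(fit_calibration(data.frame(conc = c(1, 2), area = c(1, 2))),
               class = "kynu_error_too_few_points")
  expect_error(fit_calibration(data.frame(conc = c(5, 5, 5), area = c(1, 2, 3))),
               class = "kynu_error_no_spread")
  set.seed(34)
  noisy <- data.frame(conc = 1:6, area = 1:6 + rnorm(6, sd = 2))
  expect_warning(fit_calibration(noisy), class = "kynu_warning_poor_calibration")
})

test_that("quantification inverts the curve and censors at the LOD", {
  curve <- fit_calibration(data.frame(conc = c(0, 5, 10), area = c(2, 52, 102)),
                           analyte = "KYN", lod = 0.1)
  q <- quantify(curve$slope * 5 + curve$intercept, curve)
  expect_equal(q$conc, 5)
  expect_false(q$censored)
  # a computed 0.05 uM with LOD 0.1 is censored at the LOD, never 0
  q2 <- quantify(curve$slope * 0.05 + curve$intercept, curve)
  expect_true(q2$censored)
  expect_equal(q2$conc, 0.1)
  # AA-style LOD of 0.001 behaves identically
  aa <- fit_calibration(data.frame(conc = c(0, 1, 2), area = c(0, 1000, 2000)),
                        analyte = "AA", lod = 0.001)
  q3 <- quantify(0.0005 * 1000, aa)
  expect_true(q3$censored)
  expect_equal(q3$conc, 0.001)
  expect_error(quantify(NaN, aa), class = "kynu_error_bad_area")
})

test_that("replicate summarization uses mean and n-1 SD", {
  s <- summarize_replicates(c(10, 20, 30))
  expect_equal(s$mean_uM, 20)
  expect_equal(s$sd_uM, 10)
  one <- summarize_replicates(42)
  expect_equal(one$mean_uM, 42)
  expect_true(is.na(one$sd_uM))
  expect_error(summarize_replicates(numeric()), class = "kynu_error_empty_input")
})

test_that("summarization is permutation-invariant and scales linearly", {
  set.seed(35)
  v <- runif(7, 1, 100)
  expect_equal(summarize_replicates(sample(v)), summarize_replicates(v))
  s1 <- summarize_replicates(v); s10 <- summarize_replicates(10 * v)
  expect_equal(s10$mean_uM, 10 * s1$mean_uM)
  expect_equal(s10$sd_uM, 10 * s1$sd_uM)
})

test_that("the quant pipeline recovers planted truth exactly at zero noise", {
  truth <- tidyr::expand_grid(
    sample = "candA", analyte = c("AA", "KYNA"),
    fraction = c("extracellular", "intracellular"), replicate = 1:3
  )
  set.seed(36)
  truth$conc <- round(runif(nrow(truth), 1, 50), 3)
  fx <- make_quant_fixture(tempfile(), truth,
                           lods = c(AA = 0.001, KYNA = 0.1), noise_pct = 0,
                           seed = 37)
  standards <- read_standards_csv(fx$standards_csv)
  samples <- read_samples_csv(fx$samples_csv)
  curves <- lapply(split(standards, standards$analyte), fit_calibration)
  curves <- purrr::imap(curves, function(c, an) { c$analyte <- an; c$lod <- fx$lods[[an]]; c })
  q <- quantify_samples(samples, curves)
  expected <- truth |>
    dplyr::group_by(analyte, replicate) |>
    dplyr::summarise(total = sum(conc), .groups = "drop") |>
    dplyr::group_by(analyte) |>
    dplyr::summarise(mean = mean(total), sd = sd(total))
  expect_equal(q$mean_uM, expected$mean, tolerance = 1e-6)
  expect_equal(q$sd_uM, expected$sd, tolerance = 1e-6)
  expect_equal(q$n_censored_fractions, c(0L, 0L))
})

test_that("sub-LOD fractions contribute zero to totals with censoring counted", {
  truth <- tibble::tibble(
    sample = "s", analyte = "AA",
    fraction = rep(c("extracellular", "intracellular"), 3),
    replicate = rep(1:3, each = 2),
    conc = c(10, 0.0002, 20, 0.0002, 30, 0.0002)  # intracellular below LOD
  )
  fx <- make_quant_fixture(tempfile(), truth, lods = c(AA = 0.001),
                           noise_pct = 0, seed = 38)
  standards <- read_standards_csv(fx$standards_csv)
  curve <- fit_calibration(standards, analyte = "AA", lod = 0.001)
  q <- quantify_samples(read_samples_csv(fx$samples_csv), list(AA = curve))
  expect_equal(q$mean_uM, 20, tolerance = 1e-4)
  expect_equal(q$sd_uM, 10, tolerance = 1e-4)
  expect_equal(q$n_censored_fractions, 3L)
  expect_false(q$all_censored)
})

test_that("an analyte below LOD everywhere is reported all-censored", {
  truth <- tidyr::expand_grid(sample = "s", analyte = "AA",
                              fraction = "extracellular", replicate = 1:3) |>
    dplyr::mutate(conc = 0.0001)
  fx <- make_quant_fixture(tempfile(), truth, lods = c(AA = 0.001),
                           noise_pct = 0, seed = 39)
  curve <- fit_calibration(read_standards_csv(fx$standards_csv),
                           analyte = "AA", lod = 0.001)
  q <- quantify_samples(read_samples_csv(fx$samples_csv), list(AA = curve))
  expect_true(q$all_censored)
  expect_equal(q$mean_uM, 0)
})

test_that("tidy/glance expose calibration internals", {
  curve <- fit_calibration(data.frame(conc = c(0, 1, 2), area = c(1, 11, 21)),
                           analyte = "KYN", lod = 0.1)
  td <- generics::tidy(curve)
  expect_equal(td$term, c("(Intercept)", "conc"))
  gl <- generics::glance(curve)
  expect_equal(gl$slope, 10)
  expect_equal(gl$analyte, "KYN")
})
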