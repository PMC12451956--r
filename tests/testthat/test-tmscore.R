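test_that("d0 follows the standard length scaling with its floor", {
  expect_equal(d0(153), 4.61, tolerance = 0.005)
  expect_equal(d0(15), 0.5)
  expect_equal(d0(3), 0.5)
  L <- 1:500
  expect_true(all(diff(d0(L)) >= 0))
  expect_gt(d0(400), d0(100))
})

test_that("tm_fixed evaluates its closed forms", {
  # identical coordinates, identity frame, L = n -> 1
  a <- matrix(rnorm(30), ncol = 3)
  expect_equal(tm_fixed(a, a, rigid_transform(), L = 10), 1.0)
  # one pair at exactly d0, L = 1 -> 0.5
  pa <- matrix(c(0, 0, 0), ncol = 3)
  pb <- matrix(c(d0(1), 0, 0), ncol = 3)
  expect_equal(tm_fixed(pa, pb, rigid_transform(), L = 1), 0.5)
  # and at L = 30 the same geometry contributes (1/L) * 1/(1 + d^2/d0(30)^2)
  pb30 <- matrix(c(d0(30), 0, 0), ncol = 3)
  expect_equal(tm_fixed(pa, pb30, rigid_transform(), L = 30), 0.5 / 30)
})

test_that("tm_fixed equals a direct hand summation on a 10-residue toy", {
  set.seed(13)
  a <- matrix(rnorm(30, sd = 3), ncol = 3)
  b <- a + matrix(rnorm(30, sd = 1), ncol = 3)
  tf <- rigid_transform(random_rotation(2), c(1, 0, -2))
  L <- 10
  bt <- kynuscreen:::apply_transform(b, tf)
  di <- sqrt(rowSums((a - bt)^2))
  expect_equal(tm_fixed(a, b, tf, L), sum(1 / (1 + di^2 / d0(L)^2)) / L,
               tolerance = 1e-12)
})

test_that("identical traces score TM = 1 and a rigid copy is invariant", {
  tr <- make_trace(synth_spec(n_residues = 60, seed = 41))
  res <- tm_optimize(tr, tr)
  expect_equal(res$tm, 1.0, tolerance = 1e-9)
  expect_equal(res$fold_call, "similar_fold")

  p <- perturb_trace(tr, noise_sigma = 0, seed = 42)
  res2 <- tm_optimize(tr, p$trace)
  expect_equal(res2$tm, 1.0, tolerance = 1e-6)
  expect_equal(res2$rmsd_kabsch, 0, tolerance = 1e-6)
})

test_that("the heuristic at least matches exhaustive fragment-seed search", {
  # 30-residue toys with 10 displaced residues
  tr <- make_trace(synth_spec(n_residues = 30, seed = 51))
  b <- tr
  set.seed(52)
  idx <- sample(30, 10)
  b$x[idx] <- b$x[idx] + rnorm(10, sd = 6)
  b$y[idx] <- b$y[idx] + rnorm(10, sd = 6)
  b <- suppressWarnings(kynuscreen:::new_trace(b, label = "displaced"))
  al <- global_align(trace_sequence(tr), trace_sequence(b))
  res <- tm_optimize(tr, b, al)

  # oracle: Kabsch seed from every contiguous fragment of every length >= 3,
  # no iteration, best tm_fixed
  ca <- trace_coords(tr); cb <- trace_coords(b)
  best <- 0
  for (fl in 3:30) {
    for (s in 1:(30 - fl + 1)) {
      i <- s:(s + fl - 1)
      tf <- suppressWarnings(kabsch(ca[i, , drop = FALSE], cb[i, , drop = FALSE]))
      best <- max(best, tm_fixed(ca, cb, tf, L = 30))
    }
  }
  expect_gte(res$tm, best - 1e-9)
})

test_that("tm_optimize never falls below the Kabsch-frame score", {
  set.seed(61)
  for (i in 1:5) {
    tr <- make_trace(synth_spec(n_residues = 40, noise_sigma = 0.2, seed = 60 + i))
    p <- perturb_trace(tr, noise_sigma = 1.5, seed = 70 + i)
    pc <- paired_coords(tr, p$trace)
    kb <- kabsch(pc$a, pc$b)
    res <- tm_optimize(tr, p$trace)
    expect_gte(res$tm, tm_fixed(pc$a, pc$b, kb, L = nrow(tr)) - 1e-12)
    expect_gt(res$tm, 0)
    expect_lte(res$tm, 1 + 1e-12)
  }
})

test_that("tm_optimize is invariant to rigid motion of an input", {
  tr <- make_trace(synth_spec(n_residues = 50, seed = 81))
  p <- perturb_trace(tr, noise_sigma = 0.8, seed = 82)
  base <- tm_optimize(tr, p$trace)$tm
  p2 <- perturb_trace(p$trace, noise_sigma = 0, seed = 83)  # extra rigid motion
  expect_equal(tm_optimize(tr, p2$trace)$tm, base, tolerance = 1e-6)
})

test_that("swapping the structures under shorter-normalization is symmetric", {
  a <- make_trace(synth_spec(n_residues = 45, seed = 91))
  b <- perturb_trace(a, noise_sigma = 1.0, seed = 92)$trace
  prm <- tm_params(normalization = "shorter")
  expect_equal(tm_optimize(a, b, params = prm)$tm,
               tm_optimize(b, a, params = prm)$tm, tolerance = 1e-6)
})

test_that("fold and RMSD calls use strict thresholds", {
  # printed comparison pairs map to their published calls
  expect_equal(classify_structure(0.99, 0.03),
               list(fold_call = "similar_fold", rmsd_call = "consistent"))
  expect_equal(classify_structure(0.78, 0.39),
               list(fold_call = "similar_fold", rmsd_call = "structural_difference"))
  expect_equal(classify_structure(0.32, 0.21),
               list(fold_call = "different_fold", rmsd_call = "consistent"))
  expect_equal(classify_structure(0.16, 0.35),
               list(fold_call = "different_fold", rmsd_call = "structural_difference"))
  # boundary values fall on the negative side ("above" is strict)
  expect_equal(classify_structure(0.5, 0.3),
               list(fold_call = "different_fold", rmsd_call = "consistent"))
  expect_equal(classify_structure(0.5 + 1e-9, 0.3 + 1e-9),
               list(fold_call = "similar_fold", rmsd_call = "structural_difference"))
})

test_that("helix vs decoy of matched length lands below the fold threshold", {
  helix <- make_trace(synth_spec(n_residues = 80, seed = 101))
  decoy <- make_trace(synth_spec(n_residues = 80, topology = "zigzag", seed = 102))
  res <- tm_optimize(helix, decoy, params = tm_params("shorter"))
  expect_lt(res$tm, 0.5)
  expect_equal(res$fold_call, "different_fold")
})

test_that("batch comparison tolerates a missing model", {
  d <- tempfile(); dir.create(d)
  a <- make_trace(synth_spec(n_residues = 30, seed = 111))
  b <- perturb_trace(a, noise_sigma = 0.3, seed = 112)$trace
  pa <- file.path(d, "a.pdb"); pb <- file.path(d, "b.pdb")
  write_trace_pdb(a, pa); write_trace_pdb(b, pb)
  pairs <- tibble::tibble(
    label_a = "a", path_a = pa,
    label_b = c("b", "ghost"), path_b = c(pb, file.path(d, "ghost.pdb"))
  )
  res <- compare_structures(pairs)
  expect_equal(res$status, c("ok", "not_applicable"))
  expect_gt(res$tm_ab[1], 0.5)
  expect_true(is.na(res$tm_ab[2]))
})
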