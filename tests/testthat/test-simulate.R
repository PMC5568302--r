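test_that("zero mutation rate gives identical ingroup and zero counts", {
  sim <- simulate_two_region_data(sim_sequence_params(
    theta_per_region = 0, divergence_time = 2, n_ingroup = 5,
    region_lengths = c(50L, 40L), seed = 3))
  for (r in 1:2) {
    aln <- sim$regions[[r]]$ingroup
    expect_true(all(apply(aln, 2L, function(col) length(unique(col)) == 1L)))
    rc <- region_counts(aln, sim$regions[[r]]$outgroup)
    expect_identical(rc$S, 0L)
    expect_identical(rc$D, 0)
  }
})

test_that("sequence simulation is deterministic under a fixed seed", {
  p <- sim_sequence_params(theta_per_region = 4, n_ingroup = 8,
                           region_lengths = c(300L, 200L), seed = 99)
  s1 <- simulate_two_region_data(p)
  s2 <- simulate_two_region_data(p)
  expect_identical(s1$regions, s2$regions)
})

test_that("mean segregating sites matches the Watterson expectation", {
  n <- 20; theta <- 5
  a_n <- sum(1 / (1:(n - 1)))
  reps <- 10000L
  S <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_two_region_data(sim_sequence_params(
      theta_per_region = theta, divergence_time = 0.5, n_ingroup = n,
      region_lengths = c(200L, 200L), seed = 7e6 + r))
    S[r] <- sim$truth$S_mut[1L]
  }
  se <- sd(S) / sqrt(reps)
  expect_lt(abs(mean(S) - theta * a_n), 3 * se)
})

test_that("divergence inflation scales mean divergence as (kT+1)/(T+1)", {
  T <- 2; theta <- 5; reps <- 1500L
  D <- matrix(NA_real_, reps, 2L)
  for (r in seq_len(reps)) {
    sim <- simulate_two_region_data(sim_sequence_params(
      theta_per_region = theta, divergence_time = T, n_ingroup = 10,
      region_lengths = c(400L, 400L), divergence_inflation = c(1, 5),
      seed = 8e6 + r))
    rc1 <- region_counts(sim$regions[[1L]]$ingroup, sim$regions[[1L]]$outgroup)
    rc2 <- region_counts(sim$regions[[2L]]$ingroup, sim$regions[[2L]]$outgroup)
    D[r, ] <- c(rc1$D, rc2$D)
  }
  ratio <- mean(D[, 2L]) / mean(D[, 1L])
  expect_lt(abs(ratio - (5 * T + 1) / (T + 1)), 0.2)
})

test_that("mutation overflow and invalid parameters fail loudly", {
  expect_error(simulate_two_region_data(sim_sequence_params(
    theta_per_region = 50, n_ingroup = 20, region_lengths = c(10L, 10L),
    seed = 1)), "mutations")
  expect_error(sim_sequence_params(n_ingroup = 1), "at least 2")
  expect_error(sim_sequence_params(region_lengths = c(0L, 10L)), "positive")
  expect_error(sim_sequence_params(divergence_inflation = 0), "positive")
})

test_that("coding-allele simulator plants exact amino-acid differences", {
  sim <- simulate_coding_alleles(n_groups = 2, n_haplotypes_per_group = 3,
                                 codon_count = 30, aa_diffs_between_groups = 3,
                                 syn_diffs_within_group = 0, seed = 5)
  prot <- vapply(rownames(sim$alignment), function(id) {
    translate_cds(paste0(sim$alignment[id, ], collapse = ""))
  }, character(1L))
  expect_false(any(grepl("\\*", prot)))
  p1 <- strsplit(prot[["g1_h1"]], "")[[1L]]
  p2 <- strsplit(prot[["g2_h1"]], "")[[1L]]
  expect_identical(sum(p1 != p2), 3L)
  # all members of a group translate identically
  expect_length(unique(prot[sim$truth$group == "G1"]), 1L)
  expect_length(unique(prot[sim$truth$group == "G2"]), 1L)
})

test_that("within-group synonymous variation keeps one protein per group", {
  sim <- simulate_coding_alleles(n_groups = 3, n_haplotypes_per_group = 4,
                                 codon_count = 40, aa_diffs_between_groups = 2,
                                 syn_diffs_within_group = 2, seed = 11)
  for (g in unique(sim$truth$group)) {
    ids <- sim$truth$id[sim$truth$group == g]
    sub <- sim$alignment[ids, , drop = FALSE]
    prot <- unique(vapply(ids, function(id) {
      translate_cds(paste0(sub[id, ], collapse = ""))
    }, character(1L)))
    expect_length(prot, 1L)
    # nucleotide diversity within the group is positive
    expect_gt(sum(apply(sub, 2L, function(col) length(unique(col)) > 1L)), 0L)
  }
  # degenerate case: one group, no synonymous variation -> identical rows
  mono <- simulate_coding_alleles(1, 4, 10, 0, 0, seed = 2)
  expect_identical(nrow(unique(mono$alignment)), 1L)
  expect_error(simulate_coding_alleles(5, 2, 4, 3, 0, seed = 1), "too small")
})

test_that("simulated spectra peak where the mixture says they should", {
  # pure A1, no noise: argmax exactly at lambda_max_a1 on the grid
  s0 <- simulate_spectrum(sim_spectrum_params(544, 595, a2_fraction = 0,
                                              noise_sd = 0, seed = 1))
  expect_identical(s0$wavelength[which.max(s0$absorbance)], 544L)
  # pure A2 at the rod-opsin A2 point: peak at 523 nm
  s1 <- simulate_spectrum(sim_spectrum_params(503, 523, a2_fraction = 1,
                                              noise_sd = 0, seed = 1))
  expect_identical(s1$wavelength[which.max(s1$absorbance)], 523L)
  # half mixture peaks strictly between the two pure peaks
  s5 <- simulate_spectrum(sim_spectrum_params(503, 523, a2_fraction = 0.5,
                                              noise_sd = 0, seed = 1))
  pk <- s5$wavelength[which.max(s5$absorbance)]
  expect_gt(pk, 503); expect_lt(pk, 523)
  # peak wavelength is monotone non-decreasing in the A2 fraction
  pks <- vapply(seq(0, 1, 0.1), function(phi) {
    s <- simulate_spectrum(sim_spectrum_params(544, 595, phi, 0, seed = 1))
    estimate_lambda_max(s)$lambda_max
  }, numeric(1L))
  expect_true(all(diff(pks) >= -1e-9))
  # determinism and validation
  a <- simulate_spectrum(sim_spectrum_params(544, 595, 0.3, 0.01, seed = 42))
  b <- simulate_spectrum(sim_spectrum_params(544, 595, 0.3, 0.01, seed = 42))
  expect_identical(a$absorbance, b$absorbance)
  expect_error(sim_spectrum_params(595, 544), "red-shifted")
  expect_error(sim_spectrum_params(544, 595, wavelength_grid = 560:600),
               "bracket")
  expect_error(sim_spectrum_params(544, 595, a2_fraction = 1.2), "0, 1")
})
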