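# Synthetic-data generator: profiles, datasets, peak grids, toy structures.

test_that("ground-truth profiles honour class ranges and seeding", {
  prof <- generate_profile(114, seed = 1)
  expect_equal(nrow(prof), 114)
  core <- prof$class_label == "core"
  expect_true(all(prof$s2[core] >= 0.75 & prof$s2[core] <= 0.9))
  term <- prof$class_label == "terminus"
  expect_true(all(prof$s2[term] >= 0.2 & prof$s2[term] <= 0.6))
  expect_true(all(prof$s2 >= 0 & prof$s2 <= 1))
  expect_true(all(prof$tau_e >= 0) && all(prof$rex >= 0))
  # rex fraction 15% up to rounding
  expect_equal(sum(prof$rex > 0), round(0.15 * 114))
  expect_true(all(prof$rex[prof$rex > 0] >= 1 & prof$rex[prof$rex > 0] <= 5))
  # seeded determinism
  expect_identical(generate_profile(5, seed = 7), generate_profile(5, seed = 7))
  expect_identical(generate_profile(114, seed = 3), generate_profile(114, seed = 3))
  expect_false(identical(generate_profile(114, seed = 3),
                         generate_profile(114, seed = 4)))
  expect_error(generate_profile(4), "n_residues")
})

test_that("noiseless datasets are exact forward models", {
  truth <- data.frame(residue_index = 1L, s2 = 1, tau_e = 0, rex = 0,
                      class_label = "core")
  sch <- acquisition_scheme(noise_sigma = 0)
  ds <- generate_dataset(truth, tau_m = 7.9, scheme = sch, seed = 1)
  fr <- forward_rates(1, 0, 0, 7.9)
  d <- ds$decays_r1[[1]]
  expect_equal(d$volumes, 100 * exp(-fr$r1 * d$delays), tolerance = 1e-12)
  expect_true(all(d$volumes > 0))
  # NOE pair ratio equals the forward-model NOE to machine precision
  expect_equal(ds$noe_pairs$saturated / ds$noe_pairs$unsaturated, fr$noe,
               tolerance = 1e-12)
  # r1rho decay on resonance decays at R2
  drho <- ds$decays_r1rho[[1]]
  expect_equal(drho$volumes, 100 * exp(-fr$r2 * drho$delays),
               tolerance = 1e-12)
  expect_error(generate_dataset(truth[0, ], tau_m = 7.9), "at least one")
})

test_that("dataset regeneration is bit-identical under a fixed seed", {
  prof <- generate_profile(10, seed = 2)
  a <- generate_dataset(prof, tau_m = 7.9, seed = 5)
  b <- generate_dataset(prof, tau_m = 7.9, seed = 5)
  expect_identical(a, b)
  # duplicate delays receive independent noise draws
  d <- a$decays_r1[[1]]
  dup <- d$delays == 0.01
  expect_equal(sum(dup), 2)
  expect_false(d$volumes[which(dup)[1]] == d$volumes[which(dup)[2]])
})

test_that("fitted rates recover truth within noise at 1% sigma", {
  prof <- generate_profile(100, seed = 11)
  ds <- generate_dataset(prof, tau_m = 7.9, seed = 12)
  fr <- forward_rates(prof$s2, prof$tau_e, prof$rex, 7.9)
  within3 <- vapply(seq_len(100), function(i) {
    f <- fit_exponential(ds$decays_r1[[i]], n_mc = 100, seed = i)
    abs(f$rate - fr$r1[i]) <= 3 * f$rate_error
  }, logical(1))
  expect_gte(mean(within3), 0.95)
})

test_that("peak grids are sums of Lorentzians with recoverable peaks", {
  g0 <- generate_peak_grid(data.frame(center_h = numeric(0),
                                      center_n = numeric(0),
                                      amplitude = numeric(0),
                                      lw_h = numeric(0), lw_n = numeric(0)),
                           c(-50, 50), c(-30, 30))
  expect_true(all(g0$values == 0))
  g1 <- generate_peak_grid(data.frame(center_h = 0, center_n = 0,
                                      amplitude = 7, lw_h = 20, lw_n = 12),
                           c(-60, 60), c(-40, 40), spacing = 0.5)
  expect_equal(max(g1$values), 7, tolerance = 1e-10)
  expect_error(generate_peak_grid(data.frame(center_h = 100, center_n = 0,
                                             amplitude = 1, lw_h = 5,
                                             lw_n = 5),
                                  c(-50, 50), c(-30, 30)),
               "outside")
  # two peaks 100 Hz apart barely perturb each other's crest integral
  two <- generate_peak_grid(data.frame(center_h = c(-50, 50),
                                       center_n = c(0, 0),
                                       amplitude = c(5, 5),
                                       lw_h = c(14, 14), lw_n = c(10, 10)),
                            c(-120, 120), c(-40, 40), spacing = 0.5)
  one <- generate_peak_grid(data.frame(center_h = -50, center_n = 0,
                                       amplitude = 5, lw_h = 14, lw_n = 10),
                            c(-120, 120), c(-40, 40), spacing = 0.5)
  i_two <- integrate_ellipse(two, c(-50, 0))
  i_one <- integrate_ellipse(one, c(-50, 0))
  expect_lt(abs(i_two - i_one) / i_one, 0.01)
})

test_that("toy structures have canonical backbone geometry", {
  helix <- generate_toy_structure(strrep("A", 10), "helix")
  ca <- as.matrix(helix[helix$elety == "CA", c("x", "y", "z")])
  rise <- abs(mean(diff(stats::prcomp(ca)$x[, 1])))
  expect_equal(rise, 1.5, tolerance = 0.1)
  ext <- generate_toy_structure("AAAA", "extended")
  cae <- as.matrix(ext[ext$elety == "CA", c("x", "y", "z")])
  d12 <- sqrt(sum((cae[2, ] - cae[1, ])^2))
  expect_equal(d12, 3.8, tolerance = 0.05)
  expect_setequal(unique(helix$elety), c("N", "H", "CA", "C", "O"))
  expect_equal(sort(unique(helix$resno)), 1:10)
  expect_error(generate_toy_structure("AX", "helix"), "unknown")
  expect_error(generate_toy_structure("AAA", "helix"), ">= 4")
})

test_that("synthetic bundle is compact with per-residue heavy-atom counts", {
  bun <- synthetic_bundle_structure()
  expect_identical(synthetic_bundle_structure(), bun)   # seeded
  m <- structure_model(bun)
  heavy <- m[toupper(m$elem) != "H", ]
  # heavy atoms per residue = 4 backbone + side-chain table
  seq1 <- strsplit(synthetic_2s_sequence(), "")[[1]]
  counts <- table(factor(heavy$resno, levels = 1:114))
  expected <- 4 + unname(relaxkit:::SIDECHAIN_HEAVY[seq1])
  expect_equal(as.integer(counts), expected)
  spans <- apply(m[, c("x", "y", "z")], 2, function(v) diff(range(v)))
  expect_true(all(spans < 60))   # compact, globular-scale extents
})
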