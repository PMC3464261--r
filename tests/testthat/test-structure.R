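# Structure annotation: restraint taxonomy, pepsin mapping, solvent
# accessibility, hydrodynamics, stoichiometry, PDB round trip.

test_that("restraint classification partitions by sequence separation", {
  r <- data.frame(residue_i = c(5, 5, 5, 5), residue_j = c(5, 6, 8, 20))
  cls <- classify_restraints(r)
  expect_equal(as.integer(cls), c(1L, 1L, 1L, 1L))
  empty <- classify_restraints(data.frame(residue_i = integer(0),
                                          residue_j = integer(0)))
  expect_equal(sum(empty), 0L)
  # exhaustive and disjoint on random lists
  set.seed(8)
  for (k in 1:5) {
    n <- sample(50:300, 1)
    rr <- data.frame(residue_i = sample(1:114, n, replace = TRUE),
                     residue_j = sample(1:114, n, replace = TRUE))
    expect_equal(sum(classify_restraints(rr)), n)
  }
  # a generated list with the published category counts sums to 1038
  gen <- generate_restraints(c(intra = 606, sequential = 329, short = 92,
                               long = 11), seed = 2)
  cls2 <- classify_restraints(gen)
  expect_equal(as.integer(cls2), c(606L, 329L, 92L, 11L))
  expect_equal(sum(cls2), 1038L)
})

test_that("pepsin sites reproduce the captured rule-engine oracle", {
  path <- system.file("extdata", "pepsin_oracle_sites.tsv",
                      package = "relaxkit")
  fx <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", fill = TRUE)
  for (i in seq_len(nrow(fx))) {
    want <- if (is.na(fx$sites[i]) || fx$sites[i] == "") integer(0)
            else as.integer(strsplit(fx$sites[i], ",")[[1]])
    got <- pepsin_sites(fx$sequence[i], fx$rule_set[i])$sites
    expect_equal(as.integer(got), want,
                 info = paste(fx$name[i], fx$rule_set[i]))
  }
  expect_error(pepsin_sites("AAZA"), "unknown")
  # sites always fall strictly inside the chain
  s <- pepsin_sites(synthetic_2s_sequence(), "pepsin_pH>2")
  expect_true(all(s$sites >= 1 & s$sites < nchar(s$sequence)))
})

test_that("solvent accessibility matches closed-form sphere geometry", {
  one <- protein_structure(data.frame(model = 1, chain = "A", resno = 1,
                                      resid = "ALA", elety = "CA",
                                      elem = "C", x = 0, y = 0, z = 0))
  a1 <- shrake_rupley_sasa(one, probe = 1.4, n_points = 960)
  expect_equal(a1$area, 4 * pi * 3.1^2, tolerance = 0.02 * 4 * pi * 3.1^2)
  # two identical spheres: analytic two-cap formula
  for (d in c(2.0, 3.5, 5.0)) {
    two <- protein_structure(data.frame(model = 1, chain = "A",
                                        resno = 1:2, resid = "ALA",
                                        elety = "CA", elem = "C",
                                        x = c(0, d), y = 0, z = 0))
    at <- shrake_rupley_sasa(two, probe = 1.4, n_points = 960)
    want <- oracle_two_sphere_area(3.1, d)
    expect_equal(at$area[1], want, tolerance = 0.02 * want)
    expect_equal(at$area[2], want, tolerance = 0.02 * want)
  }
  # an atom enclosed by a tight shell has zero accessible area
  shell <- relaxkit:::fibonacci_sphere(60) * 2.5
  enc <- protein_structure(data.frame(model = 1, chain = "A",
                                      resno = seq_len(61), resid = "ALA",
                                      elety = "CA", elem = "C",
                                      x = c(0, shell[, 1]),
                                      y = c(0, shell[, 2]),
                                      z = c(0, shell[, 3])))
  expect_equal(shrake_rupley_sasa(enc, n_points = 480)$area[1], 0)
  # unknown elements warn and fall back
  odd <- protein_structure(data.frame(model = 1, chain = "A", resno = 1,
                                      resid = "ALA", elety = "XX",
                                      elem = "Q", x = 0, y = 0, z = 0))
  expect_warning(shrake_rupley_sasa(odd), "default radius")
})

test_that("total accessible area drops when molecules come into contact", {
  a <- generate_toy_structure("AAAAA", "extended")
  b <- relaxkit:::transform_structure(a, diag(3), c(0, 50, 0))
  b$resno <- b$resno + 5L
  apart <- rbind(as.data.frame(a), as.data.frame(b))
  b2 <- relaxkit:::transform_structure(a, diag(3), c(0, 4.5, 0))
  b2$resno <- b2$resno + 5L
  close_ <- rbind(as.data.frame(a), as.data.frame(b2))
  s_apart <- sum(shrake_rupley_sasa(protein_structure(apart),
                                    n_points = 480)$area)
  s_close <- sum(shrake_rupley_sasa(protein_structure(close_),
                                    n_points = 480)$area)
  expect_lt(s_close, s_apart)
})

test_that("exposed-site filtering follows the accessibility threshold", {
  seqc <- "GGFLGGGGGGFLGG"
  chain <- generate_toy_structure(seqc, "extended")
  cmap <- pepsin_sites(seqc)
  expect_gt(length(cmap$sites), 0)
  sasa <- shrake_rupley_sasa(chain, include_h = TRUE)
  all_sites <- exposed_cleavage_sites(chain, cmap, 0, sasa = sasa)
  expect_equal(as.integer(all_sites), cmap$sites)
  none <- exposed_cleavage_sites(chain, cmap, Inf, sasa = sasa)
  expect_length(none, 0)
  expect_error(exposed_cleavage_sites(generate_toy_structure("AAAA",
                                                             "helix"),
                                      cmap, 0), "match")
})

test_that("bead diffusion reproduces closed-form and scaling limits", {
  kB <- 1.380649e-23; eta <- 0.797e-3; a <- 3.4e-10
  one <- bead_diffusion(matrix(0, 1, 3), bead_radius = 3.4)
  d0 <- kB * 303 / (8 * pi * eta * a^3)
  expect_equal(one$eigenvalues, rep(d0, 3), tolerance = 1e-6 * d0)
  expect_equal(one$delta, 1, tolerance = 1e-9)
  # symmetric dumbbell: analytic pair solution of the same mobility law
  L <- 10e-10
  dumb <- bead_diffusion(rbind(c(0, 0, 5), c(0, 0, -5)), bead_radius = 3.4)
  d_axis <- kB * 303 / (2 * 8 * pi * eta * a^3)
  mu_s <- 1 / (6 * pi * eta * a)
  mu_perp <- 1 / (8 * pi * eta * L) * (1 + 2 * a^2 / (3 * L^2))
  d_perp <- kB * 303 / (2 * (L / 2)^2 / (mu_s - mu_perp) +
                          2 * 8 * pi * eta * a^3)
  expect_equal(dumb$eigenvalues[3], d_axis, tolerance = 0.05 * d_axis)
  expect_equal(dumb$eigenvalues[1], d_perp, tolerance = 0.05 * d_perp)
  # doubling all lengths scales tau_m by 8
  dumb2 <- bead_diffusion(rbind(c(0, 0, 10), c(0, 0, -10)),
                          bead_radius = 6.8)
  expect_equal(dumb2$tau_m_iso / dumb$tau_m_iso, 8, tolerance = 1e-6)
})

test_that("diffusion tensors are rotation-invariant with delta >= 1", {
  set.seed(12)
  cloud <- matrix(rnorm(3 * 25, sd = 8), 25, 3)
  bd <- bead_diffusion(cloud, bead_radius = 3.4)
  th <- 0.6
  R <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  bd2 <- bead_diffusion(cloud %*% R, bead_radius = 3.4)
  expect_equal(bd2$eigenvalues, bd$eigenvalues,
               tolerance = 1e-8 * mean(bd$eigenvalues))
  expect_gte(bd$delta, 1)
  expect_true(all(diff(bd$eigenvalues) >= 0))
})

test_that("stoichiometry arithmetic reproduces the printed ratios", {
  ctrl <- stoichiometry_ratio(28.0, 21.0)
  expect_equal(ctrl$ratio, 4 / 3, tolerance = 1e-12)
  expect_equal(ctrl$label, "4:3")
  trace <- stoichiometry_ratio(116, 1.78)
  expect_equal(trace$ratio, 65.1685, tolerance = 1e-4)
  expect_equal(trace$label, "65:1")
  expect_equal(stoichiometry_ratio(10, 10)$label, "1:1")
  expect_equal(stoichiometry_ratio(1, 2)$label, "1:2")
  expect_error(stoichiometry_ratio(0, 1), "> 0")
})

test_that("PDB writing and reading round-trip a structure with a metal", {
  helix <- generate_toy_structure(strrep("A", 8), "helix")
  cm <- locate_center(helix, data.frame(resno = c(3, 5)))
  tmp <- tempfile(fileext = ".pdb")
  write_structure_pdb(helix, tmp, center = cm)
  back <- read_structure_pdb(tmp)
  expect_true("CU" %in% back$resid)
  cu <- back[back$resid == "CU", ]
  expect_equal(c(cu$x, cu$y, cu$z), cm$position, tolerance = 1e-3)
  prot <- back[back$resid != "CU", ]
  expect_equal(nrow(prot), nrow(helix))
  expect_equal(structure_sequence(prot), strrep("A", 8))
  ord <- order(prot$resno, prot$elety)
  ord0 <- order(helix$resno, helix$elety)
  expect_equal(prot$x[ord], helix$x[ord0], tolerance = 1e-3)
})
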