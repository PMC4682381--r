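# Solvation free-energy gain and the pairwise-potential binding energy,
# including the interface-sum vs thermodynamic-cycle identity.

test_that("a contact-free dimer scores zero solvation gain", {
  b <- build_dimer(dimer_spec(n_residues = 8, n_interface = 0, seed = 4))
  acc <- suppressWarnings(detect_interface(b$complex))
  expect_equal(delta_iG(b$complex, acc), 0)
})

test_that("an all-carbon interface matches the hand formula", {
  # nonpolar stubs bury carbon only: gain = -sigma_C x buried area
  b <- build_dimer(dimer_spec(n_residues = 16, n_interface = 6,
                              interface_polar_frac = 0, seed = 13))
  acc <- detect_interface(b$complex)
  at <- attr(acc, "atom_table")
  buried <- sum(at$delta_asa)
  expect_equal(delta_iG(b$complex, acc),
               solvation_params()[["C"]] * (-buried), tolerance = 1e-9)
  expect_lt(delta_iG(b$complex, acc), 0)
})

test_that("polar interfaces gain less than nonpolar per buried area", {
  np <- build_dimer(dimer_spec(n_residues = 16, n_interface = 6,
                               interface_polar_frac = 0, seed = 13))
  pol <- build_dimer(dimer_spec(n_residues = 16, n_interface = 6,
                                interface_polar_frac = 1,
                                charged_frac = 0.5, n_salt_bridges = 3,
                                n_hbonds = 3, seed = 13))
  g <- function(b) {
    acc <- detect_interface(b$complex)
    delta_iG(b$complex, acc) / interface_area(acc)
  }
  expect_gt(g(pol), g(np))
})

test_that("training is deterministic and penalises depletion correctly", {
  cxs <- lapply(fixture_dimers()[1:4], `[[`, "complex")
  p1 <- suppressWarnings(train_potential(cxs))
  p2 <- suppressWarnings(train_potential(cxs))
  expect_identical(p1$u, p2$u)
  expect_error(train_potential(list()), "empty")
})

test_that("a single over-observed short distance gives negative energy", {
  # close observations of the CA-CA pair type sit in one short bin; a
  # matching set of far pairs populates the anchor bin
  n <- 10
  base_x <- 40 * (seq_len(n) - 1)
  df <- data.frame(chain = c(rep("A", n), rep("B", 2 * n)),
                   resno = c(1:n, 1:(2 * n)), resid = "GLY",
                   elety = "CA",
                   x = c(base_x, base_x + 2.2, base_x + 9.9),
                   y = 0, z = 0)
  cx <- assign_radii(read_complex(make_pdb(df), "A", "B"))
  pot <- train_potential(list(cx), alpha = 1.61)
  bin_short <- floor(2.2 / 0.5) + 1
  expect_lt(pot$u["CA_bb|CA_bb", bin_short], 0)
})

test_that("a uniform ideal gas trains to a near-zero potential", {
  set.seed(17)
  n <- 1200
  df <- data.frame(chain = rep(c("A", "B"), each = n / 2),
                   resno = 1:n, resid = "GLY", elety = "CA",
                   x = runif(n, 0, 80), y = runif(n, 0, 80),
                   z = runif(n, 0, 80))
  df$insert <- ""; df$alt <- ""; df$o <- 1; df$elesy <- "C"
  df$is_h <- FALSE; df$is_standard <- TRUE
  rt <- ppi_radius_table()
  df$radius <- rt$by_class[["C_aliphatic"]]
  cx <- structure(list(complex_id = "gas", chain_a = "A", chain_b = "B",
                       atoms = df), class = "ppi_complex")
  # alpha = 2 is the exact exponent for a uniform gas
  pot <- train_potential(list(cx), alpha = 2, eta = 0.01)
  # skip the sparsely populated first bins where counting noise dominates
  u <- pot$u["CA_bb|CA_bb", 6:20]
  expect_lt(max(abs(u)), 0.005)
  # the default finite-size exponent stays close to zero as well
  pot2 <- train_potential(list(cx), alpha = 1.61, eta = 0.01)
  expect_lt(max(abs(pot2$u["CA_bb|CA_bb", 6:20])), 0.01)
})

test_that("interface sum equals the thermodynamic-cycle brute force", {
  pot <- fixture_potential()
  for (d in fixture_dimers()) {
    cx <- d$complex
    at <- heavy_atoms(cx)
    ia <- at$chain == cx$chain_a
    eq2 <- structure_energy(at, pot) -
      (structure_energy(at[ia, , drop = FALSE], pot) +
         structure_energy(at[!ia, , drop = FALSE], pot))
    eq3 <- score_binding_energy(cx, pot)$binding_energy
    expect_equal(eq3, eq2, tolerance = 1e-9)
  }
})

test_that("chains separated beyond the cutoff score exactly zero", {
  b <- build_dimer(dimer_spec(n_residues = 8, n_interface = 0, seed = 4))
  r <- score_binding_energy(b$complex, fixture_potential())
  expect_equal(r$binding_energy, 0)
  expect_equal(r$n_pairs, 0L)
})

test_that("a single cross-chain pair scores its table entry", {
  df <- data.frame(chain = c("A", "B"), resno = 1, resid = "GLY",
                   elety = "CA", x = c(0, 3.2), y = 0, z = 0)
  cx <- assign_radii(read_complex(make_pdb(df), "A", "B"))
  pot <- fixture_potential()
  got <- score_binding_energy(cx, pot)
  # independent lookup straight from the shipped TSV
  tsv <- read.delim(system.file("extdata", "default_potential.tsv",
                                package = "ppiface"))
  expected <- tsv$u[tsv$type_i == "CA_bb" & tsv$type_j == "CA_bb" &
                      tsv$bin_low == 3.0]
  expect_equal(got$binding_energy, expected, tolerance = 1e-12)
  expect_equal(got$n_pairs, 1L)
})

test_that("binding energy is pose-dependent but frame-invariant", {
  # a binned potential is discontinuous at bin edges, so frame invariance
  # is checked on a dimer whose planted distances avoid exact edges
  cx <- build_dimer(dimer_spec(n_residues = 18, n_interface = 7,
                               charged_frac = 0.3, n_hbonds = 2,
                               n_salt_bridges = 2,
                               saltbridge_distance = 3.45,
                               contact_gap = 4.7, seed = 19))$complex
  pot <- fixture_potential()
  base <- score_binding_energy(cx, pot)$binding_energy
  moved <- transform_complex(cx, rotation_matrix(c(1, 0, 2), 0.9),
                             c(-4, 7, 2))
  expect_equal(score_binding_energy(moved, pot)$binding_energy, base,
               tolerance = 1e-9)
  # pull chain B away: energy decays to zero beyond the cutoff
  prev <- abs(base)
  for (dz in c(5, 10, 30)) {
    shifted <- cx
    sel <- shifted$atoms$chain == "B"
    shifted$atoms$z[sel] <- shifted$atoms$z[sel] + dz
    e <- abs(score_binding_energy(shifted, pot)$binding_energy)
    expect_lte(e, prev + 1e-12)
    prev <- e
  }
  expect_equal(prev, 0)
})

test_that("potential tables round-trip through TSV", {
  pot <- fixture_potential()
  path <- tempfile(fileext = ".tsv")
  write_potential(pot, path)
  back <- read_potential(path)
  expect_equal(back$bin_width, pot$bin_width)
  expect_equal(back$r_cut, pot$r_cut)
  expect_equal(back$u[rownames(pot$u), ], pot$u, tolerance = 1e-12)
})
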