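# independent recomputation of the Kabsch-Sander four-term energy
ks_energy_oracle <- function(n, h, c, o) {
  d <- function(p, q) sqrt(sum((p - q)^2))
  0.084 * 332 * (1 / d(o, n) + 1 / d(c, h) - 1 / d(o, h) - 1 / d(c, n))
}

test_that("amide hydrogens follow the DSSP placement convention", {
  mono <- make_hairpin_monomer()
  with_h <- place_amide_hydrogens(mono)
  expect_true(all(is.na(with_h$h[1, ])))          # first residue: no H
  for (i in 2:length(mono)) {
    co <- mono$c[i - 1, ] - mono$o[i - 1, ]
    expected <- mono$n[i, ] + co / sqrt(sum(co^2))
    expect_equal(with_h$h[i, ], expected, tolerance = 1e-10)
    expect_equal(sqrt(sum((with_h$h[i, ] - mono$n[i, ])^2)), 1,
                 tolerance = 1e-10)
  }
  # prolines carry no amide hydrogen
  pro <- make_hairpin_monomer(sequence = replace(rep("ALA", 13), 5, "PRO"))
  expect_true(all(is.na(place_amide_hydrogens(pro)$h[5, ])))

  single <- peptide_chain("A", 1, "ALA", rbind(c(0, 0, 0)),
                          n = rbind(c(-1.2, 0, 0.8)),
                          c = rbind(c(1.2, 0, 0.9)),
                          o = rbind(c(1.2, 0, 2.1)))
  expect_true(all(is.na(place_amide_hydrogens(single)$h)))
})

test_that("hydrogen-bond energies match an independent recomputation", {
  # canonical linear N-H...O=C geometry at 2 A: a clear bond
  donor <- list(n = c(0, 0, 0), h = c(0, 0, 1))
  acceptor <- list(c = c(0, 0, 4.23), o = c(0, 0, 3))
  e <- hbond_energy(donor, acceptor)
  expect_lt(e, -0.5)
  expect_equal(e, ks_energy_oracle(donor$n, donor$h, acceptor$c, acceptor$o),
               tolerance = 1e-10)

  # donor and acceptor 20 A apart: negligible energy, no bond
  far <- list(c = c(0, 0, 21.23), o = c(0, 0, 20))
  expect_lt(abs(hbond_energy(donor, far)), 0.1)

  # whole-model energies equal the oracle pair by pair
  fib <- make_fibril(n_chains = 2, rise = 4.625, twist = 0,
                     noise_sigma = 0.15, seed = 1601)
  tab <- hbond_table(fib)
  expect_gt(nrow(tab), 0)
  chains <- lapply(fib$chains, place_amide_hydrogens)
  for (r in seq_len(nrow(tab))) {
    don <- chains[[tab$donor_chain[r]]]
    acc <- chains[[tab$acceptor_chain[r]]]
    i <- tab$donor_res[r]; j <- tab$acceptor_res[r]
    expect_equal(tab$energy[r],
                 ks_energy_oracle(don$n[i, ], don$h[i, ],
                                  acc$c[j, ], acc$o[j, ]),
                 tolerance = 1e-8)
  }
})

test_that("overlapping atoms clamp to the DSSP minimum energy", {
  donor <- list(n = c(0, 0, 0), h = c(0, 0, 1))
  acceptor <- list(c = c(0, 0, 1.02), o = c(0, 0, 0.05))
  expect_warning(e <- hbond_energy(donor, acceptor), "clamped")
  expect_equal(e, -9.9)
})

test_that("stacked monomers form parallel beta sheet; lone chains score zero", {
  pair <- make_fibril(n_chains = 2, rise = 4.625, twist = 0)
  b <- beta_fraction(pair)
  expect_gt(b$fraction, 50)
  states <- do.call(rbind, b$states)
  expect_true(all(states[, 4:6] == "E"))        # interior arm residues
  expect_true(all(states[, 1] == "-"))          # chain ends stay coil

  # an isolated chain has no partners: 0%
  single <- fibril_model(list(make_hairpin_monomer()))
  b1 <- beta_fraction(single)
  expect_equal(b1$fraction, 0)
  expect_equal(b1$count, 0)
})

test_that("beta count and percentage are mutually consistent", {
  fib <- make_fibril(n_chains = 6, rise = 4.625, twist = 3,
                     noise_sigma = 0.1, seed = 1611)
  b <- beta_fraction(fib)
  expect_lt(abs(b$count - b$fraction / 100 * b$total_residues), 0.05)
  expect_equal(b$total_residues, 6 * 13)
  # excluding isolated bridges can only reduce the count
  b_e <- beta_fraction(fib, include_isolated_bridges = FALSE)
  expect_lte(b_e$count, b$count)
})

test_that("H-bond assignment is invariant under global rigid motion", {
  fib <- make_fibril(n_chains = 3, rise = 4.625, twist = 0,
                     noise_sigma = 0.1, seed = 1621)
  moved <- transform_model(fib, random_rigid(1622))
  t1 <- hbond_table(fib)
  t2 <- hbond_table(moved)
  expect_equal(t1[, 1:4], t2[, 1:4], ignore_attr = TRUE)
  expect_equal(t1$energy, t2$energy, tolerance = 1e-8)
  expect_equal(beta_fraction(moved)$fraction, beta_fraction(fib)$fraction)
})

test_that("widening the inter-strand spacing destroys the H-bond network", {
  counts <- vapply(c(4.7, 5.5, 6.5, 8, 12), function(rise)
    nrow(hbond_table(make_fibril(n_chains = 2, rise = rise, twist = 0))),
    0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0L)
  far <- make_fibril(n_chains = 2, rise = 12, twist = 0)
  expect_equal(beta_fraction(far)$fraction, 0)
})

test_that("Calpha-only models are refused for beta scoring", {
  ca_only <- fibril_model(lapply(1:2, function(t) {
    src <- make_fibril(n_chains = 2, rise = 4.7, twist = 0)$chains[[t]]
    peptide_chain(src$chain_id, src$resno, src$resid, src$ca)
  }))
  expect_error(beta_fraction(ca_only), "backbone required")
})

test_that("amide-I extinction correction recovers structure fractions", {
  # dominant beta component at twice the turn extinction
  corr <- band_correction(c(0.74, 0.26), c(2, 1), c("beta", "turns"))
  expect_equal(unname(corr["beta"]), 0.37 / 0.63, tolerance = 1e-10)
  expect_equal(round(100 * corr[["beta"]]), 59)
  expect_equal(sum(corr), 1)

  # equal weights: correction is the identity
  expect_equal(unname(band_correction(c(0.3, 0.5, 0.2), c(1, 1, 1))),
               c(0.3, 0.5, 0.2))
  expect_equal(unname(band_correction(c(0.5, 0.5), c(2, 1))),
               c(1 / 3, 2 / 3), tolerance = 1e-10)

  expect_error(band_correction(c(0.7, 0.3), c(0, 1)), "> 0")
  expect_error(band_correction(c(0.7, 0.7), c(1, 1)), "sum to 1")
  expect_error(band_correction(c(0.7), c(1, 1)), "length")
})
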