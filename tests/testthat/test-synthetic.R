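test_that("hairpin monomer has the requested arm layout and geometry", {
  mono <- make_hairpin_monomer(13, c(8, 9))
  expect_equal(length(mono), 13)
  # arms of 7 and 4 extended residues around the two-residue turn
  arm1 <- mono$ca[1:7, ]
  arm2 <- mono$ca[10:13, ]
  expect_true(all(abs(diff(arm1[, 1]) - 3.788) < 1e-9))   # +x strand
  expect_true(all(abs(diff(arm2[, 1]) + 3.788) < 1e-9))   # -x strand
  # consecutive CA distances all in the extended-chain range
  d <- sqrt(rowSums(diff(mono$ca)^2))
  expect_true(all(d > 3.7 & d < 3.9))
  # default sequence carries the expected landmarks
  expect_equal(mono$resid[c(3, 6, 8, 9, 11)],
               c("VAL", "CYS", "ALA", "SER", "CYS"))
})

test_that("backbone bond geometry sits on canonical values", {
  mono <- make_hairpin_monomer()
  expect_true(validate_backbone(mono))
  # independent recomputation of the per-residue bond lengths
  d_can <- c(ca_n = 1.46, ca_c = 1.52, c_o = 1.23)
  for (i in seq_len(length(mono))) {
    expect_lt(abs(sqrt(sum((mono$ca[i, ] - mono$n[i, ])^2)) - d_can["ca_n"]),
              0.05 * d_can["ca_n"])
    expect_lt(abs(sqrt(sum((mono$ca[i, ] - mono$c[i, ])^2)) - d_can["ca_c"]),
              0.05 * d_can["ca_c"])
    expect_lt(abs(sqrt(sum((mono$c[i, ] - mono$o[i, ])^2)) - d_can["c_o"]),
              0.05 * d_can["c_o"])
  }
  # peptide C(i)-N(i+1) bond plausible along the strand arms
  for (i in c(1:6, 10:12)) {
    pep <- sqrt(sum((mono$c[i, ] - mono$n[i + 1, ])^2))
    expect_gt(pep, 1.2); expect_lt(pep, 1.5)
  }
})

test_that("hairpin construction validates its arguments", {
  expect_error(make_hairpin_monomer(4), "at least 5")
  expect_error(make_hairpin_monomer(13, c(1, 2)), "interior")
  expect_error(make_hairpin_monomer(13, c(12, 13)), "interior")
  expect_error(make_hairpin_monomer(13, c(6, 8)), "consecutive")
  expect_error(make_hairpin_monomer(13, c(8, 9), sequence = "ALA"),
               "length")
  # non-default lengths fall back to poly-alanine
  expect_equal(unique(make_hairpin_monomer(9, c(5, 6))$resid), "ALA")
})

test_that("noiseless fibrils satisfy the generator ground truth exactly", {
  fib <- make_fibril(n_chains = 30, rise = 4.625, twist = 9)
  expect_equal(fibril_length(fib), 29 * 4.625, tolerance = 1e-8)
  expect_equal(interface_angles(fib)$angles, rep(9, 29), tolerance = 1e-8)
  expect_lt(pca_rmsd(fib)$pcaRMSD, 1e-8)
  g <- fibril_geometry(fib, convention = "n-1")
  expect_equal(g$rise_per_chain, 4.625, tolerance = 1e-8)
})

test_that("fixed seeds give byte-identical PDB output; noise needs a seed", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_model(make_fibril(n_chains = 5, noise_sigma = 0.3, seed = 42), f1)
  write_model(make_fibril(n_chains = 5, noise_sigma = 0.3, seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))

  a <- make_fibril(n_chains = 5, noise_sigma = 0.3, seed = 42)
  b <- make_fibril(n_chains = 5, noise_sigma = 0.3, seed = 43)
  expect_gt(max(abs(ca_coords(a) - ca_coords(b))), 0)
  expect_gt(pca_rmsd(a)$pcaRMSD, 0)
})

test_that("generator rejects invalid parameters and handles n = 1", {
  expect_error(make_fibril(n_chains = 0), "n_chains")
  expect_error(make_fibril(rise = 0), "rise")
  expect_error(make_fibril(noise_sigma = -1), "noise_sigma")
  one <- make_fibril(n_chains = 1)
  expect_equal(n_chains(one), 1)
  expect_error(fibril_length(one), "2 chains")
  expect_error(fibril_geometry(one), "2 chains")
})

test_that("restraint tables have the forced count structure", {
  tab <- cabsdock_restraints(13, 5, pair_distance = 5, weight = 1)
  expect_equal(nrow(tab), 13 * 4)
  expect_true(all(tab$distance == 5))
  expect_true(all(tab$weight == 1))
  expect_true(all(tab$atom == "SC"))
  # adjacent chain pairing only
  expect_true(all(match(tab$chain_j, LETTERS) -
                  match(tab$chain_i, LETTERS) == 1))

  with_ss <- cabsdock_restraints(13, 5, ssbond = c(6, 11, 6.5))
  expect_equal(nrow(with_ss), 13 * 4 + 5)
  ss <- with_ss[with_ss$atom == "CA", ]
  expect_equal(nrow(ss), 5)
  expect_true(all(ss$residue_i == 6 & ss$residue_j == 11))
  expect_true(all(ss$distance == 6.5))
  expect_true(all(ss$chain_i == ss$chain_j))

  expect_equal(nrow(cabsdock_restraints(1, 2)), 1)
  expect_error(cabsdock_restraints(13, 5, ssbond = c(6, 14, 6.5)),
               "out of range")
  expect_error(cabsdock_restraints(0, 5), "n_residues")
  expect_error(cabsdock_restraints(13, 1), "n_chains")
})

test_that("restraint count formula holds across a parameter sweep", {
  for (nres in c(1, 5, 13))
    for (nch in c(2, 5, 9))
      expect_equal(nrow(cabsdock_restraints(nres, nch)), nres * (nch - 1))
})

test_that("restraint files are plain six-column text with a header", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(cabsdock_restraints(3, 3, ssbond = c(1, 3, 6.5)), f)
  lines <- readLines(f)
  expect_true(all(startsWith(lines[1:4], "#")))
  body <- strsplit(lines[-(1:4)], "\t")
  expect_true(all(lengths(body) == 7))
  expect_equal(length(body), 3 * 2 + 3)
})
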