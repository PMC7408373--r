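test_that("multi-model PDB parsing conserves models, residues and numbering", {
  pdb <- toy_pdb(n_res = 10, n_models = 3)
  ens <- read_ensemble(pdb)
  expect_length(ens$models, 3L)
  expect_identical(nrow(ens$residues), 10L)
  expect_identical(ens$residues$resno, 1:10)
  expect_identical(ens$chain, "A")
  expect_true(all(vapply(ens$models, function(m) all(m$complete), TRUE)))
})

test_that("a file without MODEL records is one implicit model", {
  pdb <- toy_pdb(n_res = 8, n_models = 1)
  atoms_only <- pdb[!grepl("^(MODEL|ENDMDL|END)", pdb)]
  ens <- read_ensemble(atoms_only)
  expect_length(ens$models, 1L)
  expect_identical(nrow(ens$residues), 8L)
})

test_that("no parsable ATOM records is an error", {
  expect_error(read_ensemble(c("HEADER    X", "REMARK 1")), "no ATOM")
})

test_that("a residue missing an atom is incomplete in that model only", {
  pdb <- toy_pdb(n_res = 10, n_models = 3)
  idx2 <- model_block_idx(pdb, 2)
  drop <- idx2[grepl(" CA ", pdb[idx2]) & grepl(" A   5 ", pdb[idx2])]
  expect_length(drop, 1L)
  ens <- read_ensemble(pdb[-drop])
  expect_false(ens$models[[2]]$complete[5])
  expect_true(ens$models[[1]]$complete[5])
  expect_true(ens$models[[3]]$complete[5])
})

test_that("models with different residue sets reconcile to the union", {
  pdb <- toy_pdb(n_res = 10, n_models = 2)
  idx2 <- model_block_idx(pdb, 2)
  drop <- idx2[grepl(" A   1 ", pdb[idx2])]   # remove residue 1 from model 2
  expect_length(drop, 3L)
  expect_warning(ens <- read_ensemble(pdb[-drop]), "union")
  expect_identical(nrow(ens$residues), 10L)
  expect_false(ens$models[[2]]$complete[1])
  expect_true(ens$models[[1]]$complete[1])
})

test_that("alternate locations resolve to the highest occupancy", {
  pdb <- toy_pdb(n_res = 7, n_models = 1)
  i_ca3 <- which(grepl(" CA ", pdb) & grepl(" A   3 ", pdb))
  line <- pdb[i_ca3]
  # altloc A at occupancy 0.40 with shifted coordinates; original B at 0.60
  alt_a <- line
  substr(alt_a, 17, 17) <- "A"
  substr(alt_a, 31, 38) <- sprintf("%8.3f", 99.0)
  substr(alt_a, 55, 60) <- sprintf("%6.2f", 0.40)
  alt_b <- line
  substr(alt_b, 17, 17) <- "B"
  substr(alt_b, 55, 60) <- sprintf("%6.2f", 0.60)
  pdb2 <- append(pdb[-i_ca3], c(alt_a, alt_b), after = i_ca3 - 1L)
  ens <- read_ensemble(pdb2)
  orig <- read_ensemble(pdb)
  expect_equal(ens$models[[1]]$ca[3, ], orig$models[[1]]$ca[3, ])
})

test_that("planar quadruples give cis 0 and trans 180", {
  a <- c(1, 0, 0); b <- c(0, 0, 0); cc <- c(0, 1, 0)
  expect_equal(dihedral(a, b, cc, c(1, 1, 0)), 0)
  expect_equal(dihedral(a, b, cc, c(-1, 1, 0)), 180)
  # degenerate geometry: collinear points
  expect_true(is.na(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))))
})

test_that("torsion computation agrees with the bio3d reference", {
  set.seed(21)
  for (k in 1:20) {
    p <- matrix(stats::rnorm(12, sd = 4), 3, 4)
    expect_equal(dihedral(p[, 1], p[, 2], p[, 3], p[, 4]),
                 as.numeric(bio3d::torsion.xyz(as.vector(p))),
                 tolerance = 1e-6)
  }
})

test_that("dihedral counts follow chain-end rules", {
  pdb <- toy_pdb(n_res = 10, n_models = 1)
  dih <- compute_dihedrals(read_ensemble(pdb))
  expect_true(is.na(dih$phi[1, 1]))    # no preceding C
  expect_true(is.na(dih$psi[10, 1]))   # no following N
  expect_identical(sum(!is.na(dih$phi[, 1])), 9L)
  expect_identical(sum(!is.na(dih$psi[, 1])), 9L)
})

test_that("numbering gaps and long C-N distances are chain breaks", {
  pdb <- toy_pdb(n_res = 12, n_models = 1)
  # renumber residues 7..12 to 8..13: numbering break between positions 6/7
  for (i in seq_along(pdb)) {
    if (grepl("^ATOM", pdb[i])) {
      resno <- as.integer(substr(pdb[i], 23, 26))
      if (resno >= 7) substr(pdb[i], 23, 26) <- sprintf("%4d", resno + 1L)
    }
  }
  dih <- compute_dihedrals(read_ensemble(pdb))
  expect_true(is.na(dih$phi[7, 1]))   # crosses the numbering gap
  expect_true(is.na(dih$psi[6, 1]))
  expect_false(is.na(dih$phi[6, 1]))
  expect_false(is.na(dih$psi[7, 1]))

  # displace the second half of an otherwise consecutive chain
  pdb2 <- toy_pdb(n_res = 12, n_models = 1)
  for (i in seq_along(pdb2)) {
    if (grepl("^ATOM", pdb2[i]) && as.integer(substr(pdb2[i], 23, 26)) >= 7) {
      x <- as.numeric(substr(pdb2[i], 31, 38))
      substr(pdb2[i], 31, 38) <- sprintf("%8.3f", x + 50)
    }
  }
  dih2 <- compute_dihedrals(read_ensemble(pdb2))
  expect_true(is.na(dih2$phi[7, 1]))  # C(6)-N(7) far beyond 2.5 A
  expect_true(is.na(dih2$psi[6, 1]))
})

test_that("specified dihedrals survive the full geometric round trip", {
  # labels chosen freely per position; only the angles are checked here
  set.seed(31)
  L <- 30
  labs <- matrix(sample(pb_labels(), L * 2, replace = TRUE), L, 2)
  pdb <- build_backbone(labs, sigma = 0, seed = 1)
  dih <- compute_dihedrals(read_ensemble(pdb))
  proto <- pb_prototypes()
  for (m in 1:2) {
    want_phi <- proto[labs[, m], 4L]
    want_psi <- proto[labs[, m], 5L]
    got_phi <- dih$phi[2:L, m]
    got_psi <- dih$psi[1:(L - 1), m]
    expect_lt(max(angular_distance(got_phi, want_phi[2:L])), 0.5)
    expect_lt(max(angular_distance(got_psi, want_psi[1:(L - 1)])), 0.5)
  }
})
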