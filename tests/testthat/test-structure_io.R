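test_that("a single-model single-chain PDB yields one backbone chain", {
  atoms <- fixture_helix_atoms(5)
  path <- write_fixture(c(fixture_pdb_lines(atoms), "TER", "END"), ".pdb")
  chains <- read_structure(path)
  expect_length(chains, 1)
  ch <- chains[[1]]
  expect_s3_class(ch, "backbone_chain")
  expect_length(ch, 5)
  expect_identical(ch$resid, 1:5)
  expect_false(anyNA(ch$N) || anyNA(ch$CA) || anyNA(ch$C))
})

test_that("multi-model files yield one chain per model with model labels", {
  atoms <- fixture_helix_atoms(4)
  body <- fixture_pdb_lines(atoms)
  lines <- c("MODEL        1", body, "ENDMDL",
             "MODEL        2", body, "ENDMDL",
             "MODEL        3", body, "ENDMDL", "END")
  path <- write_fixture(lines, ".pdb")
  chains <- read_structure(path)
  expect_length(chains, 3)
  expect_match(names(chains)[1], "model 1")
  expect_match(names(chains)[3], "model 3")
  expect_true(all(vapply(chains, length, 1L) == 4))
})

test_that("ligand HETATM groups and waters are excluded", {
  atoms <- fixture_helix_atoms(5)
  het <- data.frame(record = "HETATM", name = c("C1", "N", "CA", "C"),
                    resname = c("LIG", "LIG", "LIG", "LIG"), chain = "A",
                    resno = 101L, x = 30, y = 30, z = 30)
  wat <- data.frame(record = "HETATM", name = "O", resname = "HOH",
                    chain = "A", resno = 201L, x = 40, y = 40, z = 40)
  path <- write_fixture(c(fixture_pdb_lines(rbind(atoms, het, wat)),
                          "TER", "END"), ".pdb")
  chains <- read_structure(path)
  expect_length(chains, 1)
  expect_length(chains[[1]], 5)  # ligand and water dropped

  # but an MSE HETATM with backbone atoms is retained by default
  mse <- fixture_helix_atoms(5)
  mse$record[7:9] <- "HETATM"
  mse$resname[7:9] <- "MSE"
  path2 <- write_fixture(c(fixture_pdb_lines(mse), "TER", "END"), ".pdb")
  ch2 <- read_structure(path2)[[1]]
  expect_length(ch2, 5)
  expect_identical(ch2$resname[3], "MSE")
})

test_that("chains without amino acids are skipped with a warning", {
  atoms <- fixture_helix_atoms(5)
  wat <- data.frame(record = "HETATM", name = "O", resname = "HOH",
                    chain = "B", resno = 1:3, x = 40, y = 40, z = 40)
  path <- write_fixture(c(fixture_pdb_lines(rbind(atoms, wat)), "END"),
                        ".pdb")
  expect_warning(chains <- read_structure(path), "no amino-acid residues")
  expect_length(chains, 1)
})

test_that("alternate locations keep the highest-occupancy conformer", {
  atoms <- fixture_helix_atoms(3)
  # duplicate CA of residue 2 with an altloc at higher occupancy elsewhere
  dup <- atoms[atoms$name == "CA" & atoms$resno == 2, ]
  dup$x <- dup$x + 5
  atoms$alt <- rep(" ", nrow(atoms))
  atoms$occ <- rep(1, nrow(atoms))
  atoms$alt[atoms$name == "CA" & atoms$resno == 2] <- "A"
  atoms$occ[atoms$name == "CA" & atoms$resno == 2] <- 0.4
  dup$alt <- "B"; dup$occ <- 0.6
  path <- write_fixture(c(fixture_pdb_lines(rbind(atoms, dup)), "END"),
                        ".pdb")
  ch <- read_structure(path)[[1]]
  expect_length(ch, 3)
  # the B conformer (occupancy 0.6, x shifted by +5) wins
  base <- fixture_helix_atoms(3)
  expect_equal(ch$CA[2, 1],
               base$x[base$name == "CA" & base$resno == 2] + 5,
               tolerance = 1e-3)
})

test_that("missing backbone atoms keep the residue with NA coordinates", {
  atoms <- fixture_helix_atoms(5)
  atoms <- atoms[!(atoms$resno == 3 & atoms$name == "CA"), ]
  path <- write_fixture(c(fixture_pdb_lines(atoms), "END"), ".pdb")
  ch <- read_structure(path)[[1]]
  expect_length(ch, 5)
  expect_true(anyNA(ch$CA[3, ]))
  expect_false(anyNA(ch$N[3, ]))
})

test_that("unreadable files and unknown formats are fatal", {
  expect_error(read_structure("no/such/file.pdb"), "no/such/file.pdb")
  expect_error(read_structure(write_fixture("x", ".xyz")), "auto-detect")
})

test_that("backbone chains round-trip through minimal PDB text", {
  set.seed(12)
  ch <- build_backbone(phi = stats::runif(6, -179, 180),
                       psi = stats::runif(6, -179, 180),
                       resid = 11:16, resname = "GLY")
  path <- tempfile(fileext = ".pdb")
  write_backbone_pdb(ch, path)
  back <- read_structure(path)[[1]]
  expect_identical(back$resid, ch$resid)
  expect_identical(back$resname, ch$resname)
  for (at in c("N", "CA", "C")) {
    expect_lt(max(abs(back[[at]] - ch[[at]])), 5e-4)  # PDB: 3 decimals
  }
})

test_that("pdb and mmcif readers agree element-wise on coordinates", {
  atoms <- fixture_helix_atoms(6)
  pdb <- write_fixture(c(fixture_pdb_lines(atoms), "END"), ".pdb")
  cif <- write_fixture(fixture_cif_lines(atoms), ".cif")
  a <- read_structure(pdb)[[1]]
  b <- read_structure(cif)[[1]]
  expect_identical(a$resid, b$resid)
  for (at in c("N", "CA", "C")) {
    expect_identical(a[[at]], b[[at]])
  }
})

test_that("trajectories yield one chain per frame and exclude solvent", {
  base <- build_backbone(phi = rep(-57, 10), psi = rep(-47, 10))
  top_atoms <- fixture_helix_atoms(10)
  wat <- data.frame(record = "HETATM", name = "O", resname = "HOH",
                    chain = "A", resno = 500:502,
                    x = 40, y = 41, z = 42)
  top <- write_fixture(c(fixture_pdb_lines(rbind(top_atoms, wat)), "END"),
                       ".pdb")
  n_atoms <- nrow(top_atoms) + nrow(wat)
  set.seed(5)
  xyz <- matrix(0, 4, 3 * n_atoms)
  prot_xyz <- as.vector(t(do.call(rbind, lapply(seq_len(10), function(i) {
    rbind(base$N[i, ], base$CA[i, ], base$C[i, ])
  }))))
  for (f in 1:4) {
    xyz[f, ] <- c(prot_xyz, rep(c(40, 41, 42), 3)) + (f - 1) * 0.01
  }
  traj <- tempfile(fileext = ".nc")
  capture.output(bio3d::write.ncdf(xyz, traj))
  frames <- read_trajectory(top, traj)
  expect_length(frames, 4)
  expect_true(all(vapply(frames, length, 1L) == 10))  # waters excluded
  expect_match(names(frames)[2], "frame 2")

  # a single-frame PDB "trajectory" matches the static reading
  one <- write_fixture(c(fixture_pdb_lines(top_atoms), "END"), ".pdb")
  tr1 <- read_trajectory(one, one)
  d_static <- phi_psi(read_structure(one)[[1]])
  d_traj <- phi_psi(tr1[[1]])
  expect_equal(d_traj$phi, d_static$phi)
  expect_equal(d_traj$psi, d_static$psi)
})

test_that("trajectory atom-count mismatches and unknown formats are fatal", {
  top_atoms <- fixture_helix_atoms(4)
  top <- write_fixture(c(fixture_pdb_lines(top_atoms), "END"), ".pdb")
  xyz <- matrix(0, 2, 3 * (nrow(top_atoms) + 1))
  traj <- tempfile(fileext = ".nc")
  capture.output(bio3d::write.ncdf(xyz, traj))
  expect_error(read_trajectory(top, traj), "atom-count mismatch")
  bad <- write_fixture("not a trajectory", ".xtc")
  expect_error(read_trajectory(top, bad), "unsupported trajectory format")
})
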