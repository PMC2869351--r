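test_that("multi-model PDB round-trips frames, atoms and units", {
  gt <- small_hinged(sizes = c(3, 3), seed = 81, n_frames = 6)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(gt$ensemble, f)
  ens <- read_ensemble(f, selection = "calpha")
  expect_equal(ens$n_frames, 6)
  expect_equal(ens$n_atoms, 6)
  # PDB stores angstroms at 3 decimals; nm coordinates match to 1e-4 nm
  expect_equal(ens$coords, gt$ensemble$coords, tolerance = 1e-3)
  expect_equal(ens$atoms$resno, gt$ensemble$atoms$resno)
})

test_that("angstrom-to-nanometre conversion uses the known fixture values", {
  f <- withr::local_tempfile(fileext = ".pdb")
  xyz <- rbind(c(10, 0, 0, 0, 25, 0), c(10, 0, 0, 0, 25, 5))
  bio3d::write.pdb(file = f, xyz = xyz, resno = c(1, 2), chain = c("A", "A"),
                   resid = c("GLY", "GLY"), elety = c("CA", "CA"),
                   eleno = c(1, 2))
  ens <- read_ensemble(f)
  expect_equal(ens$coords[1, 1, ], c(1, 0, 0))    # 10 angstrom -> 1 nm
  expect_equal(ens$coords[2, 2, ], c(0, 2.5, 0.5))
})

test_that("single-model PDB and empty selections are rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = f, xyz = c(1, 2, 3), resno = 1, chain = "A",
                   resid = "GLY", elety = "CA", eleno = 1)
  expect_error(read_ensemble(f), ">= 2 conformations")
  g <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = g, xyz = rbind(c(1, 2, 3), c(1, 2, 4)), resno = 1,
                   chain = "A", resid = "GLY", elety = "N", eleno = 1)
  expect_error(read_ensemble(g, selection = "calpha"), "zero atoms")
  expect_error(read_ensemble("no-such-file.pdb"), "not found")
})

test_that("multi-frame XYZ files round-trip through the ensemble container", {
  gt <- small_hinged(sizes = c(2, 3), seed = 91, n_frames = 3)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_ensemble_xyz(gt$ensemble, f)
  ens <- read_ensemble(f, selection = "all")
  expect_equal(ens$n_frames, 3)
  expect_equal(ens$n_atoms, 5)
  expect_equal(ens$coords, gt$ensemble$coords, tolerance = 1e-6)
  expect_error(read_ensemble(f, selection = "calpha"), "all")
})

test_that("a set of single-model PDBs is matched by atom identity", {
  gt <- small_hinged(sizes = c(2, 2), seed = 101, n_frames = 4)
  td <- withr::local_tempdir()
  paths <- file.path(td, sprintf("struct%d.pdb", 1:3))
  for (i in 1:3) {
    # single model files: write frame i only
    bio3d::write.pdb(file = paths[i],
                     xyz = as.vector(t(gt$ensemble$coords[i, , ])) * 10,
                     resno = gt$ensemble$atoms$resno,
                     chain = gt$ensemble$atoms$chain,
                     resid = gt$ensemble$atoms$resid,
                     elety = gt$ensemble$atoms$elety, eleno = 1:4)
  }
  ens <- read_ensemble(paths, selection = "calpha")
  expect_equal(ens$n_frames, 3)
  expect_equal(ens$coords[2, , ], gt$ensemble$coords[2, , ],
               tolerance = 1e-3)
  # a structure with a differing atom set is rejected with a report
  bad <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = bad, xyz = c(1, 1, 1, 2, 2, 2, 3, 3, 3),
                   resno = c(1, 2, 9), chain = rep("A", 3),
                   resid = rep("GLY", 3), elety = rep("CA", 3), eleno = 1:3)
  expect_error(read_ensemble(c(paths[1], bad)), "atom sets differ")
})

test_that("domain-annotated PDB carries labels and scaled flexibility", {
  co <- array(rnorm(2 * 3 * 3), dim = c(2, 3, 3))
  ens <- conf_ensemble(co)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_domain_pdb(ens, c(1, 2, 2), flexibility = c(0, 1, 1), file = f)
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  expect_equal(pdb$atom$b, c(1, 2, 2))
  expect_equal(pdb$atom$o, c(0, 1, 1))
  # written file re-read gives identical labels (round-trip)
  expect_identical(as.integer(pdb$atom$b), c(1L, 2L, 2L))
  expect_error(write_domain_pdb(ens, integer(0), file = f), "empty")
  expect_error(write_domain_pdb(ens, c(1, 2), file = f), "length")
})
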