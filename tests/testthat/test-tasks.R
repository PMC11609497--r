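taskFixture <- function(seed = 81L, nFrames = 10L, mode = "rigid") {
  s <- generateSystem(2, 6, 4, 6, seed = seed)
  sys <- makeSystem(s$topology, s$state, "MutableSerial")
  ref <- file.path(tempdir(), sprintf("task%d.pdb", seed))
  writeStructure(ref, selectAtoms(sys, "all"))
  traj <- file.path(tempdir(), sprintf("task%d.dcd", seed))
  generateTrajectory(readStructure(ref), nFrames,
                     motionSpec(mode, seed = seed + 1L), traj)
  list(ref = ref, traj = traj, n = nFrames)
}

test_that("rmsd task reports near-zero for rigid motion and zero against itself", {
  fx <- taskFixture()
  df <- taskRmsd(fx$traj, fx$ref, "all")
  expect_equal(nrow(df), fx$n)
  expect_true(all(df$rmsd_nm < 1e-5))           # frames are rigid copies
  expect_lt(df$rmsd_nm[1], 1e-6)                # frame 1 is the reference
  # fit on CA, measure on everything: still rigid, still ~0
  df2 <- taskRmsd(fx$traj, fx$ref, "name CA", measureExpr = "all")
  expect_true(all(df2$rmsd_nm < 1e-5))
})

test_that("within-com task equals the manual library-call composition", {
  fx <- taskFixture(seed = 82L, mode = "mixed")
  expr <- "resid 2 and chain A"
  df <- taskWithinCom(fx$traj, fx$ref, expr, cutoff = 0.9)
  expect_equal(nrow(df), fx$n)
  ref <- readStructure(fx$ref)
  sys <- makeSystem(ref$topology, ref$state, "MutableSerial")
  q <- indices(selectAtoms(sys, expr))
  rd <- openTrajectory(fx$traj)
  for (i in c(1L, 4L, fx$n)) {
    st <- readFrame(rd, i)
    hits <- searchWithin(st@coords, q, 0.9, box = st@box)
    com <- centerOfMass(selectIndices(
      makeSystem(ref$topology, st, "MutableSerial"), hits), pbc = TRUE)
    expect_equal(unlist(df[i, c("x_nm", "y_nm", "z_nm")]), com,
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(df$n_atoms[i], length(hits))
  }
})

test_that("within-com saturates to the whole-system COM for huge cutoffs, unboxed", {
  s <- generateSystem(1, 5, 4, 5, seed = 83L)
  sys <- makeSystem(s$topology, state(s$state@coords), "MutableSerial")  # no box
  ref <- file.path(tempdir(), "nobox.pdb")
  writeStructure(ref, selectAtoms(sys, "all"))
  traj <- file.path(tempdir(), "nobox.xyz")
  generateTrajectory(list(topology = s$topology,
                          state = state(s$state@coords)), 3,
                     motionSpec("brownian", seed = 84L, sigma = 0.01), traj)
  df <- taskWithinCom(traj, ref, "resid 1", cutoff = 100)
  rd <- openTrajectory(traj)
  refTop <- readStructure(ref)$topology
  for (i in 1:3) {
    st <- readFrame(rd, i)
    all_i <- selectAtoms(makeSystem(refTop, st, "MutableSerial"), "all")
    expect_equal(unlist(df[i, c("x_nm", "y_nm", "z_nm")]), centerOfMass(all_i),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(df$n_atoms[i], nAtoms(refTop))
  }
})

test_that("extract task writes exactly the selected atoms for every frame", {
  fx <- taskFixture(seed = 85L, mode = "mixed")
  out <- file.path(tempdir(), "extract.dcd")
  n <- taskExtract(fx$traj, "chain A", fx$ref, out)
  expect_equal(n, fx$n)
  ref <- readStructure(fx$ref)
  sys <- makeSystem(ref$topology, ref$state, "MutableSerial")
  idx <- indices(selectAtoms(sys, "chain A"))
  rin <- openTrajectory(fx$traj); rout <- openTrajectory(out)
  expect_equal(nFrames(rout), fx$n)
  expect_equal(rout@h$natom, length(idx))
  for (i in c(1L, 3L, 8L))
    expect_identical(readFrame(rout, i)@coords,
                     readFrame(rin, i)@coords[idx, ])
  # identity extraction: "all" reproduces the input float32-exactly
  out2 <- file.path(tempdir(), "extract_all.dcd")
  taskExtract(fx$traj, "all", fx$ref, out2)
  rall <- openTrajectory(out2)
  for (i in c(2L, 9L))
    expect_identical(readFrame(rall, i)@coords, readFrame(rin, i)@coords)
})

test_that("task CSV outputs carry a header and parse back numerically", {
  fx <- taskFixture(seed = 86L)
  csv <- file.path(tempdir(), "rmsd.csv")
  df <- taskRmsd(fx$traj, fx$ref, "all", outCsv = csv)
  lines <- readLines(csv)
  expect_true(all(startsWith(lines[1:3], "#")))
  parsed <- read.csv(csv, comment.char = "#")
  expect_equal(nrow(parsed), fx$n)
  expect_equal(parsed$rmsd_nm, df$rmsd_nm, tolerance = 1e-9)
})

test_that("the CLI front-end runs end to end with documented exit codes", {
  cli <- system.file("cli", "molkit.R", package = "molkit")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  td <- tempdir()
  run <- function(...) {
    suppressWarnings(system2(rscript, c(cli, ...), stdout = TRUE, stderr = TRUE))
  }
  ref <- file.path(td, "cli.pdb"); traj <- file.path(td, "cli.dcd")
  out <- run("gen-system", "--out", ref, "--chains", "1", "--residues", "6",
             "--atoms-per-res", "4", "--box-edge", "5", "--seed", "2")
  expect_null(attr(out, "status"))
  out <- run("gen-traj", "--ref", ref, "--out", traj, "--frames", "5",
             "--seed", "3")
  expect_null(attr(out, "status"))
  csv <- file.path(td, "cli_rmsd.csv")
  out <- run("rmsd", "--traj", traj, "--ref", ref, "--out", csv)
  expect_null(attr(out, "status"))
  expect_equal(nrow(read.csv(csv, comment.char = "#")), 5L)
  # usage error -> 2, data error -> 3
  out <- run("frobnicate")
  expect_equal(attr(out, "status"), 2L)
  out <- run("rmsd", "--traj", file.path(td, "missing.dcd"), "--ref", ref,
             "--out", csv)
  expect_equal(attr(out, "status"), 3L)
})
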