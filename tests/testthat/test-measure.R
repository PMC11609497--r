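test_that("center of mass and geometry follow the weighted-mean definitions", {
  top <- topology(data.frame(name = c("A1", "A2"), resname = "LIG",
                             resid = 1L, chain = "A",
                             mass = c(1, 1), element = "C"))
  sys <- makeSystem(top, state(rbind(c(0, 0, 0), c(2, 0, 0))), "MutableSerial")
  expect_equal(centerOfMass(selectAtoms(sys, "all")), c(1, 0, 0))

  top2 <- topology(data.frame(name = c("A1", "A2"), resname = "LIG",
                              resid = 1L, chain = "A",
                              mass = c(1, 3), element = "C"))
  sys2 <- makeSystem(top2, state(rbind(c(0, 0, 0), c(4, 0, 0))), "MutableSerial")
  sel2 <- selectAtoms(sys2, "all")
  expect_equal(centerOfMass(sel2), c(3, 0, 0))
  expect_equal(centerOfGeometry(sel2), c(2, 0, 0))

  set.seed(2)
  sys3 <- toySystem(seed = 2)
  sel3 <- selectAtoms(sys3, "all")
  expect_equal(centerOfGeometry(sel3), colMeans(coords(sel3)))
  one <- selectIndices(sys3, 5L)
  expect_equal(centerOfGeometry(one), as.numeric(coords(sys3)[5, ]))
})

test_that("periodic center of mass handles boundary-straddling clusters (circular mean)", {
  top <- topology(data.frame(name = c("A1", "A2"), resname = "LIG",
                             resid = 1L, chain = "A", mass = c(1, 1),
                             element = "C"))
  st <- state(rbind(c(0.5, 2, 3), c(9.5, 2, 3)), box = periodicBox(10))
  sys <- makeSystem(top, st, "MutableSerial")
  com <- centerOfMass(selectAtoms(sys, "all"), pbc = TRUE)
  expect_equal(com[1] %% 10, 0, tolerance = 1e-9)     # not the naive 5.0
  expect_equal(com[2:3], c(2, 3), tolerance = 1e-9)
  # brute-force oracle: minimize the wrapped weighted squared distance
  want <- bruteComPBC(coords(sys), c(1, 1), c(10, 10, 10))
  expect_equal(com %% 10, want %% 10, tolerance = 1e-3)
  # pbc without a box is an error
  sysNB <- makeSystem(top, state(rbind(c(0.5, 2, 3), c(9.5, 2, 3))),
                      "MutableSerial")
  expect_error(centerOfMass(selectAtoms(sysNB, "all"), pbc = TRUE), "box")
})

test_that("periodic COM is invariant modulo the lattice under whole-box shifts", {
  set.seed(14)
  s <- generateSystem(1, 4, 4, 8, seed = 14)
  sys <- makeSystem(s$topology, s$state, "MutableSerial")
  sel <- selectAtoms(sys, "all")
  com0 <- centerOfMass(sel, pbc = TRUE)
  sub <- selectAtoms(sys, "resid 1-2")
  translateAtoms(sub, c(8, -8, 16))                 # whole multiples of the box
  com1 <- centerOfMass(sel, pbc = TRUE)
  expect_equal(com0 %% 8, com1 %% 8, tolerance = 1e-8)
})

test_that("rmsd matches the closed form and is translation invariant", {
  A <- rbind(c(0, 0, 0), c(1, 0, 0))
  B <- rbind(c(0, 0, 0), c(1, 1, 0))
  expect_equal(rmsd(A, B), sqrt(0.5))
  expect_equal(rmsd(A, A), 0)
  set.seed(3)
  X <- matrix(rnorm(60), ncol = 3); Y <- matrix(rnorm(60), ncol = 3)
  v <- c(1.5, -2, 0.7)
  expect_equal(rmsd(sweep(X, 2, v, "+"), sweep(Y, 2, v, "+")), rmsd(X, Y),
               tolerance = 1e-12)
  expect_error(rmsd(X, Y[1:10, ]), "differ in size")
})

test_that("Kabsch fit recovers constructed rigid motions exactly", {
  set.seed(4)
  ref <- matrix(rnorm(150), ncol = 3)
  tr0 <- fitTransform(ref, ref, massWeighted = FALSE)
  expect_equal(tr0@rotation, diag(3), tolerance = 1e-10)
  expect_equal(tr0@translation, c(0, 0, 0), tolerance = 1e-10)

  th <- pi / 2
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mob <- sweep(ref %*% t(Rz), 2, c(1, 2, 3), "+")
  tr <- fitTransform(mob, ref, massWeighted = FALSE)
  expect_equal(det(tr@rotation), 1, tolerance = 1e-10)
  expect_lt(plainRmsd(transformPoints(tr, mob), ref), 1e-10)
  # weighted fit on selections ties the measure and modify layers together
  sys <- toySystem(seed = 4)
  selA <- selectAtoms(sys, "all")
  refX <- coords(selA)
  applyTransform(selA, rigidTransform(Rz, c(0.3, -0.2, 0.1)))
  trW <- fitTransform(coords(selA), refX, weights = masses(selA))
  applyTransform(selA, trW)
  expect_lt(plainRmsd(coords(selA), refX), 1e-10)
})

test_that("mirrored near-planar sets give a proper rotation at the grid-search optimum", {
  set.seed(6)
  P <- cbind(matrix(rnorm(80), ncol = 2), rnorm(40, sd = 1e-4))
  M <- P; M[, 1] <- -M[, 1]                          # mirrored copy
  tr <- fitTransform(M, P, massWeighted = FALSE)
  expect_equal(det(tr@rotation), 1, tolerance = 1e-10)
  got <- plainRmsd(transformPoints(tr, M), P)
  # oracle: best over many random proper rotations (centered alignment)
  Pc <- sweep(P, 2, colMeans(P)); Mc <- sweep(M, 2, colMeans(M))
  best <- Inf
  for (k in 1:2000) best <- min(best, plainRmsd(Mc %*% t(randomRotation()), Pc))
  expect_lte(got, best + 1e-9)
})

test_that("Kabsch fit agrees with bio3d's independent superposition", {
  set.seed(41)
  for (k in 1:5) {
    ref <- matrix(rnorm(120), ncol = 3)
    mob <- sweep(ref %*% t(randomRotation()), 2, runif(3, -2, 2), "+") +
      matrix(rnorm(120, sd = 0.03), ncol = 3)
    tr <- fitTransform(mob, ref, massWeighted = FALSE)
    ours <- plainRmsd(transformPoints(tr, mob), ref)
    ext <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(ref)),
                                           mobile = as.vector(t(mob))))
    theirs <- plainRmsd(matrix(ext, ncol = 3, byrow = TRUE), ref)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("fit refuses degenerate input", {
  line <- cbind(1:5, 0, 0)
  expect_error(fitTransform(line, line, massWeighted = FALSE), "collinear")
  expect_error(fitTransform(matrix(0, 2, 3), matrix(0, 2, 3),
                            massWeighted = FALSE), "at least 3")
})

test_that("radius of gyration matches the direct formula and is rigid-motion invariant", {
  top <- topology(data.frame(name = c("A1", "A2"), resname = "L", resid = 1L,
                             chain = "A", mass = c(1, 1), element = "C"))
  sys <- makeSystem(top, state(rbind(c(0, 0, 0), c(1, 0, 0))), "MutableSerial")
  expect_equal(radiusOfGyration(selectAtoms(sys, "all")), 0.5)
  one <- selectIndices(sys, 1L)
  expect_equal(radiusOfGyration(one), 0)

  sys2 <- toySystem(seed = 8, nChains = 1, resPerChain = 25, atomsPerRes = 4)
  sel <- selectAtoms(sys2, "all")
  x <- coords(sel); w <- masses(sel); wn <- w / sum(w)
  c0 <- colSums(x * wn)
  want <- sqrt(sum(wn * rowSums(sweep(x, 2, c0)^2)))
  expect_equal(radiusOfGyration(sel), want, tolerance = 1e-12)
  rg0 <- radiusOfGyration(sel)
  set.seed(9)
  applyTransform(sel, rigidTransform(randomRotation(), runif(3)))
  expect_equal(radiusOfGyration(sel), rg0, tolerance = 1e-9)
})
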