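test_that("transforms compose and leave unselected atoms untouched", {
  sys <- gridSystem(nRes = 2, atomsPerRes = 3)
  sel <- selectAtoms(sys, "resid 1")
  other <- coords(sys)[4:6, ]
  x0 <- coords(sel)
  applyTransform(sel, rigidTransform())              # identity
  expect_identical(coords(sel), x0)
  translateAtoms(sel, c(1, 0, 0)); translateAtoms(sel, c(1, 0, 0))
  one <- coords(sel)
  coords(sel) <- x0
  translateAtoms(sel, c(2, 0, 0))
  expect_equal(coords(sel), one)
  expect_equal(coords(sys)[4:6, ], other)
  translateAtoms(sel, c(0, 0, 0))
  expect_equal(coords(sys)[4:6, ], other)
})

test_that("read-only kinds refuse every write path", {
  sys <- gridSystem("ImmutableParallel")
  sel <- selectAtoms(sys, "all")
  expect_error(applyTransform(sel, rigidTransform()), "read-only")
  expect_error(translateAtoms(sel, c(1, 0, 0)), "read-only")
  expect_error(coords(sel) <- coords(sel), "read-only")
  expect_error(wrapAtoms(sel), "read-only")
  expect_silent(invisible(coords(sel)))              # reads are fine
})

test_that("unwrap re-images split molecules by the minimum-image chain rule", {
  top <- topology(data.frame(name = c("C1", "C2"), resname = "ETH",
                             resid = 1L, chain = "A", element = "C"))
  st <- state(rbind(c(9.8, 5, 5), c(0.1, 5, 5)), box = periodicBox(10))
  sys <- makeSystem(top, st, "MutableSerial")
  sel <- selectAtoms(sys, "all")
  unwrapAtoms(sel)
  expect_equal(coords(sel)[2, 1], 10.1, tolerance = 1e-12)
  # an already-whole molecule is untouched
  st2 <- state(rbind(c(5, 5, 5), c(5.15, 5, 5)), box = periodicBox(10))
  sys2 <- makeSystem(top, st2, "MutableSerial")
  sel2 <- selectAtoms(sys2, "all")
  x0 <- coords(sel2)
  unwrapAtoms(sel2)
  expect_equal(coords(sel2), x0)
  # no box -> error
  sys3 <- makeSystem(top, state(rbind(c(9.8, 5, 5), c(0.1, 5, 5))),
                     "MutableSerial")
  expect_error(unwrapAtoms(selectAtoms(sys3, "all")), "box")
})

test_that("wrap maps all atoms into the primary cell and is idempotent", {
  set.seed(21)
  for (k in 1:5) {
    bx <- boxFromLengthsAngles(runif(1, 3, 5), runif(1, 3, 5), runif(1, 3, 5),
                               runif(1, 75, 105), runif(1, 75, 105),
                               runif(1, 75, 105))
    n <- 200
    top <- topology(data.frame(name = "C1", resname = "L",
                               resid = seq_len(n), chain = "A",
                               element = "C"))
    xyz <- matrix(runif(n * 3, -10, 10), ncol = 3)
    sys <- makeSystem(top, state(xyz, box = bx), "MutableSerial")
    sel <- selectAtoms(sys, "all")
    wrapAtoms(sel)
    f <- coords(sel) %*% solve(bx@matrix)
    expect_true(all(f >= 0 & f < 1))
    x1 <- coords(sel)
    wrapAtoms(sel)
    expect_equal(coords(sel), x1, tolerance = 1e-12)
  }
})

test_that("unwrap then wrap preserves pairwise minimum-image distances", {
  s <- generateSystem(1, 8, 3, 5, seed = 19)
  sys <- makeSystem(s$topology, s$state, "MutableSerial")
  sel <- selectAtoms(sys, "all")
  bx <- box(sel)
  pair <- function() {
    x <- coords(sel)
    vapply(2:nrow(x), function(i)
      sqrt(sum(boxWrapVector(bx, x[i, ] - x[i - 1, ])^2)), numeric(1))
  }
  d0 <- pair()
  unwrapAtoms(sel)
  wrapAtoms(sel)
  expect_equal(pair(), d0, tolerance = 1e-9)
  f <- coords(sel) %*% solve(bx@matrix)
  expect_true(all(f >= 0 & f < 1))
})

test_that("applying the fitted transform reaches the Kabsch-optimal RMSD", {
  sys <- toySystem(seed = 33)
  sel <- selectAtoms(sys, "all")
  ref <- coords(sel)
  set.seed(34)
  applyTransform(sel, rigidTransform(randomRotation(), runif(3, -1, 1)))
  tr <- fitTransform(coords(sel), ref, weights = masses(sel))
  applyTransform(sel, tr)
  expect_lt(rmsd(coords(sel), ref), 1e-10)
})
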