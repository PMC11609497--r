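test_that("grammar primitives select the documented index sets", {
  sys <- gridSystem(nRes = 2, atomsPerRes = 5)   # 10 atoms
  expect_equal(indices(selectAtoms(sys, "all")), 1:10)
  # `index` keyword is 0-based inclusive
  expect_equal(indices(selectAtoms(sys, "index 2-5")), 3:6)
  expect_equal(indices(selectAtoms(sys, "index 0 9")), c(1L, 10L))
  expect_equal(indices(selectAtoms(sys, "resid 2")), 6:10)
  expect_equal(indices(selectAtoms(sys, "name CA C")), c(2L, 3L, 7L, 8L))
  expect_equal(indices(selectAtoms(sys, "not resid 2")), 1:5)
  expect_equal(indices(selectAtoms(sys, "name CA or name O")),
               c(2L, 4L, 7L, 9L))
})

test_that("compound expressions match a brute-force predicate over the atom table", {
  sys <- gridSystem(nRes = 3, atomsPerRes = 7)   # CA at 2, 9, 16
  a <- atoms(sys)
  want <- which(a$name == "CA" & a$resid >= 1 & a$resid <= 2)
  expect_equal(indices(selectAtoms(sys, "name CA and resid 1-2")), want)
  want2 <- which((a$resname == "ALA" | a$name == "O") & a$resid != 2)
  expect_equal(indices(selectAtoms(sys, "(resname ALA or name O) and not resid 2")),
               want2)
})

test_that("within clause agrees with the brute-force distance oracle, boxed and not", {
  set.seed(42)
  for (withBox in c(FALSE, TRUE)) {
    s <- generateSystem(2, 6, 4, 5, seed = 17)
    st <- if (withBox) s$state else state(s$state@coords)
    sys <- makeSystem(s$topology, st, "MutableSerial")
    q <- indices(selectAtoms(sys, "resid 3 and chain A"))
    got <- indices(selectAtoms(sys, "within 0.8 of (resid 3 and chain A)"))
    want <- bruteWithin(coords(sys), q, 0.8,
                        if (withBox) box(sys)@matrix else NULL,
                        includeQuery = TRUE)
    expect_equal(got, want)
    # reference atoms excluded on request
    got2 <- indices(selectAtoms(sys, "within 0.8 of (resid 3 and chain A)",
                                withinIncludesSelf = FALSE))
    expect_equal(got2, setdiff(want, q))
  }
})

test_that("parse errors carry a position and empty matches are errors", {
  sys <- gridSystem()
  expect_error(selectAtoms(sys, "name"), "token")
  expect_error(selectAtoms(sys, "resid 1 frobnicate"), "integer or range")
  expect_error(selectAtoms(sys, "(name CA"), "token")
  expect_error(selectAtoms(sys, "resid 5-2"), "range")
  expect_error(selectAtoms(sys, "name ZZ"), "empty selection")
  expect_null(trySelectAtoms(sys, "name ZZ"))
  expect_error(trySelectAtoms(sys, "name ("), "token")
})

test_that("subselect narrows, never widens, and equals the system-wide intersection oracle", {
  sys <- gridSystem(nRes = 3, atomsPerRes = 7)
  parent <- selectAtoms(sys, "index 2-7")          # atoms 3..8
  wide <- subselect(parent, "index 0-100")
  expect_equal(indices(wide), indices(parent))
  sub <- subselect(parent, "resid 2")
  expect_equal(indices(sub),
               intersect(indices(parent), indices(selectAtoms(sys, "resid 2"))))
  expect_true(isAlive(parent))
  expect_error(subselect(parent, "resid 99"), "empty selection")
  # oracle equivalence over a batch of random parents and expressions
  set.seed(7)
  exprs <- c("name CA CB", "resid 1 3", "resname GLY", "not name O",
             "index 4-15")
  for (k in 1:10) {
    pidx <- sort(sample(nAtoms(sys), sample(5:15, 1)))
    p <- selectIndices(sys, pidx)
    e <- sample(exprs, 1)
    full <- trySelectAtoms(sys, e)
    want <- intersect(pidx, if (is.null(full)) integer(0) else indices(full))
    if (length(want) == 0L) expect_error(subselect(p, e), "empty selection")
    else expect_equal(indices(subselect(p, e)), want)
  }
})

test_that("splitFragments partitions the parent and keeps it alive", {
  sys <- gridSystem(nRes = 3, atomsPerRes = 2)    # resids 1,1,2,2,3,3
  parent <- selectAtoms(sys, "all")
  frags <- splitFragments(parent, "resid")
  expect_length(frags, 3L)
  expect_equal(unname(lengths(lapply(frags, indices))), rep(2L, 3))
  expect_equal(sort(unlist(lapply(frags, indices), use.names = FALSE)), indices(parent))
  expect_true(all(!duplicated(unlist(lapply(frags, indices), use.names = FALSE))))
  # degenerate key: one fragment equal to the parent
  one <- splitFragments(parent, function(idx, atoms) "k")
  expect_length(one, 1L)
  expect_equal(indices(one[[1]]), indices(parent))
  # parent remains usable
  expect_length(centerOfMass(parent), 3L)
})

test_that("fragment partition property holds for random parents and keys", {
  sys <- toySystem(seed = 23, nChains = 2, resPerChain = 5, atomsPerRes = 3)
  set.seed(9)
  for (k in 1:10) {
    pidx <- sort(sample(nAtoms(sys), sample(4:20, 1)))
    parent <- selectIndices(sys, pidx)
    key <- sample(list("resid", "chain", "name", "residue",
                       function(idx, atoms) idx %% 3), 1)[[1]]
    frags <- splitFragments(parent, key)
    all_idx <- unlist(lapply(frags, indices), use.names = FALSE)
    expect_equal(sort(all_idx), pidx)
    expect_false(any(duplicated(all_idx)))
  }
})

test_that("intoFragments consumes the parent before fragments are usable", {
  sys <- gridSystem(nRes = 3, atomsPerRes = 2)
  parent <- selectAtoms(sys, "all")
  frags <- intoFragments(parent, "resid")
  expect_false(isAlive(parent))
  expect_error(coords(parent), "consumed")
  expect_error(indices(parent), "consumed")
  expect_length(frags, 3L)
  expect_equal(sort(unlist(lapply(frags, indices), use.names = FALSE)), 1:6)
  # constant key: single fragment identical to (now dead) parent
  p2 <- selectAtoms(sys, "all")
  f2 <- intoFragments(p2, function(idx, atoms) 1L)
  expect_false(isAlive(p2))
  expect_equal(indices(f2[[1]]), 1:6)
})

test_that("MutableParallel selections never overlap and fragmentation re-claims atomically", {
  sys <- gridSystem("MutableParallel", nRes = 3, atomsPerRes = 2)
  s1 <- selectAtoms(sys, "index 0-2")
  expect_equal(usedIndices(sys), 1:3)
  expect_error(selectAtoms(sys, "index 2-3"), "overlapping parallel selection")
  s2 <- selectAtoms(sys, "index 3-5")              # disjoint: fine
  expect_equal(usedIndices(sys), 1:6)
  # subselect and splitFragments are refused for this kind
  expect_error(subselect(s1, "all"), "not implemented for this kind")
  expect_error(splitFragments(s1, "resid"), "not implemented for this kind")
  releaseSelection(s2)
  expect_equal(usedIndices(sys), 1:3)
  releaseSelection(s1)
  # fragmentation: parent claim exchanged for fragment claims, full coverage
  p <- selectAtoms(sys, "all")
  expect_equal(usedIndices(sys), 1:6)
  frags <- intoFragments(p, "resid")
  expect_equal(usedIndices(sys), 1:6)              # still fully covered
  expect_false(isAlive(p))
  expect_error(selectAtoms(sys, "index 0"), "overlapping")
  for (f in frags) releaseSelection(f)
  expect_equal(usedIndices(sys), integer(0))
})

test_that("registry claim/release bookkeeping is exact and errors on misuse", {
  sys <- gridSystem("MutableParallel", nRes = 2, atomsPerRes = 5)
  claimIndices(sys, 1:3)
  expect_equal(usedIndices(sys), 1:3)
  expect_error(claimIndices(sys, c(3L, 4L)), "index 3")
  releaseIndices(sys, 1:3)
  claimIndices(sys, c(3L, 4L))                      # free again after release
  expect_equal(usedIndices(sys), 3:4)
  releaseIndices(sys, integer(0))                   # no-op
  expect_equal(usedIndices(sys), 3:4)
  expect_error(releaseIndices(sys, 6L), "consistency")
})

test_that("registry equals a shadow-model union under randomized create/fragment/release", {
  sys <- toySystem("MutableParallel", seed = 31, nChains = 2,
                   resPerChain = 4, atomsPerRes = 4)
  n <- nAtoms(sys)
  live <- list()
  set.seed(12)
  for (step in 1:2000) {
    op <- sample(c("create", "release", "fragment"), 1,
                 prob = c(0.45, 0.35, 0.2))
    if (op == "create") {
      cand <- sort(sample(n, sample(1:8, 1)))
      shadow <- sort(unique(unlist(lapply(live, indices), use.names = FALSE)))
      if (length(intersect(cand, shadow))) {
        expect_error(selectIndices(sys, cand), "overlapping")
      } else {
        live[[length(live) + 1]] <- selectIndices(sys, cand)
      }
    } else if (op == "release" && length(live)) {
      k <- sample(length(live), 1)
      releaseSelection(live[[k]])
      live[[k]] <- NULL
    } else if (op == "fragment" && length(live)) {
      k <- sample(length(live), 1)
      frags <- intoFragments(live[[k]], function(idx, atoms) idx %% 2)
      live[[k]] <- NULL
      live <- c(live, frags)
    }
    shadow <- sort(unique(unlist(lapply(live, indices), use.names = FALSE)))
    if (length(shadow) == 0L) shadow <- integer(0)
    expect_identical(usedIndices(sys), shadow)
  }
})

test_that("BuilderSerial selections go stale on deletion but survive appends", {
  sys <- toySystem("BuilderSerial", seed = 3)
  sel <- selectAtoms(sys, "index 0-9")
  x0 <- coords(sel)
  addAtoms(sys, data.frame(name = "D1", resname = "DUM", resid = 99L,
                           chain = "Z"), matrix(0.3, 1, 3))
  expect_equal(coords(sel), x0)                    # append cannot invalidate
  deleteAtoms(sys, nAtoms(sys))
  expect_error(coords(sel), "invalidated by structural edit")
  expect_error(centerOfMass(sel), "invalidated")
  # selections created after the edit are valid
  sel2 <- selectAtoms(sys, "index 0-9")
  expect_equal(coords(sel2), x0)
})

test_that("serial kinds skip the validity check entirely on coordinate writes", {
  sys <- gridSystem("MutableSerial", nRes = 2, atomsPerRes = 3)
  sel <- selectAtoms(sys, "resid 1")
  for (k in 1:5) translateAtoms(sel, c(0.01, 0, 0))
  expect_equal(coords(sel)[, 1], cbind(0.1, 0.2, 0.3)[1:3] + 0.05)
})

test_that("structural edits are refused on non-builder kinds", {
  sys <- gridSystem("MutableSerial")
  expect_error(addAtoms(sys, data.frame(name = "D1", resname = "X",
                                        resid = 1L, chain = "A"),
                        matrix(0, 1, 3)),
               "structural edits require BuilderSerial")
  expect_error(deleteAtoms(sys, 1L), "BuilderSerial")
})
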