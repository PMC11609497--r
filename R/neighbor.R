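#' Distance-based neighbor search with a cell list
#'
#' Finds all atoms whose distance to any query atom is at most `cutoff`
#' (ties at exactly the cutoff are included). With a periodic box, distances
#' are minimum-image. The implementation bins atoms into a cell grid with
#' cells at least `cutoff` wide along each box height and scans the 27
#' neighboring cells of each occupied query cell; for triclinic boxes the
#' grid is built in fractional space and distance evaluation uses Cartesian
#' minimum image over the 27 neighboring lattice translations. If `cutoff`
#' exceeds half the smallest box height (where the cell-grid assumption
#' breaks), the search falls back to brute-force minimum image with a
#' warning.
#'
#' @param x N x 3 numeric coordinate matrix (nm).
#' @param query integer vector of 1-based query atom indices into `x`.
#' @param cutoff distance cutoff in nm (> 0).
#' @param box a [PeriodicBox-class] or NULL for aperiodic search.
#' @param includeQuery logical: should the query atoms themselves be part of
#'   the result (TRUE, default) or removed from it (FALSE)?
#' @return sorted integer vector of 1-based atom indices.
#' @examples
#' xyz <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(1.5, 0, 0))
#' searchWithin(xyz, 1L, 1.0)                     # 1 and 2
#' searchWithin(xyz, 1L, 1.0, includeQuery = FALSE)  # just 2
#' @export
searchWithin <- function(x, query, cutoff, box = NULL, includeQuery = TRUE) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) .stopUsage("searchWithin: coordinates must be N x 3")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    .stopUsage("searchWithin: cutoff must be a positive number")
  query <- sort(unique(as.integer(query)))
  if (length(query) == 0L) .stopUsage("searchWithin: empty query set")
  if (any(query < 1L) || any(query > nrow(x)))
    .stopUsage("searchWithin: query index out of range")
  res <- if (is.null(box)) {
    .searchCellFree(x, query, cutoff)
  } else {
    h <- .boxHeights(box)
    if (cutoff > min(h) / 2) {
      warning("cutoff exceeds half the smallest box height: falling back to brute-force minimum image",
              call. = FALSE)
      .searchBrutePBC(x, query, cutoff, box)
    } else {
      .searchCellPBC(x, query, cutoff, box)
    }
  }
  if (includeQuery) sort(unique(c(res, query))) else sort(setdiff(res, query))
}

# Cross squared distances between row sets (no periodicity).
.dist2 <- function(Q, C) {
  d2 <- outer(rowSums(Q^2), rowSums(C^2), "+") - 2 * tcrossprod(Q, C)
  d2[d2 < 0] <- 0
  d2
}

.searchBrutePBC <- function(x, query, cutoff, box) {
  d2 <- .minImageDist2(x[query, , drop = FALSE], x, box)
  which(apply(d2 <= cutoff^2, 2, any))
}

# Shared scan: given per-atom integer cell coordinates (N x 3), grid dims and
# a pair-distance function, collect all atoms within cutoff of any query atom.
.cellScan <- function(cell, dims, x, query, cutoff, periodic, pairDist2) {
  cid <- cell[, 1] + dims[1] * (cell[, 2] + dims[2] * cell[, 3])
  byCell <- split(seq_len(nrow(x)), cid)
  qByCell <- split(query, cid[query])
  cut2 <- cutoff^2
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  hits <- vector("list", length(qByCell))
  k <- 0L
  for (qs in qByCell) {
    k <- k + 1L
    c0 <- cell[qs[1], ]
    nb <- sweep(offsets, 2, c0, "+")
    if (periodic) {
      nb <- nb %% rep(dims, each = nrow(nb))
    } else {
      ok <- nb[, 1] >= 0 & nb[, 1] < dims[1] &
            nb[, 2] >= 0 & nb[, 2] < dims[2] &
            nb[, 3] >= 0 & nb[, 3] < dims[3]
      nb <- nb[ok, , drop = FALSE]
    }
    ncid <- unique(nb[, 1] + dims[1] * (nb[, 2] + dims[2] * nb[, 3]))
    cand <- unlist(byCell[as.character(ncid)], use.names = FALSE)
    if (is.null(cand) || length(cand) == 0L) next
    d2 <- pairDist2(x[qs, , drop = FALSE], x[cand, , drop = FALSE])
    hits[[k]] <- cand[colSums(d2 <= cut2) > 0L]
  }
  sort(unique(unlist(hits, use.names = FALSE)))
}

.searchCellFree <- function(x, query, cutoff) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  span <- pmax(hi - lo, 1e-9)
  dims <- pmax(1L, as.integer(floor(span / cutoff)))
  cs <- span / dims
  cell <- pmin(floor(sweep(sweep(x, 2, lo), 2, cs, "/")),
               matrix(rep(dims - 1L, each = nrow(x)), ncol = 3))
  storage.mode(cell) <- "integer"
  .cellScan(cell, dims, x, query, cutoff, periodic = FALSE, pairDist2 = .dist2)
}

.searchCellPBC <- function(x, query, cutoff, box) {
  m <- box@matrix
  f <- x %*% solve(m)
  f <- f - floor(f)
  h <- .boxHeights(box)
  dims <- pmax(1L, as.integer(floor(h / cutoff)))
  cell <- pmin(floor(sweep(f, 2, dims, "*")),
               matrix(rep(dims - 1L, each = nrow(x)), ncol = 3))
  storage.mode(cell) <- "integer"
  # rebuild wrapped Cartesian coordinates so the fractional binning and the
  # minimum-image distances agree
  xw <- f %*% m
  .cellScan(cell, dims, xw, query, cutoff, periodic = TRUE,
            pairDist2 = function(Q, C) .minImageDist2(Q, C, box))
}

# Per-atom neighbor lists within `cutoff` (excluding self), aperiodic.
# O(N) memory; used by sasa().
.neighborLists <- function(x, cutoff) {
  n <- nrow(x)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(x) - x[i, ])^2)
    nb <- which(d2 <= cutoff^2)
    out[[i]] <- nb[nb != i]
  }
  out
}
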