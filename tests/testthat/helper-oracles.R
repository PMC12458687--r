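# Independent oracles and tiny in-code fixtures used across the suite.

# circumsphere of 4 points (rows of P); NULL when (near-)coplanar
circumsphereOracle <- function(P) {
  A <- 2 * sweep(P[2:4, , drop = FALSE], 2, P[1, ])
  rhs <- rowSums(P[2:4, , drop = FALSE]^2) - sum(P[1, ]^2)
  if (abs(det(A)) < 1e-9) return(NULL)
  ctr <- as.numeric(solve(A, rhs))
  list(center = ctr, radius = sqrt(sum((ctr - P[1, ])^2)))
}

# all-C(n,4) brute-force alpha-sphere enumeration (no spatial pruning)
bruteAlphaSpheres <- function(xyz, rMin, rMax, tol = 1e-6) {
  n <- nrow(xyz)
  combos <- combn(n, 4)
  out <- list()
  for (c in seq_len(ncol(combos))) {
    idx <- combos[, c]
    cs <- circumsphereOracle(xyz[idx, , drop = FALSE])
    if (is.null(cs) || cs$radius < rMin || cs$radius > rMax) next
    d2 <- (xyz[, 1] - cs$center[1])^2 + (xyz[, 2] - cs$center[2])^2 +
      (xyz[, 3] - cs$center[3])^2
    d2[idx] <- Inf
    if (any(d2 < (cs$radius - tol)^2)) next
    out[[length(out) + 1L]] <- c(sort(idx), cs$center, cs$radius)
  }
  if (!length(out))
    return(data.frame(a1 = integer(), a2 = integer(), a3 = integer(),
                      a4 = integer(), x = numeric(), y = numeric(),
                      z = numeric(), radius = numeric()))
  m <- do.call(rbind, out)
  df <- data.frame(a1 = m[, 1], a2 = m[, 2], a3 = m[, 3], a4 = m[, 4],
                   x = m[, 5], y = m[, 6], z = m[, 7], radius = m[, 8])
  df[order(df$a1, df$a2, df$a3, df$a4), ]
}

# brute-force single-linkage partition via union-find on the pairwise graph
unionFindClusters <- function(centers, linkage) {
  n <- nrow(centers)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((centers[i, ] - centers[j, ])^2)) <= linkage) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, 1L)
}

# analytic volume of the union of two spheres (inclusion-exclusion with
# the spherical-lens overlap)
twoSphereUnionVolume <- function(r1, r2, d) {
  v <- 4 / 3 * pi * (r1^3 + r2^3)
  if (d >= r1 + r2) return(v)
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  v - lens
}

# analytic exposed area of two overlapping equal spheres
twoSphereExposedArea <- function(r, d) {
  if (d >= 2 * r) return(2 * 4 * pi * r^2)
  h <- r - d / 2  # height of each buried cap
  2 * (4 * pi * r^2 - 2 * pi * r * h)
}

# AUROC by explicit positive-negative pair counting (ties count 1/2)
pairCountAuroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# plain pairwise distances between row sets
crossDistO <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b)))
    out[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  out
}

# hand-built structure: n single-atom residues at given coordinates
pointStructure <- function(xyz, element = "C", resid = "ALA",
                           hetero = FALSE, b = 20,
                           modelKind = "experimental",
                           sourceId = "toy") {
  n <- nrow(xyz)
  StructureModel(data.frame(
    serial = seq_len(n), name = "CA",
    element = rep_len(element, n), resid = rep_len(resid, n),
    chain = "A", resno = seq_len(n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b = rep_len(b, n), hetero = rep_len(hetero, n),
    stringsAsFactors = FALSE), sourceId = sourceId,
    modelKind = modelKind)
}

# regular tetrahedron with given edge length, centered at the origin
tetrahedronCoords <- function(edge = 5) {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v * edge / sqrt(8)
}

# minimal hand-written PDB text: one ALA residue, four atoms
miniPDBLines <- function() c(
  "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 20.00           N",
  "ATOM      2  CA  ALA A   1       2.000   2.500   3.000  1.00 20.00           C",
  "ATOM      3  C   ALA A   1       3.000   2.000   3.500  1.00 20.00           C",
  "ATOM      4  O   ALA A   1       3.500   1.000   3.000  1.00 20.00           O",
  "END")

# quick labeled table with controllable class sizes
quickTable <- function(n = c(LBP = 60, nLBP = 80, PP = 400),
                       separation = 3, seed = 1L) {
  makeDescriptorTable(tableSpec(nPerClass = n, separation = separation,
                                seed = seed))
}
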