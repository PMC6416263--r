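# Deterministic geometric fixtures built in code.

# icosphere: subdivided icosahedron projected onto a sphere of radius r
icosphere <- function(subdiv = 3L, r = 1) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1)
  )
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdiv)) {
    mid <- new.env(parent = emptyenv())
    nv <- nrow(V)
    newF <- matrix(0L, nrow = 4L * nrow(F), ncol = 3L)
    getMid <- function(a, b) {
      key <- paste0(min(a, b), "_", max(a, b))
      id <- mid[[key]]
      if (!is.null(id)) return(id)
      V <<- rbind(V, (V[a, ] + V[b, ]) / 2)
      mid[[key]] <- nrow(V)
      nrow(V)
    }
    for (i in seq_len(nrow(F))) {
      a <- F[i, 1]; b <- F[i, 2]; c <- F[i, 3]
      ab <- getMid(a, b); bc <- getMid(b, c); ca <- getMid(c, a)
      newF[4 * i - 3, ] <- c(a, ab, ca)
      newF[4 * i - 2, ] <- c(ab, b, bc)
      newF[4 * i - 1, ] <- c(bc, c, ca)
      newF[4 * i, ] <- c(ab, bc, ca)
    }
    F <- newF
  }
  V <- V / sqrt(rowSums(V^2)) * r
  SurfaceMesh(V, F)
}

# axis-aligned closed box [0, s]^3 as 12 triangles
cubeMesh <- function(s = 1, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(0, s), c(0, s), c(0, s)))
  v <- sweep(v, 2L, origin, "+")
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7), c(1, 2, 5),
    c(2, 6, 5), c(3, 7, 4), c(4, 7, 8), c(1, 5, 3), c(3, 5, 7),
    c(2, 4, 6), c(4, 8, 6)
  )
  SurfaceMesh(v, f)
}

# independent associated-Legendre oracle (plain upward recurrence written
# against the textbook formulas, kept separate from the package's code path)
oracleLegendre <- function(l, m, x) {
  if (m == 0) {
    p0 <- rep(1, length(x)); p1 <- x
    if (l == 0) return(p0)
    if (l == 1) return(p1)
    for (k in 2:l) {
      p <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
      p0 <- p1; p1 <- p
    }
    return(p1)
  }
  # P_m^m via double factorial, Condon-Shortley phase
  dfact <- prod(seq(1, 2 * m - 1, by = 2))
  pmm <- (-1)^m * dfact * (1 - x^2)^(m / 2)
  if (l == m) return(pmm)
  pm1 <- x * (2 * m + 1) * pmm
  if (l == m + 1) return(pm1)
  for (k in (m + 2):l) {
    p <- ((2 * k - 1) * x * pm1 - (k + m - 1) * pmm) / (k - m)
    pmm <- pm1; pm1 <- p
  }
  pm1
}

# brute-force Spearman: average ranks then the Pearson formula, written out
oracleSpearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# small suite shared by the slower test files (4 models, coarse meshing)
smallSuite <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generateSuite(dStep = 27, nTheta = 48L, nPhi = 96L)
    }
    cache
  }
})

baseExtent <- function(mesh) {
  v <- meshVertices(mesh)
  b <- v[abs(v[, 3]) < 1e-8 * max(abs(v)), 1:2, drop = FALSE]
  sqrt(max(dist(b)^2))
}
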