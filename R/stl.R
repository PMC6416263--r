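#' Write a mesh as binary STL
#'
#' Binary little-endian STL with coordinates in mm.  Output is
#' deterministic: writing the same mesh twice produces byte-identical
#' files.
#'
#' @param mesh a [SurfaceMesh-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeSTL <- function(mesh, path) {
  V <- mesh@vertices
  F <- mesh@faces
  nf <- nrow(F)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  u <- b - a
  v <- c - a
  n <- cbind(
    u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1]
  )
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len

  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "spiculo binary STL (units: mm)"))
  writeBin(header[1:80], con)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  # 12 floats per facet (normal + 3 vertices), then a zero attribute count
  dat <- t(cbind(n, a, b, c))  # 12 x nf
  raw4 <- writeBin(as.vector(dat), raw(), size = 4L, endian = "little")
  m <- matrix(raw4, nrow = 48L)
  rec <- rbind(m, matrix(as.raw(0L), nrow = 2L, ncol = nf))
  writeBin(as.vector(rec), con)
  invisible(path)
}

#' Read a binary STL file as a SurfaceMesh
#'
#' Coincident facet corners (bitwise equal coordinates) are welded into
#' shared vertices so that closed surfaces read back watertight.
#'
#' @param path STL file path.
#' @return a [SurfaceMesh-class].
#' @export
readSTL <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!length(nf) || is.na(nf) || nf <= 0L) {
    stop("degenerate or unreadable STL: ", path)
  }
  raw <- readBin(con, "raw", n = nf * 50L)
  if (length(raw) < nf * 50L) stop("truncated STL: ", path)
  rec <- matrix(raw, nrow = 50L)
  vals <- readBin(as.vector(rec[1:48, ]), "numeric", n = 12L * nf,
                  size = 4L, endian = "little")
  vals <- matrix(vals, nrow = 12L)  # rows: normal, v1, v2, v3
  corners <- rbind(t(vals[4:6, ]), t(vals[7:9, ]), t(vals[10:12, ]))

  key <- paste(corners[, 1], corners[, 2], corners[, 3], sep = "|")
  first <- !duplicated(key)
  Vu <- corners[first, , drop = FALSE]
  id <- match(key, key[first])
  F <- cbind(id[seq_len(nf)], id[nf + seq_len(nf)], id[2L * nf + seq_len(nf)])
  SurfaceMesh(Vu, F)
}
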