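# Chamber voxelisation.
#
# Inside/outside classification by z-ray parity: for every (x, y) grid
# column the crossings of the column with the closed mesh are collected and
# voxel centres between successive crossing pairs are inside. A tiny
# deterministic offset of the grid origin avoids columns passing exactly
# through vertices or edges.

#' Voxelise the chamber interior
#'
#' Builds a cubic voxel grid (`resolution`^3) covering the mesh bounding box
#' with a small margin, and classifies voxel centres as inside/outside the
#' watertight mesh by ray parity along z.
#'
#' @param mesh an [EyeMesh-class] (must be closed; checked).
#' @param resolution voxels per axis (default 64).
#' @param margin margin around the bounding box, in voxels.
#' @return a [PhaseField-class] with `alpha = 0` everywhere (domain only).
#' @export
voxelizeChamber <- function(mesh, resolution = 64L, margin = 1.5) {
  vf <- meshVF(mesh)
  if (nrow(vf$f) == 0L) stop("empty mesh")
  checkClosed(vf$v, vf$f)
  n <- as.integer(resolution)
  if (n < 8L) stop("resolution too small")

  v <- vf$v; f <- vf$f
  lo <- apply(v, 2, min); hi <- apply(v, 2, max)
  ctr <- (lo + hi) / 2
  L <- max(hi - lo) * (1 + 2 * margin / n)
  pitch <- L / n
  # deterministic degeneracy-breaking offset
  origin <- ctr - L / 2 + pitch / 2 + 1.234567e-4 * pitch
  xs <- origin[1] + (seq_len(n) - 1L) * pitch
  ys <- origin[2] + (seq_len(n) - 1L) * pitch
  zs <- origin[3] + (seq_len(n) - 1L) * pitch

  # gather (column id, z) crossings face by face
  capN <- 8L * n * n
  colBuf <- integer(capN); zBuf <- numeric(capN); cnt <- 0L
  push <- function(cols, zv) {
    m <- length(cols)
    if (cnt + m > length(colBuf)) {
      colBuf <<- c(colBuf, integer(length(colBuf)))
      zBuf <<- c(zBuf, numeric(length(zBuf)))
    }
    colBuf[(cnt + 1L):(cnt + m)] <<- cols
    zBuf[(cnt + 1L):(cnt + m)] <<- zv
    cnt <<- cnt + m
  }

  # deterministic per-vertex xy jitter (consistent across shared edges, so
  # watertightness of the parity count is preserved) breaks exact
  # edge/vertex-through-column degeneracies
  hsh <- function(i, salt) {
    frac <- ((i * 2654435761 + salt) %% 65536) / 65536
    (frac - 0.5) * 1e-6 * pitch
  }
  vi <- seq_len(nrow(v))
  vj <- v
  vj[, 1] <- vj[, 1] + hsh(vi, 12345)
  vj[, 2] <- vj[, 2] + hsh(vi, 67890)
  P1 <- vj[f[, 1], , drop = FALSE]
  P2 <- vj[f[, 2], , drop = FALSE]
  P3 <- vj[f[, 3], , drop = FALSE]
  for (i in seq_len(nrow(f))) {
    x1 <- P1[i, 1]; y1 <- P1[i, 2]
    x2 <- P2[i, 1]; y2 <- P2[i, 2]
    x3 <- P3[i, 1]; y3 <- P3[i, 2]
    det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
    if (abs(det) < 1e-14) next                  # vertical face: measure zero
    ixr <- which(xs >= min(x1, x2, x3) & xs <= max(x1, x2, x3))
    iyr <- which(ys >= min(y1, y2, y3) & ys <= max(y1, y2, y3))
    if (!length(ixr) || !length(iyr)) next
    px <- rep(xs[ixr], times = length(iyr))
    py <- rep(ys[iyr], each = length(ixr))
    l1 <- ((x2 - px) * (y3 - py) - (x3 - px) * (y2 - py)) / det
    l2 <- ((x3 - px) * (y1 - py) - (x1 - px) * (y3 - py)) / det
    l3 <- 1 - l1 - l2
    hit <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(hit)) next
    zhit <- l1[hit] * P1[i, 3] + l2[hit] * P2[i, 3] + l3[hit] * P3[i, 3]
    ix <- rep(ixr, times = length(iyr))[hit]
    iy <- rep(iyr, each = length(ixr))[hit]
    push(ix + n * (iy - 1L), zhit)
  }
  if (cnt == 0L) stop("voxelisation found no crossings; is the mesh degenerate?")
  colBuf <- colBuf[seq_len(cnt)]; zBuf <- zBuf[seq_len(cnt)]

  ord <- order(colBuf, zBuf)
  colBuf <- colBuf[ord]; zBuf <- zBuf[ord]
  runs <- rle(colBuf)
  if (any(runs$lengths %% 2L != 0L))
    stop("odd crossing parity in ", sum(runs$lengths %% 2L != 0L),
         " columns; mesh may be open or degenerate")

  mask <- array(FALSE, dim = c(n, n, n))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    colId <- runs$values[k]
    zv <- zBuf[starts[k]:ends[k]]
    ix <- ((colId - 1L) %% n) + 1L
    iy <- ((colId - 1L) %/% n) + 1L
    for (p in seq(1L, length(zv), by = 2L)) {
      iz <- which(zs > zv[p] & zs < zv[p + 1L])
      if (length(iz)) mask[ix, iy, iz] <- TRUE
    }
  }

  new("PhaseField", alpha = array(0, dim = c(n, n, n)), mask = mask,
      origin = origin, pitch = pitch, fill = NA_real_, posture = "",
      converged = NA, sweeps = 0L, trace = data.frame())
}

#' @describeIn voxelizeChamber total volume of the voxelised domain (mm^3).
#' @param phase a [PhaseField-class].
#' @export
domainVolume <- function(phase) sum(phase@mask) * phase@pitch^3

#' @describeIn voxelizeChamber oil volume carried by the field (mm^3).
#' @export
oilVolume <- function(phase) sum(phase@alpha) * phase@pitch^3

# Voxel-centre coordinates along each axis.
gridAxes <- function(phase) {
  n <- dim(phase@mask)
  list(x = phase@origin[1] + (seq_len(n[1]) - 1L) * phase@pitch,
       y = phase@origin[2] + (seq_len(n[2]) - 1L) * phase@pitch,
       z = phase@origin[3] + (seq_len(n[3]) - 1L) * phase@pitch)
}

# Height along -gravity for every voxel centre, as an n^3 array (mm).
heightField <- function(phase, gravityDir) {
  ax <- gridAxes(phase)
  n <- dim(phase@mask)
  ux <- -gravityDir[1] * ax$x
  uy <- -gravityDir[2] * ax$y
  uz <- -gravityDir[3] * ax$z
  array(rep(ux, times = n[2] * n[3]), dim = n) +
    array(rep(rep(uy, each = n[1]), times = n[3]), dim = n) +
    array(rep(uz, each = n[1] * n[2]), dim = n)
}

#' Export a PhaseField as legacy-VTK structured points
#'
#' ASCII legacy VTK (STRUCTURED_POINTS) with the oil fraction and the domain
#' mask as point data, for inspection in ParaView.
#'
#' @param phase a [PhaseField-class].
#' @param file output path.
#' @export
writePhaseVTK <- function(phase, file) {
  n <- dim(phase@alpha)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "SiO phase field", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", n[1], n[2], n[3]),
               sprintf("ORIGIN %g %g %g", phase@origin[1], phase@origin[2],
                       phase@origin[3]),
               sprintf("SPACING %g %g %g", phase@pitch, phase@pitch,
                       phase@pitch),
               sprintf("POINT_DATA %d", prod(n)),
               "SCALARS alpha float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(phase@alpha), trim = TRUE), con)
  writeLines(c("SCALARS mask int 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.integer(phase@mask), trim = TRUE), con)
  invisible(file)
}
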