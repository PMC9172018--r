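# Parametric vitreous-chamber meshing.
#
# The chamber wall is a latitude/longitude ("ring ladder") triangulation of a
# sphere truncated by the planar lens cap, with one vertex ring placed
# exactly on the cap rim so the planar cap and the spherical wall share
# vertices and the mesh is watertight by construction. All three variants
# share the same connectivity: the staphyloma and cerclage are purely radial
# vertex displacements parameterised by the pre-deformation polar angle psi,
# so faces can be compared one-to-one across variants.

#' Build the triangulated chamber surface for a geometry variant
#'
#' Constructs the watertight wall mesh for one of the three morphologies:
#' `emmetropic` (truncated sphere plus planar lens cap), `staphyloma`
#' (posterior outpouching applied), or `staphyloma_cerclage` (outpouching
#' plus an encircling-band indentation at the equator).
#'
#' @param params an [EyeGeometryParams-class] object.
#' @param variant one of [eyeVariants()].
#' @return an [EyeMesh-class].
#' @examples
#' mesh <- buildEyeSurface(eyeGeometryParams(meshSubdivision = 4L), "emmetropic")
#' enclosedVolume(mesh)
#' @export
buildEyeSurface <- function(params = eyeGeometryParams(),
                            variant = c("emmetropic", "staphyloma",
                                        "staphyloma_cerclage")) {
  variant <- match.arg(variant)
  validObject(params)
  mesh <- buildTruncatedSphere(params)
  if (variant %in% c("staphyloma", "staphyloma_cerclage"))
    mesh <- applyStaphyloma(mesh, params)
  if (variant == "staphyloma_cerclage")
    mesh <- applyCerclage(mesh, params)
  mesh@variant <- variant
  validObject(mesh)   # hard failure with diagnostic if deformation broke it
  mesh
}

# Undeformed truncated sphere with planar cap; vertices organised as a ladder
# of azimuthal rings between the cap centre and the posterior pole.
buildTruncatedSphere <- function(params) {
  R <- params@sphereRadius
  h <- params@lensCapHeight
  nAz <- 3L * 2L^params@meshSubdivision
  psi0 <- if (h > 0) acos((R - h) / R) else 0

  dpsi <- 2 * pi / nAz                 # target angular spacing
  # ring latitudes snap to the segmentation knots (pars plana boundary,
  # equator, macula edge) so region boundaries fall exactly on vertex rings
  # and zone areas converge at O(h^2)
  knots <- sort(unique(c(psi0,
                         pi / 180 * params@parsPlanaBoundary,
                         pi / 2,
                         pi / 180 * (180 - params@maculaExtent),
                         pi)))
  knots <- knots[knots >= psi0 - 1e-12]
  psiWall <- psi0
  for (s in seq_len(length(knots) - 1L)) {
    len <- knots[s + 1L] - knots[s]
    nseg <- max(1L, round(len / dpsi))
    psiWall <- c(psiWall, knots[s] + len * seq_len(nseg) / nseg)
  }
  nWall <- length(psiWall) - 1L        # last entry = pole

  phi <- 2 * pi * (seq_len(nAz) - 1L) / nAz
  ringXY <- cbind(cos(phi), sin(phi))

  verts <- list(); psiV <- list(); restR <- list()
  ringStart <- integer(0)  # first vertex index of each full ring
  nV <- 0L

  addRing <- function(x, y, z, psiDeg, rr) {
    verts[[length(verts) + 1L]] <<- cbind(x, y, z)
    psiV[[length(psiV) + 1L]] <<- psiDeg
    restR[[length(restR) + 1L]] <<- rr
    ringStart <<- c(ringStart, nV + 1L)
    nV <<- nV + length(x)
  }
  addVertex <- function(p, psiDeg, rr) {
    verts[[length(verts) + 1L]] <<- matrix(p, 1L, 3L)
    psiV[[length(psiV) + 1L]] <<- psiDeg
    restR[[length(restR) + 1L]] <<- rr
    nV <<- nV + 1L
    nV
  }

  capRings <- 0L
  if (h > 0) {
    zCap <- R - h
    rRim <- R * sin(psi0)
    nCap <- max(1L, round(rRim / (R * dpsi)))
    apexIdx <- addVertex(c(0, 0, zCap), 0, zCap)  # cap centre, on the axis
    if (nCap > 1L) {
      for (k in seq_len(nCap - 1L)) {
        r <- rRim * k / nCap
        p <- cbind(r * ringXY[, 1], r * ringXY[, 2], zCap)
        psiDeg <- atan2(r, zCap) * 180 / pi
        addRing(p[, 1], p[, 2], p[, 3], rep(psiDeg, nAz),
                rep(sqrt(r^2 + zCap^2), nAz))
      }
    }
    capRings <- nCap - 1L
  } else {
    apexIdx <- addVertex(c(0, 0, R), 0, R)        # anterior pole
  }

  # spherical wall rings, the first exactly on the cap rim
  wallFrom <- if (h > 0) 1L else 2L   # psiWall[1] is 0 when h == 0 (pole)
  for (i in wallFrom:nWall) {
    ps <- psiWall[i]
    s <- R * sin(ps); z <- R * cos(ps)
    addRing(s * ringXY[, 1], s * ringXY[, 2], rep(z, nAz),
            rep(ps * 180 / pi, nAz), rep(R, nAz))
  }
  poleIdx <- addVertex(c(0, 0, -R), 180, R)       # posterior pole

  V <- do.call(rbind, verts)
  psiAll <- unlist(psiV)
  restAll <- unlist(restR)
  nRings <- length(ringStart)

  faces <- vector("list", nRings + 1L)
  capFlag <- vector("list", nRings + 1L)
  seqA <- seq_len(nAz); nxt <- c(seqA[-1L], 1L)
  # apex fan
  r1 <- ringStart[1L]
  faces[[1L]] <- cbind(apexIdx, r1 - 1L + seqA, r1 - 1L + nxt)
  capFlag[[1L]] <- rep(h > 0 && capRings >= 0L, nAz)  # refined below
  # ring-to-ring quads
  for (i in seq_len(nRings - 1L)) {
    a <- ringStart[i] - 1L; b <- ringStart[i + 1L] - 1L
    t1 <- cbind(a + seqA, b + seqA, b + nxt)
    t2 <- cbind(a + seqA, b + nxt, a + nxt)
    faces[[i + 1L]] <- rbind(t1, t2)
    # cap faces: both rings within the planar cap (ring index <= capRings + 1
    # counts the rim ring, whose quads belong to the wall, so strictly the
    # band between cap-interior rings)
    capFlag[[i + 1L]] <- rep(h > 0 && i <= capRings, 2L * nAz)
  }
  # pole fan
  rl <- ringStart[nRings] - 1L
  faces[[nRings + 1L]] <- cbind(poleIdx, rl + nxt, rl + seqA)
  capFlag[[nRings + 1L]] <- rep(FALSE, nAz)
  # apex fan is part of the cap only when a cap exists
  capFlag[[1L]] <- rep(h > 0, nAz)

  F <- do.call(rbind, faces)
  storage.mode(F) <- "integer"
  isCap <- unlist(capFlag)

  if (signedVolumeOf(V, F) < 0) F <- F[, c(1L, 3L, 2L)]

  new("EyeMesh", vertices = V, faces = F, psi = psiAll, restRadius = restAll,
      isCap = isCap, variant = "emmetropic", params = params)
}

#' Apply the posterior staphyloma outpouching
#'
#' Displaces vertices with pre-deformation polar angle psi >= the onset angle
#' radially outward by `staphylomaDepth * s(u)`, where
#' `u = (psi - onset) / (180 - onset)` and `s` is the cubic smoothstep
#' `3u^2 - 2u^3`. The junction is C1-smooth and the posterior pole moves by
#' exactly `staphylomaDepth`.
#'
#' @param mesh an [EyeMesh-class].
#' @param params an [EyeGeometryParams-class].
#' @return the deformed [EyeMesh-class].
#' @export
applyStaphyloma <- function(mesh, params = mesh@params) {
  u <- (mesh@psi - params@staphylomaOnset) / (180 - params@staphylomaOnset)
  u <- pmin(pmax(u, 0), 1)
  d <- params@staphylomaDepth * (3 * u^2 - 2 * u^3)
  displaceRadially(mesh, d)
}

#' Apply the encircling-band (cerclage) indentation
#'
#' Displaces vertices radially inward by
#' `cerclageDepth * exp(-(a / sigma)^2)`, where `a` is the meridional arc
#' distance from the equator (psi = 90 deg) on the undeformed sphere and
#' `sigma = cerclageWidth / 2`. The indentation is rotationally symmetric
#' about the optical axis.
#'
#' @inheritParams applyStaphyloma
#' @return the deformed [EyeMesh-class].
#' @export
applyCerclage <- function(mesh, params = mesh@params) {
  a <- params@sphereRadius * abs(mesh@psi - 90) * pi / 180
  sig <- params@cerclageWidth / 2
  d <- -params@cerclageDepth * exp(-(a / sig)^2)
  r <- sqrt(rowSums(mesh@vertices^2))
  if (any(r + d <= 0))
    stop("cerclage depth exceeds the local radius")
  displaceRadially(mesh, d)
}

displaceRadially <- function(mesh, d) {
  if (all(d == 0)) return(mesh)
  r <- sqrt(rowSums(mesh@vertices^2))
  scl <- (r + d) / r
  mesh@vertices <- mesh@vertices * scl
  mesh
}

#' Enclosed volume of a closed oriented mesh
#'
#' Divergence-theorem signed volume; positive for outward orientation. Fails
#' on an open mesh.
#'
#' @param mesh an [EyeMesh-class], or a list with elements `vertices` and
#'   `faces` for ad-hoc meshes.
#' @return volume in mm^3 (cubed vertex units).
#' @export
enclosedVolume <- function(mesh) {
  vf <- meshVF(mesh)
  checkClosed(vf$v, vf$f)
  signedVolumeOf(vf$v, vf$f)
}

#' @describeIn enclosedVolume per-face areas (mm^2).
#' @export
faceAreas <- function(mesh) {
  vf <- meshVF(mesh)
  faceAreasOf(vf$v, vf$f)
}

#' @describeIn enclosedVolume per-face outward unit normals.
#' @export
faceNormals <- function(mesh) {
  vf <- meshVF(mesh)
  v <- vf$v; f <- vf$f
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cr <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])
  cr / sqrt(rowSums(cr^2))
}

#' @describeIn enclosedVolume per-face centroids.
#' @export
faceCentroids <- function(mesh) {
  vf <- meshVF(mesh)
  (vf$v[vf$f[, 1], , drop = FALSE] + vf$v[vf$f[, 2], , drop = FALSE] +
     vf$v[vf$f[, 3], , drop = FALSE]) / 3
}

meshVF <- function(mesh) {
  if (is(mesh, "EyeMesh")) list(v = mesh@vertices, f = mesh@faces)
  else if (is.list(mesh) && all(c("vertices", "faces") %in% names(mesh)))
    list(v = mesh$vertices, f = mesh$faces)
  else stop("expected an EyeMesh or a list(vertices, faces)")
}

checkClosed <- function(v, f) {
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  if (any(cnt != 2L))
    stop("mesh is not closed: ", sum(cnt != 2L), " boundary/non-manifold edges")
  invisible(TRUE)
}

#' Export a mesh to OBJ or binary STL
#'
#' File name convention for the pipeline is `<variant>_<subdivision>.<ext>`.
#'
#' @param mesh an [EyeMesh-class].
#' @param file output path.
#' @param format "obj" (text, with per-vertex psi as a comment header) or
#'   "stl" (binary).
#' @export
writeMesh <- function(mesh, file, format = c("obj", "stl")) {
  format <- match.arg(format)
  v <- mesh@vertices; f <- mesh@faces
  if (format == "obj") {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(sprintf("# EyeMesh %s, %d vertices, %d faces",
                       mesh@variant, nrow(v), nrow(f)), con)
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else {
    n <- faceNormals(mesh)
    con <- file(file, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    tri <- array(0, dim = c(12L, nrow(f)))
    tri[1:3, ] <- t(n)
    tri[4:6, ] <- t(v[f[, 1], , drop = FALSE])
    tri[7:9, ] <- t(v[f[, 2], , drop = FALSE])
    tri[10:12, ] <- t(v[f[, 3], , drop = FALSE])
    for (i in seq_len(nrow(f))) {
      writeBin(tri[, i], con, size = 4L, endian = "little")
      writeBin(as.integer(0L), con, size = 2L, endian = "little")
    }
  }
  invisible(file)
}
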