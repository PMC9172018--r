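# Flat-interface (zero-capillarity) equilibrium.
#
# With interfacial tension neglected the buoyant oil occupies the region of
# the chamber above a horizontal plane (perpendicular to gravity). The plane
# offset is found by bisection on the enclosed volume above the plane;
# wetted areas use exact triangle-plane clipping, so partially wetted faces
# contribute their clipped fraction.

#' Flat-interface contact solver
#'
#' Finds the horizontal plane such that the chamber volume on the
#' anti-gravity side equals `fill` times the chamber volume (oil floats),
#' then reports per-region SiO contact by exact triangle clipping. This is
#' both the zero-capillarity baseline and the initialiser for
#' [minimizeCapillaryEnergy()].
#'
#' @param mesh an [EyeMesh-class].
#' @param map a [RegionMap-class] for the mesh.
#' @param fill oil fill fraction in [0, 1] (fraction of chamber volume).
#' @param posture a [Posture-class].
#' @param tol bisection tolerance as a fraction of the chamber volume.
#' @return a [ContactReport-class]; `meta` carries the plane offset
#'   (`planeHeight`, mm along -gravity), the contact-line length per region
#'   and in total (mm), and `method = "flat"`.
#' @export
solveFlatInterface <- function(mesh, map, fill, posture, tol = 1e-6) {
  if (!is.numeric(fill) || length(fill) != 1L || fill < 0 || fill > 1)
    stop("fill must be a single number in [0, 1]")
  g <- posture@gravityDir
  v <- mesh@vertices
  u <- unname(-(v %*% g)[, 1])               # height along -gravity, mm
  V <- enclosedVolume(mesh)
  target <- fill * V

  if (fill == 0 || fill == 1) {
    frac <- rep(as.numeric(fill), nrow(mesh@faces))
    h <- if (fill == 1) min(u) else max(u)
    return(buildContactReport(mesh, map, frac, fill, posture@name,
                              meta = list(method = "flat", planeHeight = h,
                                          lineLength = 0,
                                          lineLengthByRegion = NULL)))
  }

  lo <- min(u) - 1e-9; hi <- max(u) + 1e-9
  # volumeAbove(lo) = V, volumeAbove(hi) = 0 (decreasing in h)
  h <- NA_real_
  for (it in seq_len(200L)) {
    h <- (lo + hi) / 2
    va <- volumeAbovePlane(mesh, u, g, h)
    if (abs(va - target) <= tol * V) break
    if (va > target) lo <- h else hi <- h
    if (hi - lo < 1e-14 * (max(u) - min(u))) break
  }

  clip <- clipAreasAbove(mesh, u, h)
  report <- buildContactReport(mesh, map, clip$frac, fill, posture@name,
                               meta = list(method = "flat", planeHeight = h,
                                           lineLength = clip$lineLength,
                                           lineLengthByRegion = clip$lineByRegion(map)))
  report
}

# Volume of the part of the closed mesh with u >= h. Uses a reference point
# on the plane so the planar cut cap contributes nothing to the signed sum.
volumeAbovePlane <- function(mesh, u, g, h) {
  v <- mesh@vertices; f <- mesh@faces
  p0 <- -g * h                                  # a point with u(p0) = h
  u1 <- u[f[, 1]]; u2 <- u[f[, 2]]; u3 <- u[f[, 3]]
  allIn <- u1 >= h & u2 >= h & u3 >= h
  allOut <- u1 <= h & u2 <= h & u3 <= h
  vol <- 0
  if (any(allIn)) {
    fi <- f[allIn, , drop = FALSE]
    a <- sweep(v[fi[, 1], , drop = FALSE], 2, p0)
    b <- sweep(v[fi[, 2], , drop = FALSE], 2, p0)
    c <- sweep(v[fi[, 3], , drop = FALSE], 2, p0)
    vol <- vol + sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
                     a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
                     a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  }
  straddle <- which(!allIn & !allOut)
  for (i in straddle) {
    tris <- clipTriAbove(v[f[i, ], , drop = FALSE], u[f[i, ]], h)$tris
    for (tr in tris) {
      a <- tr[1, ] - p0; b <- tr[2, ] - p0; c <- tr[3, ] - p0
      vol <- vol + (a[1] * (b[2] * c[3] - b[3] * c[2]) +
                    a[2] * (b[3] * c[1] - b[1] * c[3]) +
                    a[3] * (b[1] * c[2] - b[2] * c[1])) / 6
    }
  }
  unname(vol)
}

# Wetted (u >= h) area fraction per face plus contact-line bookkeeping.
clipAreasAbove <- function(mesh, u, h) {
  v <- mesh@vertices; f <- mesh@faces
  A <- faceAreasOf(v, f)
  u1 <- u[f[, 1]]; u2 <- u[f[, 2]]; u3 <- u[f[, 3]]
  frac <- numeric(nrow(f))
  frac[u1 >= h & u2 >= h & u3 >= h] <- 1
  straddle <- which(!(u1 >= h & u2 >= h & u3 >= h) &
                    !(u1 <= h & u2 <= h & u3 <= h))
  segLen <- numeric(nrow(f))
  for (i in straddle) {
    cl <- clipTriAbove(v[f[i, ], , drop = FALSE], u[f[i, ]], h)
    aw <- sum(vapply(cl$tris, triArea, numeric(1)))
    frac[i] <- min(1, aw / A[i])
    segLen[i] <- cl$segLen
  }
  list(frac = frac, lineLength = sum(segLen),
       lineByRegion = function(map) tapply(segLen, map@region, sum))
}

# Clip one triangle to the half-space u >= h (Sutherland-Hodgman, which
# preserves the winding order so signed volumes stay consistent); returns
# the kept sub-triangles and the length of the intersection segment.
clipTriAbove <- function(P, uu, h) {
  inside <- uu >= h
  if (all(inside)) return(list(tris = list(P), segLen = 0))
  if (!any(inside)) return(list(tris = list(), segLen = 0))
  out <- vector("list", 4L); nOut <- 0L
  cross <- vector("list", 2L); nCross <- 0L
  for (k in 1:3) {
    k2 <- if (k == 3L) 1L else k + 1L
    if (inside[k]) { nOut <- nOut + 1L; out[[nOut]] <- P[k, ] }
    if (inside[k] != inside[k2]) {
      t <- (h - uu[k]) / (uu[k2] - uu[k])
      p <- P[k, ] + t * (P[k2, ] - P[k, ])
      nOut <- nOut + 1L; out[[nOut]] <- p
      nCross <- nCross + 1L; cross[[nCross]] <- p
    }
  }
  tris <- lapply(seq_len(nOut - 2L), function(j)
    rbind(out[[1L]], out[[j + 1L]], out[[j + 2L]]))
  segLen <- if (nCross == 2L) sqrt(sum((cross[[1L]] - cross[[2L]])^2)) else 0
  list(tris = tris, segLen = segLen)
}

triArea <- function(tr) {
  ab <- tr[2, ] - tr[1, ]; ac <- tr[3, ] - tr[1, ]
  cr <- c(ab[2] * ac[3] - ab[3] * ac[2],
          ab[3] * ac[1] - ab[1] * ac[3],
          ab[1] * ac[2] - ab[2] * ac[1])
  0.5 * sqrt(sum(cr^2))
}

# Shared ContactReport assembly from a per-face wetted fraction.
buildContactReport <- function(mesh, map, faceWetted, fill, postureName,
                               meta = list()) {
  A <- map@faceArea
  grid <- expand.grid(region = regionLevels(),
                      hemifield = c("superior", "inferior"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- mapply(function(r, hf) {
    sel <- map@region == r & map@hemifield == hf
    a <- sum(A[sel]); w <- sum(A[sel] * faceWetted[sel])
    c(a, w)
  }, grid$region, grid$hemifield)
  tab <- data.frame(region = grid$region, hemifield = grid$hemifield,
                    area_mm2 = rows[1, ], wetted_mm2 = rows[2, ],
                    stringsAsFactors = FALSE)
  tab <- tab[tab$area_mm2 > 0, ]
  tab$contact_pct <- 100 * tab$wetted_mm2 / tab$area_mm2
  rownames(tab) <- NULL
  nonLens <- map@region != "lens"
  overall <- 100 * sum(A[nonLens] * faceWetted[nonLens]) / sum(A[nonLens])
  new("ContactReport", variant = mesh@variant, posture = postureName,
      fill = fill, table = tab, overall = overall,
      faceWetted = as.numeric(faceWetted), meta = meta)
}

#' Accessors for ContactReport
#'
#' `contactTable()` returns the per-(region, hemifield) table;
#' `overallContact()` the area-weighted overall percentage (non-lens
#' denominator); `regionContact()` a single region's pooled percentage
#' (hemifields combined unless one is requested).
#'
#' @param report a [ContactReport-class].
#' @export
contactTable <- function(report) report@table

#' @rdname contactTable
#' @export
overallContact <- function(report) report@overall

#' @rdname contactTable
#' @param region region name.
#' @param hemifield optional "superior" or "inferior".
#' @export
regionContact <- function(report, region, hemifield = NULL) {
  tab <- report@table
  sel <- tab$region == region
  if (!is.null(hemifield)) sel <- sel & tab$hemifield == hemifield
  if (!any(sel)) return(NA_real_)
  100 * sum(tab$wetted_mm2[sel]) / sum(tab$area_mm2[sel])
}

#' @rdname contactTable
#' @export
hemifieldContact <- function(report, hemifield) {
  tab <- report@table
  sel <- tab$hemifield == hemifield & tab$region != "lens"
  100 * sum(tab$wetted_mm2[sel]) / sum(tab$area_mm2[sel])
}
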