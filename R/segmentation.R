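# Retinal surface segmentation.
#
# Faces are labelled from the face-mean pre-deformation polar angle psi, so
# the same face carries the same label in all three variants (deformation
# invariance); only the cerclage variant relabels band faces whose inward
# indentation exceeds half of the maximum indent. Hemifields split on the
# sign of the face-centroid y coordinate (ties go superior).

#' Label mesh faces into retinal regions and hemifields
#'
#' Regions follow the clinical partition: lens (planar cap faces), pars
#' plana (cap rim to `parsPlanaBoundary`), pre-equatorial retina (boundary
#' to 90 deg), post-equatorial retina (90 deg to `180 - maculaExtent`),
#' macula (a `maculaExtent`-degree polar cone about the posterior pole), and
#' `cerclage_band` in the banded variant.
#'
#' @param mesh an [EyeMesh-class] carrying pre-deformation psi per vertex.
#' @param params geometry parameters; defaults to those stored in the mesh.
#' @param variant variant controlling band relabelling; defaults to the
#'   mesh's variant.
#' @return a [RegionMap-class].
#' @export
labelRegions <- function(mesh, params = mesh@params, variant = mesh@variant) {
  psiF <- rowMeans(matrix(mesh@psi[mesh@faces], ncol = 3L))
  lab <- rep(NA_character_, nrow(mesh@faces))
  lab[mesh@isCap] <- "lens"
  open <- !mesh@isCap
  lab[open & psiF < params@parsPlanaBoundary] <- "pars_plana"
  lab[open & psiF >= params@parsPlanaBoundary & psiF < 90] <- "pre_equatorial"
  lab[open & psiF >= 90 & psiF < 180 - params@maculaExtent] <- "post_equatorial"
  lab[open & psiF >= 180 - params@maculaExtent] <- "macula"

  if (variant == "staphyloma_cerclage" && params@cerclageDepth > 0) {
    a <- params@sphereRadius * abs(psiF - 90) * pi / 180
    indent <- exp(-(a / (params@cerclageWidth / 2))^2)
    lab[open & indent > 0.5] <- "cerclage_band"
  }
  if (anyNA(lab)) stop("internal error: unlabeled face")

  cy <- faceCentroids(mesh)[, 2]
  hemi <- ifelse(cy >= 0, "superior", "inferior")

  new("RegionMap",
      region = factor(lab, levels = regionLevels()),
      hemifield = factor(hemi, levels = c("superior", "inferior")),
      faceArea = faceAreas(mesh),
      variant = variant)
}

#' Region area table
#'
#' Areas per (region, hemifield) and their share of the retinal surface. The
#' denominator for shares is the total area minus the lens faces; lens rows
#' carry `NA` shares. Non-lens shares sum to 100.
#'
#' @param map a [RegionMap-class].
#' @return data.frame with columns region, hemifield, area_mm2, share_pct.
#' @export
regionAreas <- function(map) {
  grid <- expand.grid(region = regionLevels(),
                      hemifield = c("superior", "inferior"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  area <- mapply(function(r, h)
    sum(map@faceArea[map@region == r & map@hemifield == h]),
    grid$region, grid$hemifield)
  retinal <- sum(map@faceArea[map@region != "lens"])
  share <- ifelse(grid$region == "lens", NA_real_, 100 * area / retinal)
  out <- data.frame(region = grid$region, hemifield = grid$hemifield,
                    area_mm2 = as.numeric(area), share_pct = share,
                    stringsAsFactors = FALSE)
  out <- out[out$area_mm2 > 0, ]
  rownames(out) <- NULL
  out
}

#' Export per-face region labels as an OBJ with face groups
#'
#' Visual-inspection helper: one `g <region>` group per region so any OBJ
#' viewer can colour regions independently.
#' @param mesh an [EyeMesh-class].
#' @param map the matching [RegionMap-class].
#' @param file output path.
#' @export
writeRegionsOBJ <- function(mesh, map, file) {
  con <- file(file, "w")
  on.exit(close(con))
  v <- mesh@vertices
  writeLines(sprintf("# EyeMesh %s regions", mesh@variant), con)
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  for (r in regionLevels()) {
    idx <- which(map@region == r)
    if (!length(idx)) next
    writeLines(sprintf("g %s", r), con)
    f <- mesh@faces[idx, , drop = FALSE]
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(file)
}
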