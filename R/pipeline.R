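# Sweep orchestration: (variant x posture x fill) contact reports, the
# derived figure-style tables, and deterministic CSV/JSON export.

#' Sweep configuration
#'
#' All knobs of a contact sweep in one validated list. The defaults are the
#' study conditions: all three geometry variants, the three postures, fills
#' 80-100% in 5% steps.
#'
#' @param geometry an [EyeGeometryParams-class].
#' @param variants subset of [eyeVariants()].
#' @param postures subset of [postureNames()].
#' @param fills fill percentages in [0, 100].
#' @param resolution voxel grid resolution per axis.
#' @param fluids a [FluidProperties-class].
#' @param coarseInit warm-start fine solves from half resolution.
#' @param opts solver options passed to [minimizeCapillaryEnergy()].
#' @param outputDir optional directory for CSV/JSON export.
#' @param seed reserved; the default solvers are deterministic and use no
#'   RNG.
#' @return a list of class `sweepConfig`.
#' @export
sweepConfig <- function(geometry = eyeGeometryParams(),
                        variants = eyeVariants(),
                        postures = postureNames(),
                        fills = c(80, 85, 90, 95, 100),
                        resolution = 64L,
                        fluids = fluidProperties(),
                        coarseInit = TRUE,
                        opts = list(),
                        outputDir = NULL,
                        seed = NULL) {
  stopifnot(length(variants) >= 1L, length(postures) >= 1L,
            all(variants %in% eyeVariants()),
            all(postures %in% postureNames()),
            all(fills >= 0 & fills <= 100))
  structure(list(geometry = geometry, variants = variants,
                 postures = postures, fills = fills,
                 resolution = as.integer(resolution), fluids = fluids,
                 coarseInit = coarseInit, opts = opts,
                 outputDir = outputDir, seed = seed),
            class = "sweepConfig")
}

#' Read a sweep configuration from YAML
#'
#' Keys mirror [sweepConfig()] arguments; `geometry` and `fluids` are nested
#' maps whose keys match the respective constructor arguments.
#'
#' @param path YAML file path.
#' @return a `sweepConfig`.
#' @export
readSweepConfig <- function(path) {
  y <- yaml::read_yaml(path)
  geo <- do.call(eyeGeometryParams, as.list(y$geometry))
  flu <- do.call(fluidProperties, as.list(y$fluids))
  args <- y[setdiff(names(y), c("geometry", "fluids"))]
  do.call(sweepConfig, c(list(geometry = geo, fluids = flu), args))
}

#' Run a contact sweep
#'
#' Solves the static equilibrium for every (variant, posture, fill) case in
#' the configuration and collects region-level and overall results in long
#' format with full provenance columns. Per-case failures are recorded and
#' the sweep continues; the result carries a `failed` attribute.
#'
#' @param config a [sweepConfig()].
#' @param verbose print per-case progress.
#' @return list of class `tamponadeSweep`: `results` (region rows),
#'   `overall` (one row per case), `reports` (named [ContactReport-class]
#'   list), `config`.
#' @export
runSweep <- function(config = sweepConfig(), verbose = FALSE) {
  fills <- sort(config$fills)
  regionRows <- list(); overallRows <- list(); reports <- list()
  failures <- character(0)
  for (variant in config$variants) {
    mesh <- buildEyeSurface(config$geometry, variant)
    map <- labelRegions(mesh)
    domains <- list(fine = voxelizeChamber(mesh, config$resolution),
                    coarse = if (config$coarseInit && config$resolution >= 48L)
                      voxelizeChamber(mesh,
                                      max(24L, config$resolution %/% 2L)))
    for (post in config$postures) {
      po <- posture(post)
      for (fillPct in fills) {
        caseId <- sprintf("%s|%s|%g", variant, post, fillPct)
        res <- tryCatch(
          solveEquilibrium(mesh, map, fillPct / 100, po,
                           fluids = config$fluids,
                           resolution = config$resolution,
                           coarseInit = config$coarseInit,
                           opts = config$opts, domains = domains),
          error = function(e) e)
        if (inherits(res, "error")) {
          failures <- c(failures, paste0(caseId, ": ", conditionMessage(res)))
          next
        }
        rep <- res$report
        tab <- rep@table
        tab$variant <- variant; tab$posture <- post; tab$fill_pct <- fillPct
        tab$resolution <- config$resolution
        tab$sweeps <- res$phase@sweeps
        tab$converged <- res$phase@converged
        regionRows[[caseId]] <- tab
        overallRows[[caseId]] <- data.frame(
          variant = variant, posture = post, fill_pct = fillPct,
          overall_contact_pct = rep@overall,
          inferior_contact_pct = hemifieldContact(rep, "inferior"),
          superior_contact_pct = hemifieldContact(rep, "superior"),
          resolution = config$resolution, sweeps = res$phase@sweeps,
          converged = res$phase@converged, stringsAsFactors = FALSE)
        reports[[caseId]] <- rep
        if (verbose)
          message(sprintf("%-40s overall %.1f%% (%d sweeps)", caseId,
                          rep@overall, res$phase@sweeps))
      }
    }
  }
  results <- do.call(rbind, c(regionRows, list(make.row.names = FALSE)))
  overall <- do.call(rbind, c(overallRows, list(make.row.names = FALSE)))
  cols <- c("variant", "posture", "fill_pct", "region", "hemifield",
            "area_mm2", "wetted_mm2", "contact_pct", "resolution", "sweeps",
            "converged")
  results <- results[, cols]
  out <- structure(list(results = results, overall = overall,
                        reports = reports, config = config),
                   class = "tamponadeSweep")
  attr(out, "failed") <- failures
  if (length(failures))
    warning(length(failures), " case(s) failed: ",
            paste(failures, collapse = "; "))
  if (!is.null(config$outputDir)) writeSweepCSV(out, config$outputDir)
  out
}

#' Write sweep outputs as CSV
#'
#' Deterministic long-format CSVs (`contact_regions.csv`,
#' `contact_overall.csv`); identical configurations reproduce byte-identical
#' files.
#'
#' @param sweep a `tamponadeSweep`.
#' @param dir output directory (created if needed).
#' @export
writeSweepCSV <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sweep$results, file.path(dir, "contact_regions.csv"),
                   row.names = FALSE)
  utils::write.csv(sweep$overall, file.path(dir, "contact_overall.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Figure-style summary tables
#'
#' Pivots of the sweep results mirroring the panel structure of the contact
#' figures: overall contact vs fill per posture (one column per variant),
#' superior and inferior pre-/post-equatorial contact vs fill, and the
#' regional breakdown at 90% fill. Missing cells are explicit `NA` with a
#' warning.
#'
#' @param sweep a `tamponadeSweep`.
#' @return list of data.frames: `overallByPosture`, `superiorQuadrants`,
#'   `inferiorQuadrants`, `regional90`.
#' @export
summarizeFigures <- function(sweep) {
  ov <- sweep$overall
  res <- sweep$results
  pivot <- function(df, value) {
    out <- stats::reshape(df[, c("posture", "fill_pct", "variant", value)],
                          direction = "wide", idvar = c("posture", "fill_pct"),
                          timevar = "variant")
    names(out) <- sub(paste0(value, "."), "", names(out), fixed = TRUE)
    rownames(out) <- NULL
    out
  }
  overallByPosture <- pivot(ov, "overall_contact_pct")
  if (anyNA(overallByPosture))
    warning("missing sweep cells; NA left in summary tables")

  quad <- function(hemi) {
    sub <- res[res$hemifield == hemi &
                 res$region %in% c("pre_equatorial", "post_equatorial"), ]
    agg <- stats::aggregate(cbind(wetted_mm2, area_mm2) ~
                              variant + posture + fill_pct + region,
                            data = sub, FUN = sum)
    agg$contact_pct <- 100 * agg$wetted_mm2 / agg$area_mm2
    agg[order(agg$region, agg$posture, agg$variant, agg$fill_pct),
        c("region", "posture", "variant", "fill_pct", "contact_pct")]
  }

  reg90 <- res[res$fill_pct == 90, ]
  regional90 <- if (nrow(reg90)) {
    agg <- stats::aggregate(cbind(wetted_mm2, area_mm2) ~
                              variant + posture + region, data = reg90,
                            FUN = sum)
    agg$contact_pct <- 100 * agg$wetted_mm2 / agg$area_mm2
    agg[order(agg$posture, agg$variant, agg$region),
        c("posture", "variant", "region", "contact_pct")]
  } else data.frame()

  list(overallByPosture = overallByPosture,
       superiorQuadrants = quad("superior"),
       inferiorQuadrants = quad("inferior"),
       regional90 = regional90)
}

#' Plot overall contact vs fill (one panel per posture)
#'
#' Thin ggplot2 helper over the sweep's overall table; returns the plot
#' object (ggplot2 must be installed).
#'
#' @param sweep a `tamponadeSweep`.
#' @export
plotOverallContact <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ov <- sweep$overall
  ggplot2::ggplot(ov, ggplot2::aes(x = .data$fill_pct,
                                   y = .data$overall_contact_pct,
                                   colour = .data$variant)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~posture) +
    ggplot2::labs(x = "SiO fill (% of chamber volume)",
                  y = "retinal surface in contact with SiO (%)") +
    ggplot2::ylim(0, 100)
}

#' @export
print.tamponadeSweep <- function(x, ...) {
  cat(sprintf("tamponadeSweep: %d case(s), resolution %d^3\n",
              nrow(x$overall), x$config$resolution))
  print(utils::head(x$overall, 12), row.names = FALSE)
  invisible(x)
}
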