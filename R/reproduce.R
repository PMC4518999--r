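# TSV export and the figure-reproduction driver. All numerics are
# serialized with 9 significant digits so repeated runs with the same
# configuration are byte-identical; infeasible phase-plane cells are
# written as explicit NA tokens, never zeros.

.fmt9 <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 9, format = "g"))
}

#' Export flux vectors, FVA tables, grids and envelopes as TSV
#'
#' @param x an [FBAResult-class], FVA data.frame, [PhasePlaneGrid-class] or
#'   [ProductionEnvelope-class].
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
exportTSV <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is(x, "FBAResult")) {
    writeLines("reaction\tflux", con)
    for (i in seq_along(x@fluxes)) {
      writeLines(paste(names(x@fluxes)[i], .fmt9(x@fluxes[i]), sep = "\t"), con)
    }
  } else if (is.data.frame(x) && all(c("reaction", "min_flux") %in% names(x))) {
    writeLines("reaction\tmin_flux\tmax_flux", con)
    for (i in seq_len(nrow(x))) {
      writeLines(paste(x$reaction[i], .fmt9(x$min_flux[i]),
                       .fmt9(x$max_flux[i]), sep = "\t"), con)
    }
  } else if (is(x, "PhasePlaneGrid")) {
    writeLines(paste(c(paste0(x@xId, "\\", x@yId), .fmt9(x@y)),
                     collapse = "\t"), con)
    for (i in seq_along(x@x)) {
      writeLines(paste(c(.fmt9(x@x[i]), .fmt9(x@growth[i, ])),
                       collapse = "\t"), con)
    }
  } else if (is(x, "ProductionEnvelope")) {
    writeLines("growth\tmin_product\tmax_product", con)
    for (i in seq_along(x@growth)) {
      writeLines(paste(.fmt9(x@growth[i]), .fmt9(x@minProduct[i]),
                       .fmt9(x@maxProduct[i]), sep = "\t"), con)
    }
  } else {
    stop("no TSV export for objects of class ", class(x)[1L], call. = FALSE)
  }
  invisible(path)
}

#' Reproduce the strain phase planes and growth envelopes
#'
#' Regenerates, for each named strain of the constrained core model, the
#' phenotypic phase-plane surface over (glucose uptake, ethanol secretion)
#' and the ethanol production envelope, writing one TSV per figure panel
#' plus a JSON manifest echoing the configuration. Deterministic given the
#' configuration.
#'
#' @param dir output directory (created if needed).
#' @param strains strain names (default all four).
#' @param glucose_uptake glucose uptake bound (default 10).
#' @param h2_yield_cap hydrogen yield cap (default 0.9).
#' @param n_points grid resolution (default 50; phase planes use it per
#'   axis, so cost grows quadratically).
#' @return invisibly, a list of the computed objects.
#' @export
reproduceFigures <- function(dir, strains = c("WT", "ldh_pta", "ldh_hfs",
                                              "ldh_hfs_glud"),
                             glucose_uptake = 10, h2_yield_cap = 0.9,
                             n_points = 50) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  core <- applyHydrogenaseConstraints(
    buildCoreModel(glucose_uptake = glucose_uptake),
    hydrogenaseConstraintSet(h2_yield_cap = h2_yield_cap))
  out <- list()
  for (s in strains) {
    sm <- strainModel(core, s)
    pp <- phasePlane(sm, "EX_glc", "EX_etoh",
                     x_range = c(-glucose_uptake, 0),
                     y_range = c(0, 2 * glucose_uptake),
                     n_points = n_points)
    env <- productionEnvelope(sm, "EX_etoh", n_points = n_points)
    exportTSV(pp, file.path(dir, sprintf("phase_plane_%s.tsv", s)))
    exportTSV(env, file.path(dir, sprintf("envelope_%s.tsv", s)))
    out[[s]] <- list(phase_plane = pp, envelope = env)
  }
  manifest <- list(package = "thermoflux",
                   version = as.character(utils::packageVersion("thermoflux")),
                   strains = strains, glucose_uptake = glucose_uptake,
                   h2_yield_cap = h2_yield_cap, n_points = n_points)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
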