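#' Stoichiometric metabolic model
#'
#' Central container for a constraint-based metabolic model: metabolites,
#' reactions with flux bounds and gene-protein-reaction (GPR) rules, an
#' objective reaction (typically biomass), and optional extra linear
#' inequality constraints over fluxes (used e.g. for the hydrogen yield cap,
#' which must couple \eqn{v_{H_2}} to glucose uptake rather than fix a
#' bound).
#'
#' Flux units are mmol gDW\eqn{^{-1}} h\eqn{^{-1}}; the biomass flux is in
#' h\eqn{^{-1}}. Exchange reactions are written \code{met[e] ->} so that
#' positive flux is secretion and negative flux is uptake.
#'
#' @slot metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment}, \code{formula} (empty string when unknown).
#' @slot reactions data.frame with columns \code{id}, \code{name},
#'   \code{lower_bound}, \code{upper_bound}, \code{gene_rule} (boolean
#'   expression over gene ids with \code{&}, \code{|}, parentheses; empty
#'   means no gene associated), \code{is_exchange}.
#' @slot stoichiometry named list, one element per reaction id, each a named
#'   numeric vector of signed coefficients over metabolite ids (negative =
#'   consumed).
#' @slot objectiveId character, the id of the objective (biomass) reaction;
#'   may be empty for fragments.
#' @slot compartments named character vector of declared compartments.
#' @slot extraConstraints list of linear constraints, each
#'   \code{list(coefficients = <named numeric over reaction ids>,
#'   sense = "<="|">="|"=", rhs = <number>)}.
#' @slot annotations list of opaque fields preserved by the readers/writers.
#'
#' @seealso [readModel()], [validateModel()], [solveFBA()], [buildCoreModel()]
#' @export
setClass("MetabolicModel",
  representation(
    metabolites = "data.frame",
    reactions = "data.frame",
    stoichiometry = "list",
    objectiveId = "character",
    compartments = "character",
    extraConstraints = "list",
    annotations = "list"
  ),
  prototype(
    metabolites = data.frame(id = character(), name = character(),
                             compartment = character(), formula = character(),
                             stringsAsFactors = FALSE),
    reactions = data.frame(id = character(), name = character(),
                           lower_bound = numeric(), upper_bound = numeric(),
                           gene_rule = character(), is_exchange = logical(),
                           stringsAsFactors = FALSE),
    stoichiometry = list(),
    objectiveId = character(),
    compartments = c(c = "cytosol", e = "extracellular"),
    extraConstraints = list(),
    annotations = list()
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character()
  met <- object@metabolites
  rxn <- object@reactions
  need_m <- c("id", "name", "compartment", "formula")
  need_r <- c("id", "name", "lower_bound", "upper_bound", "gene_rule",
              "is_exchange")
  if (!all(need_m %in% names(met))) {
    msg <- c(msg, "metabolites must have columns id, name, compartment, formula")
  }
  if (!all(need_r %in% names(rxn))) {
    msg <- c(msg, paste("reactions must have columns", paste(need_r, collapse = ", ")))
  }
  if (length(msg)) return(msg)
  if (nrow(rxn) && !identical(sort(names(object@stoichiometry)), sort(rxn$id))) {
    msg <- c(msg, "stoichiometry list must have exactly one entry per reaction id")
  }
  if (length(msg)) msg else TRUE
})

#' Structural validation report
#'
#' Result of [validateModel()]. Problems are reported, never raised:
#' \code{errors} holds defects that make the model unsolvable (duplicate
#' ids, unresolved references, inverted bounds), \code{warnings} holds
#' advisory findings (orphan metabolites, elemental imbalance where formulas
#' permit checking), and \code{statistics} counts genes, metabolites,
#' reactions, gene-associated reactions and exchange reactions.
#'
#' @slot errors data.frame with columns \code{code}, \code{message}.
#' @slot warnings data.frame with columns \code{code}, \code{message}.
#' @slot statistics named integer vector.
#' @export
setClass("ValidationReport",
  representation(errors = "data.frame", warnings = "data.frame",
                 statistics = "integer"))

#' Flux balance analysis result
#'
#' @slot status one of \code{"optimal"}, \code{"infeasible"},
#'   \code{"unbounded"}.
#' @slot objectiveValue optimal objective flux (\code{NA} unless optimal).
#' @slot fluxes named numeric flux vector satisfying \eqn{S v = 0}, the
#'   bounds and all extra constraints (length 0 unless optimal).
#' @export
setClass("FBAResult",
  representation(status = "character", objectiveValue = "numeric",
                 fluxes = "numeric"))

#' Phenotypic phase-plane grid
#'
#' Maximal growth over a grid of two fixed fluxes. Infeasible cells are
#' \code{NA}, never zero.
#'
#' @slot xId,yId reaction ids of the two fixed fluxes.
#' @slot x,y grid values along each axis.
#' @slot growth matrix of maximal growth, rows indexed by \code{x}, columns
#'   by \code{y}; \code{NA} marks infeasible cells.
#' @export
setClass("PhasePlaneGrid",
  representation(xId = "character", yId = "character",
                 x = "numeric", y = "numeric", growth = "matrix"))

#' Production envelope
#'
#' Minimum and maximum product flux attainable at each growth value from 0
#' to the growth optimum.
#'
#' @slot productId reaction id of the product exchange.
#' @slot growth grid of growth values.
#' @slot minProduct,maxProduct product flux bounds at each growth value
#'   (each is itself an LP optimum).
#' @export
setClass("ProductionEnvelope",
  representation(productId = "character", growth = "numeric",
                 minProduct = "numeric", maxProduct = "numeric"))

#' Knockout design
#'
#' A set of disabled reactions together with the growth optimum of the
#' knockout model and the product flux it guarantees. \code{productMax} is
#' the largest product flux among growth-optimal states; \code{productMin}
#' is the guaranteed (worst-case) product flux at the growth optimum, the
#' quantity that measures growth coupling.
#'
#' @slot reactions character vector of disabled reaction ids.
#' @slot growth inner-optimal growth (h^-1).
#' @slot productId product reaction id.
#' @slot productMax,productMin max/min product flux at the inner optimum.
#' @slot status solver status string.
#' @export
setClass("KnockoutDesign",
  representation(reactions = "character", growth = "numeric",
                 productId = "character", productMax = "numeric",
                 productMin = "numeric", status = "character"))

#' Gap-filling result
#'
#' @slot added reaction ids activated from the universe.
#' @slot growth growth achieved by draft + additions.
#' @slot status \code{"optimal"} or \code{"infeasible"} (universe cannot
#'   reach the growth threshold).
#' @export
setClass("GapfillResult",
  representation(added = "character", growth = "numeric", status = "character"))

#' Synthetic model bundle
#'
#' A generated test network with its analytically known ground truth.
#' Regenerating with the same seed reproduces the bundle exactly.
#'
#' @slot model the [MetabolicModel-class].
#' @slot groundTruth named list of expected quantities (e.g. optimal
#'   objective, coupled minimum product, removed reaction ids).
#' @slot universe optional universe model for gap-filling bundles (an empty
#'   model otherwise).
#' @slot seed integer seed used for generation.
#' @export
setClass("SyntheticModelBundle",
  representation(model = "MetabolicModel", groundTruth = "list",
                 universe = "MetabolicModel", seed = "integer"))

setMethod("show", "MetabolicModel", function(object) {
  cat(sprintf("MetabolicModel: %d metabolites, %d reactions\n",
              nrow(object@metabolites), nrow(object@reactions)))
  if (length(object@objectiveId)) {
    cat("  objective:", object@objectiveId, "\n")
  }
  ng <- length(modelGenes(object))
  cat(sprintf("  genes: %d, exchanges: %d, extra constraints: %d\n",
              ng, sum(object@reactions$is_exchange),
              length(object@extraConstraints)))
})

setMethod("show", "FBAResult", function(object) {
  cat("FBAResult:", object@status)
  if (identical(object@status, "optimal")) {
    cat(sprintf(", objective = %.6g", object@objectiveValue))
  }
  cat("\n")
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d error(s), %d warning(s)\n",
              nrow(object@errors), nrow(object@warnings)))
  st <- object@statistics
  cat("  ", paste(sprintf("%s=%d", names(st), st), collapse = ", "), "\n")
  if (nrow(object@errors)) {
    for (i in seq_len(min(5L, nrow(object@errors)))) {
      cat("  E:", object@errors$code[i], object@errors$message[i], "\n")
    }
  }
})

setMethod("show", "KnockoutDesign", function(object) {
  cat("KnockoutDesign:",
      if (length(object@reactions)) paste(object@reactions, collapse = " + ")
      else "(no knockouts)", "\n")
  cat(sprintf("  growth %.6g, %s at optimum: min %.6g, max %.6g [%s]\n",
              object@growth, object@productId, object@productMin,
              object@productMax, object@status))
})

setMethod("show", "GapfillResult", function(object) {
  cat("GapfillResult:", object@status)
  if (identical(object@status, "optimal")) {
    cat(sprintf(" — %d addition(s), growth %.6g\n  %s\n",
                length(object@added), object@growth,
                if (length(object@added)) paste(object@added, collapse = ", ")
                else "(none needed)"))
  } else cat("\n")
})

setMethod("show", "ProductionEnvelope", function(object) {
  cat(sprintf("ProductionEnvelope for %s over %d growth values in [%.4g, %.4g]\n",
              object@productId, length(object@growth), min(object@growth),
              max(object@growth)))
})

setMethod("show", "PhasePlaneGrid", function(object) {
  cat(sprintf("PhasePlaneGrid: %s (%d points) x %s (%d points), %d infeasible cells\n",
              object@xId, length(object@x), object@yId, length(object@y),
              sum(is.na(object@growth))))
})

setMethod("show", "SyntheticModelBundle", function(object) {
  cat(sprintf("SyntheticModelBundle (seed %d): %d reactions; ground truth: %s\n",
              object@seed, nrow(object@model@reactions),
              paste(names(object@groundTruth), collapse = ", ")))
})
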