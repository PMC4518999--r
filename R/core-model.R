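# Curated core model of T. saccharolyticum central fermentative metabolism.
#
# The six reactions printed in the curated knockout-design table (GLNS,
# GLUDy, GLUSy, LDH_L, PTAr, HFS) enter verbatim in the table's formula
# grammar, with their published locus tags. Everything else (lumped
# glycolysis, POR, the two-step ethanol branch, the hydrogenase complement,
# RNF, the transhydrogenase, the alpha-ketoglutarate branch, biomass,
# maintenance, transport and exchange) is a documented lumped skeleton
# chosen to reproduce the organism's mixed-acid fermentation physiology:
# glucose -> 2 pyruvate + 2 ATP + 2 NADH; pyruvate to lactate (LDH_L),
# to acetate (POR/PTAr/ACK, +1 ATP, electrons stranded on Fd/NADH) or to
# ethanol (POR + 2 NADH per ethanol, redox-neutral per glucose); surplus
# electrons leave as H2. Ferredoxin is a Fdred/Fdox pair carrying 2
# electrons, so one H2 (2 e-) is one NADH-equivalent.

.CORE_GENE_TABLE <- c(
  LDH_L = "Tsac_0179", PTAr = "Tsac_1744", GLNS = "Tsac_2029",
  GLUDy = "Tsac_2172", GLUSy = "Tsac_1234",
  HFS = "Tsac_1550 & Tsac_1551 & Tsac_1552 & Tsac_1553")

.CORE_ALIASES <- c(LDH = "LDH_L", PTA = "PTAr", GLUD = "GLUDy", GLUS = "GLUSy",
                   ACKr = "ACK")

#' Build the core fermentation model of T. saccharolyticum
#'
#' Constructs a self-consistent ~40-reaction stoichiometric model of
#' glucose fermentation to ethanol, acetate, lactate, CO2 and H2, including
#' the published formulas for GLNS, GLUDy, GLUSy, LDH_L, PTAr and HFS with
#' their locus-tag gene rules (HFS requires all four genes of the hfs
#' operon), the full hydrogenase complement (HFS, ECH, BIFH2, NADH2), a
#' ferredoxin:NAD oxidoreductase, nitrogen assimilation exclusively through
#' glutamate and glutamine, an alpha-ketoglutarate supply branch, ATP
#' maintenance and a biomass objective. Construction is deterministic.
#'
#' Unprinted stoichiometries (glycolysis lump, POR, the ethanol branch,
#' hydrogenase variants, RNF, THD, AKGS, biomass, maintenance) are fixed
#' choices documented in the package vignette; gene ids for reactions
#' without a published locus tag are \code{g_*} placeholders.
#'
#' @param glucose_uptake maximal glucose uptake rate,
#'   mmol gDW\eqn{^{-1}} h\eqn{^{-1}} (default 10).
#' @param atp_maintenance non-growth ATP maintenance flux lower bound
#'   (default 2).
#' @return a [MetabolicModel-class] with objective \code{BIOMASS}; no
#'   hydrogenase constraints are applied yet (see
#'   [applyHydrogenaseConstraints()]).
#' @examples
#' m <- buildCoreModel()
#' validateModel(m)
#' @export
buildCoreModel <- function(glucose_uptake = 10, atp_maintenance = 2) {
  stopifnot(glucose_uptake >= 0, atp_maintenance >= 0)
  g <- .CORE_GENE_TABLE
  rows <- rbind(
    # id, name, formula, lb, ub, gene_rule
    c("EX_glc", "D-glucose exchange", "glc-D[e] ->", -glucose_uptake, 0, ""),
    c("EX_etoh", "ethanol exchange", "etoh[e] ->", 0, 1000, ""),
    c("EX_ac", "acetate exchange", "ac[e] ->", 0, 1000, ""),
    c("EX_lac", "L-lactate exchange", "lac-L[e] ->", 0, 1000, ""),
    c("EX_h2", "hydrogen exchange", "H2[e] ->", 0, 1000, ""),
    c("EX_co2", "CO2 exchange", "CO2[e] ->", 0, 1000, ""),
    c("EX_pyr", "pyruvate exchange", "pyr[e] ->", 0, 1000, ""),
    c("EX_nh4", "ammonium exchange", "NH4[e] ->", -1000, 0, ""),
    c("EX_h2o", "water exchange", "H2O[e] ->", -1000, 1000, ""),
    c("EX_h", "proton exchange", "H[e] ->", -1000, 1000, ""),
    c("GLCt", "glucose transport", "glc-D[e] -> glc-D[c]", 0, 1000, "g_glct"),
    c("ETOHt", "ethanol transport", "etoh[c] -> etoh[e]", 0, 1000, ""),
    c("ACt", "acetate transport", "ac[c] -> ac[e]", 0, 1000, ""),
    c("LACt", "lactate transport", "lac-L[c] -> lac-L[e]", 0, 1000, ""),
    c("H2t", "hydrogen transport", "H2[c] -> H2[e]", 0, 1000, ""),
    c("CO2t", "CO2 transport", "CO2[c] -> CO2[e]", 0, 1000, ""),
    c("PYRt", "pyruvate efflux", "pyr[c] -> pyr[e]", 0, 1000, ""),
    c("NH4t", "ammonium transport", "NH4[e] -> NH4[c]", 0, 1000, ""),
    c("H2Ot", "water transport", "H2O[c] <=> H2O[e]", -1000, 1000, ""),
    c("Ht", "proton transport", "H[c] <=> H[e]", -1000, 1000, ""),
    c("GLYC", "glycolysis (lumped)",
      "glc-D[c] + 2 ADP[c] + 2 Pi[c] + 2 NAD[c] -> 2 pyr[c] + 2 ATP[c] + 2 NADH[c] + 2 H[c] + 2 H2O[c]",
      0, 1000, "g_glyc"),
    c("POR", "pyruvate:ferredoxin oxidoreductase",
      "pyr[c] + CoA[c] + Fdox[c] -> AcCoA[c] + CO2[c] + Fdred[c]",
      0, 1000, "g_por"),
    c("LDH_L", "L-lactate dehydrogenase",
      "lac-L[c] + NAD[c] <=> NADH[c] + H[c] + pyr[c]", -1000, 1000, g[["LDH_L"]]),
    c("PTAr", "phosphotransacetylase",
      "Pi[c] + AcCoA[c] <=> CoA[c] + actp[c]", -1000, 1000, g[["PTAr"]]),
    c("ACK", "acetate kinase",
      "actp[c] + ADP[c] -> ac[c] + ATP[c]", 0, 1000, "g_ack"),
    c("ACALD", "acetaldehyde dehydrogenase",
      "AcCoA[c] + NADH[c] + H[c] <=> acald[c] + CoA[c] + NAD[c]",
      -1000, 1000, "g_aldh"),
    c("ALCD", "alcohol dehydrogenase",
      "acald[c] + NADH[c] + H[c] <=> etoh[c] + NAD[c]", -1000, 1000, "g_adh"),
    c("HFS", "ferredoxin hydrogenase (hfs)",
      "Fdred[c] + 2 H[c] <=> Fdox[c] + H2[c]", -1000, 1000, g[["HFS"]]),
    c("ECH", "energy-conserving hydrogenase",
      "Fdred[c] + 2 H[c] <=> Fdox[c] + H2[c]", -1000, 1000, "g_ech"),
    c("BIFH2", "bifurcating hydrogenase",
      "Fdred[c] + NADH[c] + 3 H[c] <=> 2 H2[c] + Fdox[c] + NAD[c]",
      -1000, 1000, "g_bifh2"),
    c("NADH2", "NADH hydrogenase",
      "NADH[c] + H[c] <=> H2[c] + NAD[c]", -1000, 1000, "g_nadh2"),
    c("RNF", "ferredoxin:NAD oxidoreductase",
      "Fdred[c] + NAD[c] + H[c] -> Fdox[c] + NADH[c]", 0, 1000, "g_rnf"),
    c("THD", "transhydrogenase",
      "NADH[c] + NADP[c] -> NAD[c] + NADPH[c]", 0, 1000, "g_thd"),
    c("AKGS", "alpha-ketoglutarate synthesis (lumped)",
      "pyr[c] + AcCoA[c] + NADP[c] + H2O[c] -> akg[c] + CoA[c] + NADPH[c] + 2 H[c]",
      0, 1000, "g_akgs"),
    c("GLNS", "glutamine synthetase",
      "glu-L[c] + ATP[c] + NH4[c] - > ADP[c] + Pi[c] + H[c] + gln-L[c]",
      0, 1000, g[["GLNS"]]),
    c("GLUDy", "glutamate dehydrogenase (NADP)",
      "NADP[c] + H2O[c] + glu-L[c] < = > H[c] + NADPH[c] + NH4[c] + akg[c]",
      -1000, 1000, g[["GLUDy"]]),
    c("GLUSy", "glutamate synthase (NADPH)",
      "H[c] + NADPH[c] + gln-L[c] + akg[c] - > NADP[c] + 2 glu-L[c]",
      0, 1000, g[["GLUSy"]]),
    c("ATPM", "ATP maintenance",
      "ATP[c] + H2O[c] -> ADP[c] + Pi[c] + H[c]", atp_maintenance, 1000, ""),
    c("BIOMASS", "biomass synthesis",
      paste("4 pyr[c] + AcCoA[c] + 60 ATP[c] + 18 NADPH[c] + 0.6 glu-L[c]",
            "+ 0.2 gln-L[c] + 42 H2O[c] ->",
            "60 ADP[c] + 60 Pi[c] + 18 NADP[c] + CoA[c] + 78 H[c]"),
      0, 1000, ""))
  tab <- data.frame(id = rows[, 1], name = rows[, 2], formula = rows[, 3],
                    lb = as.numeric(rows[, 4]), ub = as.numeric(rows[, 5]),
                    gene_rule = rows[, 6], stringsAsFactors = FALSE)
  makeModel(tab, objective = "BIOMASS",
            metabolite_formulas = c("glc-D[e]" = "C6H12O6",
                                    "glc-D[c]" = "C6H12O6",
                                    "etoh[e]" = "C2H6O", "etoh[c]" = "C2H6O",
                                    "H2[c]" = "H2", "H2[e]" = "H2",
                                    "CO2[c]" = "CO2", "CO2[e]" = "CO2",
                                    "H2O[c]" = "H2O", "H2O[e]" = "H2O"))
}

#' Hydrogenase constraint set
#'
#' The top-down constraint set that replicates observed fermentation
#' behaviour: the energy-conserving hydrogenase is blocked, the bifurcating
#' and NADH hydrogenases are restricted to the hydrogen-uptake direction,
#' and total hydrogen export is capped at a molar yield per glucose taken
#' up. The yield cap is a coupling constraint
#' \eqn{v_{EX\_h2} \le cap \cdot |v_{EX\_glc}|}, not a fixed bound, so it
#' scales with uptake.
#'
#' @param blocked reaction ids to block entirely (default \code{"ECH"}).
#' @param uptake_only reaction ids restricted to the H2-consuming direction
#'   (default \code{c("BIFH2", "NADH2")}); the producing direction is
#'   identified from the sign of the \code{H2[c]} coefficient.
#' @param h2_yield_cap mol H2 per mol glucose (default 0.9).
#' @param h2_exchange,glucose_exchange exchange reaction ids.
#' @return a \code{HydrogenaseConstraintSet} (a classed list).
#' @export
hydrogenaseConstraintSet <- function(blocked = "ECH",
                                     uptake_only = c("BIFH2", "NADH2"),
                                     h2_yield_cap = 0.9,
                                     h2_exchange = "EX_h2",
                                     glucose_exchange = "EX_glc") {
  stopifnot(h2_yield_cap >= 0)
  structure(list(blocked = blocked, uptake_only = uptake_only,
                 h2_yield_cap = h2_yield_cap, h2_exchange = h2_exchange,
                 glucose_exchange = glucose_exchange),
            class = "HydrogenaseConstraintSet")
}

#' Apply the hydrogenase constraint set to a model
#'
#' Blocks the named hydrogenases, restricts the uptake-only hydrogenases to
#' their H2-consuming direction (the H2-producing direction's bound is
#' zeroed based on the written direction of each formula) and appends the
#' hydrogen yield-cap coupling constraint. Applying the set twice equals
#' applying it once.
#'
#' @param model a [MetabolicModel-class] containing the named reactions.
#' @param cset a [hydrogenaseConstraintSet()].
#' @return the constrained model.
#' @export
applyHydrogenaseConstraints <- function(model,
                                        cset = hydrogenaseConstraintSet()) {
  stopifnot(inherits(cset, "HydrogenaseConstraintSet"))
  all_ids <- c(cset$blocked, cset$uptake_only, cset$h2_exchange,
               cset$glucose_exchange)
  missing <- setdiff(all_ids, model@reactions$id)
  if (length(missing)) {
    stop("constraint set names reaction(s) absent from the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (rid in cset$blocked) {
    model <- setReactionBounds(model, rid, lower = 0, upper = 0)
  }
  for (rid in cset$uptake_only) {
    h2 <- model@stoichiometry[[rid]]["H2[c]"]
    if (is.na(h2) || h2 == 0) {
      stop("reaction ", rid, " does not involve H2[c]; cannot restrict ",
           "its hydrogen direction", call. = FALSE)
    }
    if (h2 > 0) { # forward produces H2: forbid positive flux
      model <- setReactionBounds(model, rid, upper = 0)
    } else {
      model <- setReactionBounds(model, rid, lower = 0)
    }
  }
  cap <- list(coefficients = setNames(c(1, cset$h2_yield_cap),
                                      c(cset$h2_exchange, cset$glucose_exchange)),
              sense = "<=", rhs = 0)
  dup <- vapply(model@extraConstraints, function(e) {
    identical(e$sense, cap$sense) && identical(e$rhs, cap$rhs) &&
      identical(sort(names(e$coefficients)), sort(names(cap$coefficients))) &&
      all(abs(e$coefficients[names(cap$coefficients)] - cap$coefficients) < 1e-12)
  }, TRUE)
  if (!any(dup)) {
    model@extraConstraints <- c(model@extraConstraints, list(cap))
  }
  model
}

#' Named engineered strains
#'
#' The strain constructors reproduce the engineered knockout strains
#' studied experimentally: \code{WT} (no knockouts), \code{ldh_pta}
#' (carbon-centric: LDH_L + PTAr), \code{ldh_hfs} (electron-centric:
#' LDH_L + HFS), and \code{ldh_hfs_glud} (LDH_L + HFS + GLUDy). Reaction
#' ids follow the curated table (LDH_L, PTAr, GLUDy); the prose aliases
#' LDH, PTA and GLUD are accepted.
#'
#' @param name strain name.
#' @return \code{strainSpec} returns a list with \code{name} and
#'   \code{disabled}; \code{strainModel} returns the knocked-out model.
#' @export
strainSpec <- function(name = c("WT", "ldh_pta", "ldh_hfs", "ldh_hfs_glud")) {
  valid <- c("WT", "ldh_pta", "ldh_hfs", "ldh_hfs_glud")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop("unknown strain name '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  disabled <- switch(name,
                     WT = character(),
                     ldh_pta = c("LDH_L", "PTAr"),
                     ldh_hfs = c("LDH_L", "HFS"),
                     ldh_hfs_glud = c("LDH_L", "HFS", "GLUDy"))
  list(name = name, disabled = disabled)
}

#' @rdname strainSpec
#' @param model a core model with [applyHydrogenaseConstraints()] already
#'   applied.
#' @export
strainModel <- function(model, name) {
  spec <- strainSpec(name)
  knockOutReactions(model, spec$disabled)
}

#' Resolve prose reaction aliases used in the strain literature
#'
#' @param ids character vector of reaction ids or aliases (LDH, PTA, GLUD,
#'   GLUS, ACKr).
#' @return canonical reaction ids.
#' @export
resolveReactionAlias <- function(ids) {
  hit <- match(ids, names(.CORE_ALIASES))
  ids[!is.na(hit)] <- .CORE_ALIASES[hit[!is.na(hit)]]
  ids
}

#' ATP cost of ammonium assimilation by route
#'
#' Pure stoichiometric accounting (independent of bounds, solver and flux
#' scale) of the net ATP consumed per ammonium incorporated into glutamate.
#' The \code{GLUD} route runs glutamate dehydrogenase in the aminating
#' direction and spends no ATP; the \code{GLNS_GLUS} route (glutamine
#' synthetase + glutamate synthase, forced when GLUD is deleted) nets
#' akg + NH4 + NADPH + ATP -> glu, i.e. one additional mol ATP per mol
#' ammonium.
#'
#' @param model a model containing GLUDy, GLNS and GLUSy.
#' @param route \code{"GLUD"} or \code{"GLNS_GLUS"}.
#' @return mol ATP per mol NH4 assimilated (numeric scalar).
#' @export
ammoniumAssimilationAtpCost <- function(model,
                                        route = c("GLUD", "GLNS_GLUS")) {
  route <- match.arg(route)
  need <- if (route == "GLUD") "GLUDy" else c("GLNS", "GLUSy")
  missing <- setdiff(need, model@reactions$id)
  if (length(missing)) {
    stop("route reactions missing from model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  net <- numeric()
  addst <- function(net, st, w) {
    for (m in names(st)) {
      net[m] <- (if (m %in% names(net)) net[m] else 0) + w * st[m]
    }
    net
  }
  if (route == "GLUD") {
    # aminating direction = reverse of the written (deaminating) formula
    net <- addst(net, model@stoichiometry[["GLUDy"]], -1)
  } else {
    net <- addst(net, model@stoichiometry[["GLNS"]], 1)
    net <- addst(net, model@stoichiometry[["GLUSy"]], 1)
  }
  nh4 <- -net["NH4[c]"]
  if (is.na(nh4) || nh4 <= 0) {
    stop("route does not consume NH4[c]; cannot express an ATP cost per ",
         "ammonium", call. = FALSE)
  }
  atp <- net["ATP[c]"]
  atp <- if (is.na(atp)) 0 else -atp
  unname(atp / nh4)
}

#' Gene-associated internal reactions (knockout candidates)
#'
#' The candidate set used for knockout design: reactions that carry a gene
#' rule and are neither exchanges, nor the objective (biomass), nor ATP
#' maintenance.
#'
#' @param model a [MetabolicModel-class].
#' @param exclude additional reaction ids to exclude.
#' @return character vector of reaction ids.
#' @export
candidateReactions <- function(model, exclude = "ATPM") {
  rx <- model@reactions
  keep <- !rx$is_exchange & nzchar(trimws(rx$gene_rule)) &
    !(rx$id %in% c(model@objectiveId, exclude))
  rx$id[keep]
}
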