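# Seeded generators of toy stoichiometric networks with analytically known
# optima: the test substrate for the solver stack. Ground-truth values are
# hand-derivable from each construction and recorded in the bundle, never
# computed by the code under test.

.with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.empty_model <- function() new("MetabolicModel")

#' Linear pathway bundle
#'
#' A chain \code{EX_in -> M1 -> ... -> Mn -> EX_out} whose intermediate
#' step bounds are drawn at random but kept at or above the uptake bound,
#' so the FBA optimum equals the uptake bound (the bottleneck); optionally
#' one step is tightened below it, making that step the bottleneck.
#'
#' @param n_steps number of internal steps (>= 1).
#' @param uptake_bound substrate uptake bound (default 10).
#' @param seed integer seed; the same seed reproduces the bundle exactly.
#' @param tight_step,tight_bound optionally tighten step \code{tight_step}
#'   (1-based) to \code{tight_bound}.
#' @return a [SyntheticModelBundle-class] with ground truth
#'   \code{optimum}.
#' @export
generateLinearPathway <- function(n_steps, uptake_bound = 10, seed = 1,
                                  tight_step = NULL, tight_bound = NULL) {
  stopifnot(n_steps >= 1, uptake_bound > 0)
  .with_seed(seed, {
    loose <- runif(n_steps, 1.2, 3) * uptake_bound
    if (!is.null(tight_step)) {
      stopifnot(tight_step >= 1, tight_step <= n_steps,
                !is.null(tight_bound))
      loose[tight_step] <- tight_bound
    }
    rows <- list(
      c("EX_in", "substrate exchange", "S[e] ->", -uptake_bound, 0, ""),
      c("UPT", "substrate uptake", "S[e] -> M1[c]", 0, 1000, ""))
    for (i in seq_len(n_steps)) {
      to <- if (i == n_steps) "P[c]" else sprintf("M%d[c]", i + 1)
      rows[[length(rows) + 1L]] <-
        c(sprintf("STEP%d", i), sprintf("pathway step %d", i),
          sprintf("M%d[c] -> %s", i, to), 0, loose[i], "")
    }
    rows[[length(rows) + 1L]] <- c("SEC", "product secretion",
                                   "P[c] -> P[e]", 0, 1000, "")
    rows[[length(rows) + 1L]] <- c("EX_out", "product exchange", "P[e] ->",
                                   0, 1000, "")
    tab <- do.call(rbind, rows)
    model <- makeModel(data.frame(id = tab[, 1], name = tab[, 2],
                                  formula = tab[, 3],
                                  lb = as.numeric(tab[, 4]),
                                  ub = as.numeric(tab[, 5]),
                                  gene_rule = tab[, 6],
                                  stringsAsFactors = FALSE),
                       objective = "EX_out")
    new("SyntheticModelBundle", model = model,
        groundTruth = list(optimum = min(uptake_bound, loose)),
        universe = .empty_model(), seed = as.integer(seed))
  })
}

#' Growth-coupled toy network
#'
#' A ~12-reaction network emulating the redox structure behind
#' electron-centred strain design: catabolism of the substrate produces
#' biomass precursor X, ATP and a reduced cofactor; the cofactor can be
#' reoxidized either by sink A (venting a gas, no product — the
#' hydrogenase-like valve) or by sink B (secreting a reduced product at the
#' cost of one precursor). With A open the minimum product at optimal
#' growth is 0; with A knocked out every unit of substrate forces one unit
#' of product, growth halves, and the coupled minimum equals the uptake
#' bound — all derivable by hand from the stoichiometry:
#' per substrate, CAT yields 2 X + 1 red + 2 ATP; biomass consumes X + ATP;
#' sink B consumes X + red per product.
#'
#' @param seed integer seed (jitters only inessential capacity bounds).
#' @param uptake_bound substrate uptake bound U (default 10).
#' @return a [SyntheticModelBundle-class] with ground truth
#'   \code{wild_optimum} (2U), \code{sinkA_knockout_optimum} (U),
#'   \code{coupled_min_product} (U) and \code{optknock_k1} ("SINKA").
#' @export
generateCoupledToy <- function(seed = 1, uptake_bound = 10) {
  stopifnot(uptake_bound > 0)
  U <- uptake_bound
  .with_seed(seed, {
    cap <- function() round(runif(1, 2.5, 5) * U, 3) # never binding (< 2.5U is)
    rows <- rbind(
      c("EX_S", "substrate exchange", "S[e] ->", -U, 0, ""),
      c("St", "substrate uptake", "S[e] -> S[c]", 0, cap(), ""),
      c("CAT", "catabolism",
        "S[c] + ox[c] + 2 ADP[c] -> 2 X[c] + red[c] + 2 ATP[c]",
        0, cap(), "g_cat"),
      c("BIO", "biomass", "X[c] + ATP[c] -> ADP[c]", 0, 1000, ""),
      c("SINKA", "electron sink A (gas vent)", "red[c] -> ox[c] + gasA[c]",
        0, cap(), "g_sinkA"),
      c("PRODB", "electron sink B (reduced product)",
        "X[c] + red[c] -> prodB[c] + ox[c]", 0, cap(), "g_prodB"),
      c("ATPASE", "ATP futile hydrolysis", "ATP[c] -> ADP[c]", 0, 1000, ""),
      c("GAt", "gas transport", "gasA[c] -> gasA[e]", 0, 1000, ""),
      c("EX_gasA", "gas exchange", "gasA[e] ->", 0, 1000, ""),
      c("Bt", "product transport", "prodB[c] -> prodB[e]", 0, 1000, ""),
      c("EX_prodB", "product exchange", "prodB[e] ->", 0, 1000, ""))
    model <- makeModel(data.frame(id = rows[, 1], name = rows[, 2],
                                  formula = rows[, 3],
                                  lb = as.numeric(rows[, 4]),
                                  ub = as.numeric(rows[, 5]),
                                  gene_rule = rows[, 6],
                                  stringsAsFactors = FALSE),
                       objective = "BIO")
    new("SyntheticModelBundle", model = model,
        groundTruth = list(wild_optimum = 2 * U,
                           sinkA_knockout_optimum = U,
                           coupled_min_product = U,
                           product_id = "EX_prodB",
                           optknock_k1 = "SINKA"),
        universe = .empty_model(), seed = as.integer(seed))
  })
}

#' Degrade a model into a gap-filling test instance
#'
#' Removes \code{k} growth-essential reactions (found by single-knockout
#' essentiality testing) from a feasible model, records them, and builds a
#' universe consisting of the removed reactions plus mass-balanced decoy
#' reactions over fresh dead-end metabolites (which can never carry
#' steady-state flux, so they cannot substitute for the removals).
#'
#' @param model a feasible [MetabolicModel-class] with a biomass objective.
#' @param k number of reactions to remove (0 <= k <= number of essential
#'   reactions).
#' @param seed integer seed.
#' @param n_decoys number of decoy universe reactions (default 10).
#' @param min_growth essentiality threshold (default 1e-3).
#' @return a [SyntheticModelBundle-class]: \code{model} is the gapped
#'   draft, \code{universe} the repair universe, ground truth records
#'   \code{removed} ids and \code{original_growth}.
#' @export
degradeModel <- function(model, k, seed = 1, n_decoys = 10,
                         min_growth = 1e-3) {
  stopifnot(k >= 0)
  .assert_solvable(model)
  base <- solveFBA(model)
  if (!identical(base@status, "optimal") ||
      base@objectiveValue < min_growth) {
    stop("model must be feasible with growth >= min_growth", call. = FALSE)
  }
  lp <- .build_lp(model, validated = TRUE)
  growth_id <- model@objectiveId
  cand <- model@reactions$id[!model@reactions$is_exchange &
                             model@reactions$id != growth_id]
  cand <- cand[vapply(cand, function(j) {
    lb <- model@reactions$lower_bound[match(j, model@reactions$id)]
    ub <- model@reactions$upper_bound[match(j, model@reactions$id)]
    lb <= 0 && ub >= 0
  }, TRUE)]
  essential <- cand[vapply(cand, function(j) {
    r <- .lp_opt(lp, setNames(1, growth_id), "max", fixes = setNames(0, j))
    !identical(r$status, "optimal") || r$objective < min_growth
  }, TRUE)]
  if (k > length(essential)) {
    stop("k = ", k, " exceeds the number of growth-essential reactions (",
         length(essential), ")", call. = FALSE)
  }
  .with_seed(seed, {
    removed <- if (k > 0) sort(sample(essential, k)) else character()
    keep <- setdiff(model@reactions$id, removed)
    draft <- .subset_reactions(model, keep)

    rows <- lapply(seq_len(n_decoys), function(i) {
      c(sprintf("DECOY%d", i), sprintf("decoy reaction %d", i),
        sprintf("dca%d[c] -> dcb%d[c]", i, i), 0,
        round(runif(1, 1, 100), 3), "")
    })
    tabs <- do.call(rbind, rows)
    decoys <- makeModel(data.frame(id = tabs[, 1], name = tabs[, 2],
                                   formula = tabs[, 3],
                                   lb = as.numeric(tabs[, 4]),
                                   ub = as.numeric(tabs[, 5]),
                                   gene_rule = tabs[, 6],
                                   stringsAsFactors = FALSE))
    universe <- .concat_models(.subset_reactions(model, removed,
                                                 keep_objective = FALSE),
                               decoys)
    new("SyntheticModelBundle", model = draft,
        groundTruth = list(removed = removed, k = k,
                           original_growth = base@objectiveValue),
        universe = universe, seed = as.integer(seed))
  })
}

# Keep only the named reactions (and the metabolites they use).
.subset_reactions <- function(model, keep, keep_objective = TRUE) {
  idx <- match(keep, model@reactions$id)
  rx <- model@reactions[idx, , drop = FALSE]
  rownames(rx) <- NULL
  st <- model@stoichiometry[keep]
  used <- unique(unlist(lapply(st, names)))
  mets <- model@metabolites[model@metabolites$id %in% used, , drop = FALSE]
  rownames(mets) <- NULL
  obj <- if (keep_objective && length(model@objectiveId) &&
             model@objectiveId %in% keep) model@objectiveId else character()
  ec <- Filter(function(e) all(names(e$coefficients) %in% keep),
               model@extraConstraints)
  m <- new("MetabolicModel", metabolites = mets, reactions = rx,
           stoichiometry = st, objectiveId = obj,
           compartments = model@compartments, extraConstraints = ec,
           annotations = model@annotations)
  validObject(m)
  m
}

.concat_models <- function(a, b) {
  rx <- rbind(a@reactions, b@reactions)
  st <- c(a@stoichiometry, b@stoichiometry)
  new_mets <- b@metabolites[!(b@metabolites$id %in% a@metabolites$id), ,
                            drop = FALSE]
  mets <- rbind(a@metabolites, new_mets)
  rownames(mets) <- NULL
  comp <- a@compartments
  extra <- setdiff(unique(mets$compartment), names(comp))
  if (length(extra)) comp <- c(comp, setNames(extra, extra))
  m <- new("MetabolicModel", metabolites = mets, reactions = rx,
           stoichiometry = st, objectiveId = a@objectiveId,
           compartments = comp, extraConstraints = a@extraConstraints,
           annotations = a@annotations)
  validObject(m)
  m
}

#' Write / read a synthetic bundle as a directory
#'
#' The bundle directory holds \code{model.json}, \code{universe.json}
#' (when non-empty) and \code{ground_truth.json} (which also records the
#' seed).
#'
#' @param bundle a [SyntheticModelBundle-class].
#' @param dir directory path (created if needed).
#' @return \code{writeSyntheticBundle} invisibly returns \code{dir};
#'   \code{readSyntheticBundle} returns the bundle.
#' @export
writeSyntheticBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeModel(bundle@model, file.path(dir, "model.json"))
  if (nrow(bundle@universe@reactions)) {
    writeModel(bundle@universe, file.path(dir, "universe.json"))
  }
  jsonlite::write_json(c(bundle@groundTruth, list(seed = bundle@seed)),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeSyntheticBundle
#' @export
readSyntheticBundle <- function(dir) {
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  seed <- as.integer(gt$seed)
  gt$seed <- NULL
  upath <- file.path(dir, "universe.json")
  new("SyntheticModelBundle",
      model = readModel(file.path(dir, "model.json")),
      groundTruth = gt,
      universe = if (file.exists(upath)) readModel(upath) else .empty_model(),
      seed = seed)
}
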