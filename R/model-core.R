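#' Parse a reaction formula string
#'
#' The formula grammar follows the way reactions are printed in curated
#' reconstruction tables: terms are \code{<coefficient> <metabolite>[<c|e>]}
#' joined by \code{+}, sides separated by \code{->} (irreversible) or
#' \code{<=>} (reversible); whitespace around \code{+}, inside arrows
#' (\code{"- >"}, \code{"< = >"}, \code{"< == >"}) and before the
#' compartment suffix (\code{"NADH [c]"}) is insignificant. Tokens with
#' internal hyphens (\code{glu-L}, \code{lac-L}) are atomic metabolite
#' names; a missing compartment suffix defaults to \code{[c]}. An empty
#' product side (\code{"glc-D[e] ->"}) denotes an exchange reaction:
#' positive flux secretes, negative flux takes up.
#'
#' @param formula character(1) formula string.
#' @return list with \code{stoichiometry} (named numeric over full
#'   metabolite ids such as \code{"glu-L[c]"}, negative = consumed),
#'   \code{reversible} (logical), \code{is_exchange} (logical: one side
#'   empty).
#' @examples
#' parseReactionFormula(
#'   "glu-L[c] + ATP[c] + NH4[c] - > ADP[c] + Pi[c] + H[c] + gln-L[c]")
#' @export
parseReactionFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("<\\s*=+\\s*>", "<=>", formula)
  s <- gsub("-\\s*>", "->", s)
  reversible <- grepl("<=>", s, fixed = TRUE)
  parts <- if (reversible) strsplit(s, "<=>", fixed = TRUE)[[1L]]
           else strsplit(s, "->", fixed = TRUE)[[1L]]
  if (!grepl("<=>|->", s)) {
    stop("formula has no reaction arrow ('->' or '<=>'): ", formula,
         call. = FALSE)
  }
  if (length(parts) > 2L) {
    stop("formula has more than one arrow: ", formula, call. = FALSE)
  }
  lhs <- .parse_formula_side(parts[1L], formula)
  rhs <- if (length(parts) == 2L) .parse_formula_side(parts[2L], formula)
         else numeric()
  stoich <- numeric()
  for (m in names(lhs)) stoich[m] <- (if (m %in% names(stoich)) stoich[m] else 0) - lhs[m]
  for (m in names(rhs)) stoich[m] <- (if (m %in% names(stoich)) stoich[m] else 0) + rhs[m]
  stoich <- stoich[abs(stoich) > 0]
  list(stoichiometry = stoich, reversible = reversible,
       is_exchange = (length(lhs) == 0L) || (length(rhs) == 0L))
}

.parse_formula_side <- function(side, formula) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric())
  terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1L]])
  out <- numeric()
  pat <- "^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?([A-Za-z][A-Za-z0-9_.-]*)\\s*(\\[([A-Za-z])\\])?$"
  for (tm in terms) {
    g <- regmatches(tm, regexec(pat, tm))[[1L]]
    if (!length(g)) {
      stop("cannot parse formula term '", tm, "' in: ", formula, call. = FALSE)
    }
    coef <- if (nzchar(trimws(g[2L]))) as.numeric(trimws(g[2L])) else 1
    comp <- if (nzchar(g[5L])) g[5L] else "c"
    id <- paste0(g[3L], "[", comp, "]")
    out[id] <- (if (id %in% names(out)) out[id] else 0) + coef
  }
  out
}

#' Assemble a metabolic model from a reaction table
#'
#' Builds a [MetabolicModel-class] from a data.frame of reactions whose
#' stoichiometries are given as formula strings in the grammar of
#' [parseReactionFormula()] (curated table rows can be pasted in verbatim).
#' Metabolites are declared implicitly from the formulas; their compartment
#' comes from the \code{[c]}/\code{[e]} suffix.
#'
#' Default bounds are \eqn{\pm 1000} for reversible and \eqn{[0, 1000]} for
#' irreversible reactions (mmol gDW\eqn{^{-1}} h\eqn{^{-1}}); explicit
#' \code{lb}/\code{ub} columns (NA = use default) override them.
#'
#' @param reactions data.frame with columns \code{id}, \code{formula} and
#'   optionally \code{name}, \code{lb}, \code{ub}, \code{gene_rule}.
#' @param objective id of the objective (biomass) reaction, or \code{NULL}.
#' @param extra_constraints list of
#'   \code{list(coefficients = <named numeric>, sense, rhs)} constraints.
#' @param metabolite_formulas optional named character vector of elemental
#'   formulas keyed by full metabolite id (e.g. \code{"glc-D[e]" = "C6H12O6"}).
#' @param default_bound magnitude of the default flux bound.
#' @return a validated [MetabolicModel-class].
#' @export
makeModel <- function(reactions, objective = NULL, extra_constraints = list(),
                      metabolite_formulas = character(),
                      default_bound = 1000) {
  stopifnot(is.data.frame(reactions), all(c("id", "formula") %in% names(reactions)))
  n <- nrow(reactions)
  name <- if ("name" %in% names(reactions)) as.character(reactions$name)
          else as.character(reactions$id)
  gpr <- if ("gene_rule" %in% names(reactions)) {
    gr <- as.character(reactions$gene_rule); gr[is.na(gr)] <- ""; gr
  } else rep("", n)
  lb_in <- if ("lb" %in% names(reactions)) as.numeric(reactions$lb) else rep(NA_real_, n)
  ub_in <- if ("ub" %in% names(reactions)) as.numeric(reactions$ub) else rep(NA_real_, n)

  stoich <- vector("list", n)
  lb <- ub <- numeric(n)
  is_ex <- logical(n)
  for (i in seq_len(n)) {
    p <- parseReactionFormula(as.character(reactions$formula[i]))
    stoich[[i]] <- p$stoichiometry
    is_ex[i] <- p$is_exchange
    lb[i] <- if (!is.na(lb_in[i])) lb_in[i] else if (p$reversible) -default_bound else 0
    ub[i] <- if (!is.na(ub_in[i])) ub_in[i] else default_bound
  }
  names(stoich) <- as.character(reactions$id)

  met_ids <- sort(unique(unlist(lapply(stoich, names))))
  comp <- sub("^.*\\[([A-Za-z])\\]$", "\\1", met_ids)
  base <- sub("\\[[A-Za-z]\\]$", "", met_ids)
  formulas <- rep("", length(met_ids))
  if (length(metabolite_formulas)) {
    hit <- match(met_ids, names(metabolite_formulas))
    formulas[!is.na(hit)] <- unname(metabolite_formulas[hit[!is.na(hit)]])
  }
  model <- new("MetabolicModel",
    metabolites = data.frame(id = met_ids, name = base, compartment = comp,
                             formula = formulas, stringsAsFactors = FALSE),
    reactions = data.frame(id = as.character(reactions$id), name = name,
                           lower_bound = lb, upper_bound = ub,
                           gene_rule = gpr, is_exchange = is_ex,
                           stringsAsFactors = FALSE),
    stoichiometry = stoich,
    objectiveId = if (is.null(objective)) character() else as.character(objective),
    extraConstraints = extra_constraints)
  validObject(model)
  model
}

# ---- accessors ------------------------------------------------------------

#' Accessors for MetabolicModel components
#'
#' @param model a [MetabolicModel-class].
#' @return \code{modelReactions}/\code{modelMetabolites} return the
#'   underlying data.frames; \code{reactionIds}/\code{metaboliteIds} the id
#'   vectors; \code{modelGenes} the sorted union of genes over all GPR
#'   rules; \code{objectiveId} the objective reaction id;
#'   \code{reactionBounds} a two-column matrix of bounds.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
modelReactions <- function(model) model@reactions

#' @rdname model-accessors
#' @export
modelMetabolites <- function(model) model@metabolites

#' @rdname model-accessors
#' @export
reactionIds <- function(model) model@reactions$id

#' @rdname model-accessors
#' @export
metaboliteIds <- function(model) model@metabolites$id

#' @rdname model-accessors
#' @export
modelGenes <- function(model) {
  sort(unique(unlist(lapply(model@reactions$gene_rule, function(r) {
    r <- trimws(r)
    if (nzchar(r)) .rule_token_genes(r) else character()
  }))))
}

#' @rdname model-accessors
#' @export
objectiveId <- function(model) model@objectiveId

#' @rdname model-accessors
#' @export
reactionBounds <- function(model) {
  cbind(lower = setNames(model@reactions$lower_bound, model@reactions$id),
        upper = model@reactions$upper_bound)
}

#' Set flux bounds on one or more reactions
#'
#' @param model a [MetabolicModel-class].
#' @param ids reaction ids.
#' @param lower,upper replacement bounds, recycled over \code{ids}; \code{NA}
#'   leaves the existing bound.
#' @return the modified model (the input is untouched).
#' @export
setReactionBounds <- function(model, ids, lower = NA, upper = NA) {
  idx <- match(ids, model@reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  lower <- rep_len(lower, length(idx)); upper <- rep_len(upper, length(idx))
  keep <- !is.na(lower)
  model@reactions$lower_bound[idx[keep]] <- lower[keep]
  keep <- !is.na(upper)
  model@reactions$upper_bound[idx[keep]] <- upper[keep]
  model
}

# ---- stoichiometric matrix ------------------------------------------------

#' Stoichiometric matrix of a model
#'
#' Returns the matrix S with one row per metabolite and one column per
#' reaction; entry (i, j) is the signed coefficient of metabolite i in
#' reaction j (zero elsewhere). Steady-state flux vectors satisfy
#' \eqn{S v = 0}.
#'
#' @param model a [MetabolicModel-class] passing [validateModel()] with no
#'   errors.
#' @return numeric matrix with metabolite-id row names and reaction-id
#'   column names (0 x 0 for an empty model).
#' @export
stoichiometricMatrix <- function(model) {
  mids <- model@metabolites$id
  rids <- model@reactions$id
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(rids)) {
    st <- model@stoichiometry[[rids[j]]]
    if (!length(st)) next
    hit <- match(names(st), mids)
    if (anyNA(hit)) {
      stop("reaction ", rids[j], " references undeclared metabolite(s): ",
           paste(names(st)[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    S[hit, j] <- unname(st)
  }
  S
}

# ---- validation -----------------------------------------------------------

.parse_elemental <- function(formula) {
  if (!nzchar(formula)) return(NULL)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula)) return(NA)
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1L]]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(ifelse(grepl("[0-9]+$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  tapply(ct, el, sum)
}

#' Validate a metabolic model structurally
#'
#' Reports (never raises) structural defects: duplicate ids, unresolved
#' metabolite/objective/constraint references, inverted bounds
#' (\code{BOUNDS_INVERTED}), empty stoichiometries on non-exchange
#' reactions, undeclared compartments. Orphan metabolites (appearing in no
#' reaction) and elemental imbalance are advisory warnings; the elemental
#' check runs only for non-exchange reactions whose metabolites all carry
#' formulas, since curated tables often omit water/proton bookkeeping.
#'
#' @param model a [MetabolicModel-class].
#' @return a [ValidationReport-class]; a model with errors is rejected by
#'   the solvers.
#' @export
validateModel <- function(model) {
  err <- list(); wrn <- list()
  add_e <- function(code, msg) err[[length(err) + 1L]] <<- c(code, msg)
  add_w <- function(code, msg) wrn[[length(wrn) + 1L]] <<- c(code, msg)

  met <- model@metabolites; rxn <- model@reactions
  dup <- unique(met$id[duplicated(met$id)])
  for (d in dup) add_e("DUPLICATE_METABOLITE", paste("duplicate metabolite id:", d))
  dup <- unique(rxn$id[duplicated(rxn$id)])
  for (d in dup) add_e("DUPLICATE_REACTION", paste("duplicate reaction id:", d))

  for (cc in setdiff(unique(met$compartment), names(model@compartments))) {
    add_e("UNKNOWN_COMPARTMENT", paste("compartment not declared:", cc))
  }

  used <- character()
  for (rid in rxn$id) {
    st <- model@stoichiometry[[rid]]
    if (!length(st) && !rxn$is_exchange[match(rid, rxn$id)]) {
      add_e("EMPTY_STOICHIOMETRY",
            paste("non-exchange reaction with empty stoichiometry:", rid))
    }
    missing <- setdiff(names(st), met$id)
    for (mm in missing) {
      add_e("UNRESOLVED_METABOLITE",
            paste0("reaction ", rid, " references undeclared metabolite ", mm))
    }
    used <- c(used, names(st))
  }
  inv <- which(rxn$lower_bound > rxn$upper_bound)
  for (i in inv) {
    add_e("BOUNDS_INVERTED",
          sprintf("reaction %s has lower bound %g > upper bound %g",
                  rxn$id[i], rxn$lower_bound[i], rxn$upper_bound[i]))
  }
  if (length(model@objectiveId) && !all(model@objectiveId %in% rxn$id)) {
    add_e("UNRESOLVED_OBJECTIVE",
          paste("objective reaction not in model:", model@objectiveId))
  }
  for (ec in model@extraConstraints) {
    missing <- setdiff(names(ec$coefficients), rxn$id)
    for (mm in missing) {
      add_e("UNRESOLVED_CONSTRAINT_REF",
            paste("extra constraint references unknown reaction:", mm))
    }
  }
  orphan <- setdiff(met$id, unique(used))
  for (o in orphan) add_w("ORPHAN_METABOLITE", paste("metabolite in no reaction:", o))

  # advisory elemental balance where formulas permit
  forms <- setNames(met$formula, met$id)
  for (i in seq_len(nrow(rxn))) {
    if (rxn$is_exchange[i]) next
    st <- model@stoichiometry[[rxn$id[i]]]
    if (!length(st) || !all(names(st) %in% names(forms))) next
    fs <- forms[names(st)]
    if (!all(nzchar(fs))) next
    parsed <- lapply(fs, .parse_elemental)
    if (any(vapply(parsed, function(p) length(p) == 1L && is.na(p[1L]), TRUE))) next
    bal <- list()
    for (k in seq_along(st)) {
      for (el in names(parsed[[k]])) {
        bal[[el]] <- (if (is.null(bal[[el]])) 0 else bal[[el]]) +
          st[k] * parsed[[k]][[el]]
      }
    }
    off <- names(bal)[vapply(bal, function(v) abs(v) > 1e-6, TRUE)]
    if (length(off)) {
      add_w("ELEMENTAL_IMBALANCE",
            sprintf("reaction %s is not balanced for element(s) %s",
                    rxn$id[i], paste(off, collapse = ", ")))
    }
  }

  gene_assoc <- vapply(rxn$gene_rule, function(g) nzchar(trimws(g)), TRUE)
  stats <- c(genes = length(modelGenes(model)),
             metabolites = nrow(met),
             reactions = nrow(rxn),
             gene_associated = sum(gene_assoc),
             exchanges = sum(rxn$is_exchange))
  as_df <- function(x) {
    if (!length(x)) {
      data.frame(code = character(), message = character(), stringsAsFactors = FALSE)
    } else {
      data.frame(code = vapply(x, `[`, "", 1L), message = vapply(x, `[`, "", 2L),
                 stringsAsFactors = FALSE)
    }
  }
  new("ValidationReport", errors = as_df(err), warnings = as_df(wrn),
      statistics = setNames(as.integer(stats), names(stats)))
}

.assert_solvable <- function(model) {
  rep <- validateModel(model)
  if (nrow(rep@errors)) {
    stop("model fails validation with ", nrow(rep@errors), " error(s); first: ",
         rep@errors$code[1L], " - ", rep@errors$message[1L], call. = FALSE)
  }
  invisible(TRUE)
}

# ---- knockouts ------------------------------------------------------------

#' Disable reactions by fixing their flux to zero
#'
#' @param model a [MetabolicModel-class].
#' @param reaction_ids character vector of reaction ids to disable (may be
#'   empty).
#' @return a copy of the model with \code{lower_bound = upper_bound = 0} for
#'   each named reaction; the original is untouched and the reaction and
#'   metabolite sets are unchanged.
#' @export
knockOutReactions <- function(model, reaction_ids) {
  reaction_ids <- unique(as.character(reaction_ids))
  if (!length(reaction_ids)) return(model)
  missing <- setdiff(reaction_ids, model@reactions$id)
  if (length(missing)) {
    stop("cannot knock out unknown reaction id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  setReactionBounds(model, reaction_ids, lower = 0, upper = 0)
}

#' Reactions disabled by a gene deletion set
#'
#' Propagates gene deletions through the GPR rules: a reaction is disabled
#' exactly when its rule evaluates \code{FALSE} under the deletion set.
#' Reactions with no gene association are never disabled.
#'
#' @param model a [MetabolicModel-class].
#' @param deleted_genes character vector of deleted gene ids.
#' @return character vector of disabled reaction ids.
#' @export
reactionsDisabledByGenes <- function(model, deleted_genes) {
  deleted_genes <- as.character(deleted_genes)
  if (!length(deleted_genes)) return(character())
  off <- vapply(model@reactions$gene_rule,
                function(r) !evaluateGeneRule(r, deleted_genes), TRUE)
  model@reactions$id[off]
}
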