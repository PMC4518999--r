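#' Read and write metabolic models
#'
#' Two native dialects plus a reader for a small SBML subset:
#' \describe{
#'   \item{native-json}{A documented JSON schema holding all model fields
#'     (metabolites, reactions with stoichiometry maps, bounds, GPR rules,
#'     objective, extra constraints, annotations). \code{read(write(m))} is
#'     the identity field-for-field; unrecognized top-level fields are
#'     preserved as opaque annotations.}
#'   \item{native-tsv}{One reaction per row — \code{id}, \code{name},
#'     \code{formula} (the grammar of [parseReactionFormula()], so curated
#'     table rows paste in verbatim), \code{lb}, \code{ub},
#'     \code{gene_rule}. Empty bounds are inferred from the arrow:
#'     \code{<=>} maps to \eqn{\pm 1000}, \code{->} to \eqn{[0, 1000]}.
#'     Objective, compartments, metabolite formulas and extra constraints
#'     travel in \code{#!} directive lines.}
#'   \item{sbml-subset}{Reader for an SBML Level 3 core subset: species,
#'     reactions with stoichiometric speciesReferences, reversibility,
#'     bounds via fbc flux-bound parameters. Anything beyond the subset
#'     (function definitions, rules, events, algebraic constraints) is an
#'     explicit unsupported-feature error, never a silent omission.}
#' }
#'
#' @param path file path.
#' @param format one of \code{"native-json"}, \code{"native-tsv"},
#'   \code{"sbml-subset"}; default guesses from the file extension
#'   (\code{.json}, \code{.tsv}, \code{.xml}/\code{.sbml}).
#' @param model a [MetabolicModel-class] (for \code{writeModel}).
#' @return \code{readModel} returns a [MetabolicModel-class];
#'   \code{writeModel} invisibly returns \code{path}.
#' @name model-io
NULL

.guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         json = "native-json", tsv = "native-tsv", txt = "native-tsv",
         xml = "sbml-subset", sbml = "sbml-subset",
         stop("cannot guess model format from extension of ", path,
              call. = FALSE))
}

#' @rdname model-io
#' @export
readModel <- function(path, format = .guess_format(path)) {
  format <- match.arg(format, c("native-json", "native-tsv", "sbml-subset"))
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  switch(format,
         "native-json" = .read_json_model(path),
         "native-tsv" = .read_tsv_model(path),
         "sbml-subset" = .read_sbml_model(path))
}

#' @rdname model-io
#' @export
writeModel <- function(model, path, format = .guess_format(path)) {
  format <- match.arg(format, c("native-json", "native-tsv", "sbml-subset"))
  stopifnot(is(model, "MetabolicModel"))
  switch(format,
         "native-json" = .write_json_model(model, path),
         "native-tsv" = .write_tsv_model(model, path),
         "sbml-subset" = stop("SBML export is not supported (reader only)",
                              call. = FALSE))
  invisible(path)
}

# ---- native JSON ----------------------------------------------------------

.KNOWN_JSON_FIELDS <- c("format", "version", "compartments", "metabolites",
                        "reactions", "objective_id", "extra_constraints",
                        "annotations")

.write_json_model <- function(model, path) {
  rx <- model@reactions
  reactions <- lapply(seq_len(nrow(rx)), function(i) {
    st <- model@stoichiometry[[rx$id[i]]]
    list(id = rx$id[i], name = rx$name[i],
         stoichiometry = as.list(st),
         lower_bound = rx$lower_bound[i], upper_bound = rx$upper_bound[i],
         gene_rule = rx$gene_rule[i], is_exchange = rx$is_exchange[i])
  })
  mt <- model@metabolites
  metabolites <- lapply(seq_len(nrow(mt)), function(i) {
    list(id = mt$id[i], name = mt$name[i], compartment = mt$compartment[i],
         formula = mt$formula[i])
  })
  doc <- list(format = "thermoflux-model", version = 1L,
              compartments = as.list(model@compartments),
              metabolites = metabolites, reactions = reactions,
              objective_id = if (length(model@objectiveId)) model@objectiveId else NULL,
              extra_constraints = lapply(model@extraConstraints, function(e) {
                list(coefficients = as.list(e$coefficients), sense = e$sense,
                     rhs = e$rhs)
              }),
              annotations = model@annotations)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

.read_json_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse JSON model ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  get_chr <- function(x, f, d = "") if (is.null(x[[f]])) d else as.character(x[[f]])
  mets <- doc$metabolites
  met_df <- data.frame(
    id = vapply(mets, get_chr, "", "id"),
    name = vapply(mets, get_chr, "", "name"),
    compartment = vapply(mets, get_chr, "", "compartment"),
    formula = vapply(mets, get_chr, "", "formula"),
    stringsAsFactors = FALSE)
  rxs <- doc$reactions
  if (is.null(rxs)) stop("JSON model ", path, " has no 'reactions' field",
                         call. = FALSE)
  stoich <- lapply(rxs, function(r) {
    st <- r$stoichiometry
    if (is.null(st) || !length(st)) return(setNames(numeric(0), character(0)))
    setNames(vapply(st, as.numeric, 0), names(st))
  })
  rxn_df <- data.frame(
    id = vapply(rxs, get_chr, "", "id"),
    name = vapply(rxs, get_chr, "", "name"),
    lower_bound = vapply(rxs, function(r) as.numeric(r$lower_bound), 0),
    upper_bound = vapply(rxs, function(r) as.numeric(r$upper_bound), 0),
    gene_rule = vapply(rxs, get_chr, "", "gene_rule"),
    is_exchange = vapply(rxs, function(r) isTRUE(r$is_exchange), TRUE),
    stringsAsFactors = FALSE)
  names(stoich) <- rxn_df$id
  comp <- if (!is.null(doc$compartments)) {
    setNames(vapply(doc$compartments, as.character, ""), names(doc$compartments))
  } else c(c = "cytosol", e = "extracellular")
  ecs <- lapply(doc$extra_constraints, function(e) {
    list(coefficients = setNames(vapply(e$coefficients, as.numeric, 0),
                                 names(e$coefficients)),
         sense = as.character(e$sense), rhs = as.numeric(e$rhs))
  })
  ann <- if (is.null(doc$annotations)) list() else doc$annotations
  extra <- doc[setdiff(names(doc), .KNOWN_JSON_FIELDS)]
  if (length(extra)) ann <- modifyList(ann, extra)
  m <- new("MetabolicModel", metabolites = met_df, reactions = rxn_df,
           stoichiometry = stoich,
           objectiveId = if (is.null(doc$objective_id)) character()
                         else as.character(doc$objective_id),
           compartments = comp, extraConstraints = ecs, annotations = ann)
  validObject(m)
  m
}

# ---- native TSV -----------------------------------------------------------

.format_num <- function(x) {
  vapply(x, function(v) {
    s <- as.character(v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, "")
}

.stoich_to_formula <- function(st, reversible) {
  side <- function(v) {
    paste(vapply(seq_along(v), function(k) {
      cf <- abs(v[k])
      if (abs(cf - 1) < 1e-12) names(v)[k]
      else paste(.format_num(cf), names(v)[k])
    }, ""), collapse = " + ")
  }
  lhs <- st[st < 0]; rhs <- st[st > 0]
  paste(side(lhs), if (reversible) "<=>" else "->", side(rhs))
}

.write_tsv_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#! thermoflux-model-tsv 1", con)
  writeLines(paste0("#! compartments ",
                    jsonlite::toJSON(as.list(model@compartments),
                                     auto_unbox = TRUE)), con)
  if (length(model@objectiveId)) {
    writeLines(paste("#! objective", model@objectiveId), con)
  }
  for (e in model@extraConstraints) {
    writeLines(paste0("#! constraint ",
                      jsonlite::toJSON(list(coefficients = as.list(e$coefficients),
                                            sense = e$sense, rhs = e$rhs),
                                       auto_unbox = TRUE, digits = NA)), con)
  }
  mt <- model@metabolites
  for (i in which(nzchar(mt$formula))) {
    writeLines(paste("#! metabolite_formula", mt$id[i], mt$formula[i]), con)
  }
  writeLines(paste("id", "name", "formula", "lb", "ub", "gene_rule",
                   sep = "\t"), con)
  rx <- model@reactions
  for (i in seq_len(nrow(rx))) {
    st <- model@stoichiometry[[rx$id[i]]]
    rev <- rx$lower_bound[i] < 0 && rx$upper_bound[i] > 0
    writeLines(paste(rx$id[i], rx$name[i], .stoich_to_formula(st, rev),
                     .format_num(rx$lower_bound[i]),
                     .format_num(rx$upper_bound[i]), rx$gene_rule[i],
                     sep = "\t"), con)
  }
}

.read_tsv_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  directives <- grep("^#!", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("TSV model ", path, " has no table rows", call. = FALSE)
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("id", "formula")
  if (!all(need %in% header)) {
    stop("TSV model ", path, " header must contain at least: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_along(body[-1L]), function(k) {
    f <- strsplit(body[k + 1L], "\t", fixed = TRUE)[[1L]]
    # strsplit drops trailing empty fields; restore them when the row has
    # the right number of tab separators
    n_tabs <- lengths(regmatches(body[k + 1L], gregexpr("\t", body[k + 1L],
                                                        fixed = TRUE)))
    if (length(f) < length(header) && n_tabs == length(header) - 1L) {
      f <- c(f, rep("", length(header) - length(f)))
    }
    if (length(f) < length(header)) {
      stop("TSV model ", path, ", row ", k, " ('",
           substr(body[k + 1L], 1, 40), "...'): expected ", length(header),
           " fields, found ", length(f), call. = FALSE)
    }
    setNames(as.list(f[seq_along(header)]), header)
  })
  grab <- function(row, col, d = NA) {
    if (col %in% names(row) && nzchar(trimws(row[[col]]))) row[[col]] else d
  }
  tab <- data.frame(
    id = vapply(rows, function(r) r$id, ""),
    name = vapply(rows, function(r) as.character(grab(r, "name", r$id)), ""),
    formula = vapply(rows, function(r) r$formula, ""),
    lb = vapply(rows, function(r) as.numeric(grab(r, "lb")), 0),
    ub = vapply(rows, function(r) as.numeric(grab(r, "ub")), 0),
    gene_rule = vapply(rows, function(r) as.character(grab(r, "gene_rule", "")), ""),
    stringsAsFactors = FALSE)

  objective <- NULL
  ecs <- list()
  met_formulas <- character()
  comp <- NULL
  for (d in directives) {
    d <- sub("^#!\\s*", "", d)
    key <- sub("\\s.*$", "", d)
    rest <- trimws(sub("^\\S+\\s*", "", d))
    if (key == "objective") objective <- rest
    if (key == "constraint") {
      e <- jsonlite::fromJSON(rest, simplifyVector = FALSE)
      ecs[[length(ecs) + 1L]] <-
        list(coefficients = setNames(vapply(e$coefficients, as.numeric, 0),
                                     names(e$coefficients)),
             sense = as.character(e$sense), rhs = as.numeric(e$rhs))
    }
    if (key == "metabolite_formula") {
      kv <- strsplit(rest, "\\s+")[[1L]]
      met_formulas[kv[1L]] <- kv[2L]
    }
    if (key == "compartments") {
      cl <- jsonlite::fromJSON(rest, simplifyVector = FALSE)
      comp <- setNames(vapply(cl, as.character, ""), names(cl))
    }
  }
  m <- makeModel(tab, objective = objective, extra_constraints = ecs,
                 metabolite_formulas = met_formulas)
  if (!is.null(comp)) m@compartments <- comp
  validObject(m)
  m
}

# ---- SBML subset ----------------------------------------------------------

.read_sbml_model <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file ", path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model_node, "xml_missing")) {
    stop("SBML file ", path, " has no <model> element", call. = FALSE)
  }
  for (feat in c("listOfFunctionDefinitions", "listOfRules", "listOfEvents",
                 "listOfConstraints", "listOfInitialAssignments")) {
    if (!inherits(xml2::xml_find_first(model_node, paste0("./", feat)),
                  "xml_missing")) {
      stop("unsupported SBML feature in ", path, ": ", feat, call. = FALSE)
    }
  }
  params <- xml2::xml_find_all(model_node, ".//listOfParameters/parameter")
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))
  comps <- xml2::xml_find_all(model_node, ".//listOfCompartments/compartment")
  comp <- setNames(ifelse(is.na(xml2::xml_attr(comps, "name")),
                          xml2::xml_attr(comps, "id"),
                          xml2::xml_attr(comps, "name")),
                   xml2::xml_attr(comps, "id"))
  if (!length(comp)) comp <- c(c = "cytosol", e = "extracellular")

  sp <- xml2::xml_find_all(model_node, ".//listOfSpecies/species")
  met_df <- data.frame(
    id = xml2::xml_attr(sp, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  xml2::xml_attr(sp, "id"), xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = ifelse(is.na(xml2::xml_attr(sp, "chemicalFormula")), "",
                     xml2::xml_attr(sp, "chemicalFormula")),
    stringsAsFactors = FALSE)
  boundary <- xml2::xml_attr(sp, "boundaryCondition")
  drop_ids <- met_df$id[!is.na(boundary) & boundary == "true"]

  rxns <- xml2::xml_find_all(model_node, ".//listOfReactions/reaction")
  n <- length(rxns)
  stoich <- vector("list", n)
  ids <- character(n); nms <- character(n)
  lb <- numeric(n); ub <- numeric(n); gpr <- character(n); isx <- logical(n)
  for (i in seq_len(n)) {
    r <- rxns[[i]]
    ids[i] <- xml2::xml_attr(r, "id")
    nm <- xml2::xml_attr(r, "name")
    nms[i] <- if (is.na(nm)) ids[i] else nm
    side <- function(which) {
      refs <- xml2::xml_find_all(r, paste0("./", which, "/speciesReference"))
      if (!length(refs)) return(numeric())
      sv <- xml2::xml_attr(refs, "stoichiometry")
      sv[is.na(sv)] <- "1"
      setNames(as.numeric(sv), xml2::xml_attr(refs, "species"))
    }
    lhs <- side("listOfReactants"); rhs <- side("listOfProducts")
    st <- numeric()
    for (mm in names(lhs)) st[mm] <- (if (mm %in% names(st)) st[mm] else 0) - lhs[mm]
    for (mm in names(rhs)) st[mm] <- (if (mm %in% names(st)) st[mm] else 0) + rhs[mm]
    st <- st[!(names(st) %in% drop_ids)]
    stoich[[i]] <- st
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lbp <- xml2::xml_attr(r, "lowerFluxBound")
    ubp <- xml2::xml_attr(r, "upperFluxBound")
    lb[i] <- if (!is.na(lbp) && lbp %in% names(pvals)) pvals[[lbp]]
             else if (rev) -1000 else 0
    ub[i] <- if (!is.na(ubp) && ubp %in% names(pvals)) pvals[[ubp]] else 1000
    gpr_node <- xml2::xml_find_first(r, ".//geneProductAssociation")
    gpr[i] <- if (inherits(gpr_node, "xml_missing")) "" else .sbml_gpr(gpr_node)
    isx[i] <- length(st[st < 0]) == 0L || length(st[st > 0]) == 0L
  }
  names(stoich) <- ids
  met_df <- met_df[!(met_df$id %in% drop_ids), , drop = FALSE]

  obj_ref <- xml2::xml_find_first(
    model_node, ".//listOfObjectives/objective/listOfFluxObjectives/fluxObjective")
  objective <- if (inherits(obj_ref, "xml_missing")) character()
               else xml2::xml_attr(obj_ref, "reaction")
  m <- new("MetabolicModel",
           metabolites = met_df,
           reactions = data.frame(id = ids, name = nms, lower_bound = lb,
                                  upper_bound = ub, gene_rule = gpr,
                                  is_exchange = isx, stringsAsFactors = FALSE),
           stoichiometry = stoich, objectiveId = objective,
           compartments = comp, extraConstraints = list(),
           annotations = list(source = "sbml"))
  validObject(m)
  m
}

.sbml_gpr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm %in% c("geneProductAssociation")) {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1L) return("")
    return(.sbml_gpr(kids[[1L]]))
  }
  if (nm == "geneProductRef") return(xml2::xml_attr(node, "geneProduct"))
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, .sbml_gpr, "")
  op <- if (nm == "and") " & " else if (nm == "or") " | " else
    stop("unsupported SBML gene association element: ", nm, call. = FALSE)
  paste0("(", paste(parts, collapse = op), ")")
}
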