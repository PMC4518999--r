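#' Evaluate a gene-protein-reaction rule under a gene deletion set
#'
#' GPR rules are boolean expressions over gene identifiers with \code{&}
#' (all subunits required, e.g. a four-gene hydrogenase operon), \code{|}
#' (isoenzymes) and parentheses. A gene literal evaluates to \code{FALSE}
#' iff the gene is deleted. The empty rule means "no gene associated" and
#' always evaluates \code{TRUE}: such reactions cannot be removed by gene
#' deletion.
#'
#' @param rule character(1) rule, e.g.
#'   \code{"Tsac_1550 & Tsac_1551 & Tsac_1552 & Tsac_1553"} or
#'   \code{"(a & b) | c"}; \code{""} for no association.
#' @param deleted_genes character vector of deleted gene ids.
#' @return logical(1): is the reaction still catalyzed?
#' @examples
#' evaluateGeneRule("(a & b) | c", "a")   # TRUE via c
#' evaluateGeneRule("a & b", "a")         # FALSE
#' evaluateGeneRule("", c("a", "b"))      # TRUE (no gene associated)
#' @export
evaluateGeneRule <- function(rule, deleted_genes = character()) {
  stopifnot(is.character(rule), length(rule) == 1L)
  rule <- trimws(rule)
  if (!nzchar(rule)) return(TRUE)
  expr <- .parse_gene_rule(rule)
  genes <- .rule_token_genes(rule)
  env <- new.env(parent = baseenv()) # resolves only `&`, `|`, `(`
  for (g in genes) {
    assign(chartr("-", ".", g), !(g %in% deleted_genes), envir = env)
  }
  isTRUE(eval(expr, env))
}

#' Genes referenced by a GPR rule
#'
#' @inheritParams evaluateGeneRule
#' @return character vector of gene ids (empty for the empty rule).
#' @export
ruleGenes <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1L)
  rule <- trimws(rule)
  if (!nzchar(rule)) return(character())
  .parse_gene_rule(rule) # syntax check
  .rule_token_genes(rule)
}

# Rules are restricted to identifiers, & | ( ) and whitespace, so the parsed
# expression cannot contain calls other than the boolean operators.
.parse_gene_rule <- function(rule) {
  if (!grepl("^[A-Za-z0-9_.()&|[:space:]-]+$", rule)) {
    stop("malformed gene rule (illegal characters): ", rule, call. = FALSE)
  }
  safe <- chartr("-", ".", rule) # hyphens in gene ids -> syntactic names
  expr <- tryCatch(str2lang(safe),
                   error = function(e) stop("malformed gene rule: ", rule,
                                            call. = FALSE))
  .check_rule_ast(expr, rule)
  expr
}

.check_rule_ast <- function(e, rule) {
  if (is.name(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op %in% c("&", "|", "&&", "||")) {
      if (length(e) != 3L) stop("malformed gene rule: ", rule, call. = FALSE)
      .check_rule_ast(e[[2L]], rule)
      .check_rule_ast(e[[3L]], rule)
      return(invisible(TRUE))
    }
    if (op == "(") return(.check_rule_ast(e[[2L]], rule))
  }
  stop("malformed gene rule: ", rule, call. = FALSE)
}

.rule_token_genes <- function(rule) {
  unique(regmatches(rule, gregexpr("[A-Za-z0-9_.-]+", rule))[[1L]])
}
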