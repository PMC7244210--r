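## GPR boolean rule parsing and DNF decomposition.
##
## A GPR (gene-protein-reaction) rule is a boolean expression over gene
## identifiers, with AND joining subunits of a complex and OR joining
## isoenzymes. We expand arbitrary nesting to full disjunctive normal form:
## a list of AND-clauses (gene sets), one per functional enzyme. OR
## relationships are deliberately not collapsed; every isoenzyme is kept.

.GPR_AND <- c("and", "&", "&&")
.GPR_OR  <- c("or", "|", "||")

.gprTokenize <- function(gpr) {
  m <- gregexpr("\\(|\\)|[^\\s()]+", gpr, perl = TRUE)
  regmatches(gpr, m)[[1]]
}

## Recursive-descent parser returning a list of character vectors (clauses).
## Grammar:  or := and (OR and)* ;  and := atom (AND atom)* ;
##           atom := "(" or ")" | gene
.gprParse <- function(tokens, maxClauses, context) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() { tok <- tokens[pos]; pos <<- pos + 1L; tok }

  parseAtom <- function() {
    tok <- peek()
    if (is.na(tok))
      stop("unexpected end of GPR", context, call. = FALSE)
    if (tok == "(") {
      advance()
      res <- parseOr()
      if (!identical(peek(), ")"))
        stop("unbalanced parentheses in GPR", context, call. = FALSE)
      advance()
      return(res)
    }
    if (tok == ")" || tolower(tok) %in% c(.GPR_AND, .GPR_OR))
      stop("unexpected token '", tok, "' in GPR", context, call. = FALSE)
    advance()
    list(tok)
  }

  parseAnd <- function() {
    left <- parseAtom()
    while (!is.na(peek()) && tolower(peek()) %in% .GPR_AND) {
      advance()
      right <- parseAtom()
      if (length(left) * length(right) > maxClauses)
        stop("DNF expansion exceeds ", maxClauses, " clauses", context,
             call. = FALSE)
      left <- unlist(lapply(left, function(a)
        lapply(right, function(b) union(a, b))), recursive = FALSE)
    }
    left
  }

  parseOr <- function() {
    clauses <- parseAnd()
    while (!is.na(peek()) && tolower(peek()) %in% .GPR_OR) {
      advance()
      clauses <- c(clauses, parseAnd())
      if (length(clauses) > maxClauses)
        stop("DNF expansion exceeds ", maxClauses, " clauses", context,
             call. = FALSE)
    }
    clauses
  }

  out <- parseOr()
  if (pos <= length(tokens))
    stop("trailing tokens in GPR near '", tokens[pos], "'", context,
         call. = FALSE)
  out
}

.canonicalClauses <- function(clauses) {
  cl <- lapply(clauses, function(g) sort(unique(g)))
  ids <- vapply(cl, paste, character(1), collapse = "&")
  cl[!duplicated(ids)]
}

#' Decompose a GPR rule string into enzyme gene sets
#'
#' Expands a boolean gene-protein-reaction rule (genes joined by
#' \code{and}/\code{or} with arbitrary parenthesised nesting; \code{&}, \code{|}
#' and C-style doubled operators are also accepted, case-insensitively) into
#' disjunctive normal form. Each AND-clause of the result is one enzyme: a
#' sorted, deduplicated set of gene identifiers. An empty or missing rule
#' yields an empty list (a gene-free reaction).
#'
#' The expansion of nested rules can blow up combinatorially, so it is capped:
#' exceeding \code{maxClauses} clauses is a hard error.
#'
#' @param gpr a single GPR rule string (may be \code{NA} or empty).
#' @param maxClauses cap on the number of DNF clauses (default 256).
#' @param reaction optional reaction identifier used in error messages.
#' @return list of character vectors, one sorted gene set per enzyme.
#' @examples
#' gprToEnzymes("g1 and g2")            # one complex {g1, g2}
#' gprToEnzymes("g1 or (g2 and g3)")    # isoenzymes {g1} and {g2, g3}
#' gprToEnzymes("")                     # gene-free: list()
#' @export
gprToEnzymes <- function(gpr, maxClauses = 256L, reaction = NULL) {
  context <- if (is.null(reaction)) "" else paste0(" (reaction ", reaction, ")")
  if (length(gpr) != 1L)
    stop("gprToEnzymes expects a single rule string", call. = FALSE)
  if (is.na(gpr) || !nzchar(trimws(gpr))) return(list())
  tokens <- .gprTokenize(trimws(gpr))
  if (!length(tokens)) return(list())
  .canonicalClauses(.gprParse(tokens, maxClauses = maxClauses,
                              context = context))
}

.enzymeIdFor <- function(genes) paste(sort(unique(genes)), collapse = "&")

#' Build a ReactionCatalog from reaction identifiers and GPR rules
#'
#' Decomposes each reaction's GPR into enzymes ([gprToEnzymes()]) and
#' assembles the catalog. Enzymes are deduplicated across reactions by their
#' canonical identifier (sorted gene ids joined by \code{"&"}); reactions
#' without any gene association are recorded as gene-free. Gene identifiers
#' are taken verbatim from the input; set \code{caseFold} to match
#' case-insensitively against expression data later (identifiers are then
#' lower-cased here).
#'
#' @param reactions data.frame with columns \code{reaction_id}, \code{gpr}
#'   and optionally \code{subsystem}.
#' @param maxClauses DNF expansion cap per reaction, see [gprToEnzymes()].
#' @param caseFold lower-case all gene identifiers (default FALSE).
#' @return a [ReactionCatalog-class] object.
#' @examples
#' buildReactionCatalog(data.frame(
#'   reaction_id = c("R1", "R2", "R3"),
#'   gpr = c("g1 and g2", "g1 or (g2 and g3)", "")))
#' @export
buildReactionCatalog <- function(reactions, maxClauses = 256L,
                                 caseFold = FALSE) {
  if (!all(c("reaction_id", "gpr") %in% names(reactions)))
    stop("reactions must have columns reaction_id and gpr")
  rid <- as.character(reactions$reaction_id)
  if (anyDuplicated(rid))
    stop("duplicated reaction identifiers: ",
         paste(unique(rid[duplicated(rid)]), collapse = ", "))
  subsystem <- if ("subsystem" %in% names(reactions))
    as.character(reactions$subsystem) else rep("", length(rid))
  subsystem[is.na(subsystem)] <- ""

  enzymes <- list()
  rxnEnzymes <- vector("list", length(rid))
  names(rxnEnzymes) <- rid
  for (i in seq_along(rid)) {
    clauses <- gprToEnzymes(as.character(reactions$gpr[i]),
                            maxClauses = maxClauses, reaction = rid[i])
    if (caseFold) clauses <- lapply(clauses, tolower)
    ids <- vapply(clauses, .enzymeIdFor, character(1))
    rxnEnzymes[[i]] <- unique(ids)
    newEnz <- !(ids %in% names(enzymes))
    if (any(newEnz)) {
      add <- clauses[newEnz]
      names(add) <- ids[newEnz]
      add <- add[!duplicated(names(add))]
      enzymes <- c(enzymes, add)
    }
  }
  new("ReactionCatalog",
      reactions = data.frame(reaction_id = rid, subsystem = subsystem,
                             stringsAsFactors = FALSE),
      rxnEnzymes = rxnEnzymes,
      enzymes = enzymes,
      geneFree = rid[lengths(rxnEnzymes) == 0L])
}
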