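## Reading metabolic models: SBML Level 3 with the fbc package, or a plain
## JSON dialect {id, reactions: [{id, subsystem, gene_reaction_rule}]}.

#' Read a genome-scale metabolic model into a ReactionCatalog
#'
#' Extracts reaction identifiers and gene associations from an SBML (Level 3
#' FBC gene-product associations) or JSON model file and decomposes every
#' GPR into enzymes (see [buildReactionCatalog()]). Stoichiometry, bounds and
#' compartments are ignored; only the reaction-enzyme-gene mapping is kept.
#'
#' For SBML, gene products are reported by their \code{fbc:label} when
#' present (the identifier GPRs are written in), falling back to
#' \code{fbc:id}. The JSON dialect expects fields \code{id} and
#' \code{reactions}, each reaction an object with \code{id}, optional
#' \code{subsystem}, and \code{gene_reaction_rule}.
#'
#' @param path path to the model file.
#' @param format \code{"auto"} (by extension), \code{"sbml"} or \code{"json"}.
#' @param maxClauses DNF expansion cap per reaction.
#' @param caseFold lower-case gene identifiers (default FALSE).
#' @return a [ReactionCatalog-class].
#' @export
readMetabolicModel <- function(path, format = c("auto", "sbml", "json"),
                               maxClauses = 256L, caseFold = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
                     xml = "sbml", sbml = "sbml", json = "json",
                     stop("cannot infer model format from extension '.",
                          ext, "'; pass format explicitly"))
  }
  switch(format,
         sbml = .readSBMLModel(path, maxClauses = maxClauses,
                               caseFold = caseFold),
         json = .readJSONModel(path, maxClauses = maxClauses,
                               caseFold = caseFold))
}

.readJSONModel <- function(path, maxClauses, caseFold) {
  mod <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(mod$reactions)) stop("JSON model has no 'reactions' field")
  rows <- lapply(mod$reactions, function(r) {
    if (is.null(r$id)) stop("JSON model reaction without an 'id'")
    data.frame(reaction_id = as.character(r$id),
               subsystem = if (is.null(r$subsystem)) "" else
                 as.character(r$subsystem),
               gpr = if (is.null(r$gene_reaction_rule)) "" else
                 as.character(r$gene_reaction_rule),
               stringsAsFactors = FALSE)
  })
  buildReactionCatalog(do.call(rbind, rows), maxClauses = maxClauses,
                       caseFold = caseFold)
}

## SBML parsing is namespace-agnostic (local-name() matching) so that any
## SBML level 3 + fbc document parses regardless of prefix choices.
.readSBMLModel <- function(path, maxClauses, caseFold) {
  doc <- xml2::read_xml(path)

  gp <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gpId <- vapply(gp, .xmlAttrLocal, character(1), "id")
  gpLabel <- vapply(gp, .xmlAttrLocal, character(1), "label")
  labelOf <- ifelse(is.na(gpLabel) | !nzchar(gpLabel), gpId, gpLabel)
  names(labelOf) <- gpId

  rxns <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (!length(rxns)) stop("SBML model contains no reactions: ", path)

  rid <- vapply(rxns, .xmlAttrLocal, character(1), "id")

  enzymes <- list()
  rxnEnzymes <- vector("list", length(rid))
  names(rxnEnzymes) <- rid
  for (i in seq_along(rxns)) {
    gpa <- xml2::xml_find_first(
      rxns[[i]], "./*[local-name()='geneProductAssociation']")
    clauses <- if (inherits(gpa, "xml_missing")) list() else {
      kids <- xml2::xml_children(gpa)
      if (!length(kids)) list() else
        .canonicalClauses(.sbmlAssocDNF(kids[[1]], labelOf,
                                        maxClauses = maxClauses,
                                        reaction = rid[i]))
    }
    if (caseFold) clauses <- lapply(clauses, tolower)
    ids <- vapply(clauses, .enzymeIdFor, character(1))
    rxnEnzymes[[i]] <- unique(ids)
    newEnz <- setdiff(ids, names(enzymes))
    if (length(newEnz)) {
      add <- clauses[match(newEnz, ids)]
      names(add) <- newEnz
      enzymes <- c(enzymes, add)
    }
  }
  new("ReactionCatalog",
      reactions = data.frame(reaction_id = rid,
                             subsystem = rep("", length(rid)),
                             stringsAsFactors = FALSE),
      rxnEnzymes = rxnEnzymes,
      enzymes = enzymes,
      geneFree = rid[lengths(rxnEnzymes) == 0L])
}

.xmlAttrLocal <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", name, "$"), names(at))
  if (length(hit)) unname(at[hit[1]]) else NA_character_
}

## Convert an fbc association subtree (and/or/geneProductRef) to DNF clauses.
.sbmlAssocDNF <- function(node, labelOf, maxClauses, reaction) {
  tag <- xml2::xml_name(node)
  if (tag == "geneProductRef") {
    ref <- .xmlAttrLocal(node, "geneProduct")
    if (is.na(ref)) stop("geneProductRef without a geneProduct attribute ",
                         "(reaction ", reaction, ")", call. = FALSE)
    gene <- if (ref %in% names(labelOf)) unname(labelOf[ref]) else ref
    return(list(gene))
  }
  kids <- xml2::xml_children(node)
  parts <- lapply(kids, .sbmlAssocDNF, labelOf = labelOf,
                  maxClauses = maxClauses, reaction = reaction)
  if (tag == "or") {
    out <- do.call(c, parts)
    if (length(out) > maxClauses)
      stop("DNF expansion exceeds ", maxClauses, " clauses (reaction ",
           reaction, ")", call. = FALSE)
    return(out)
  }
  if (tag == "and") {
    out <- list(character(0))
    for (p in parts) {
      if (length(out) * length(p) > maxClauses)
        stop("DNF expansion exceeds ", maxClauses, " clauses (reaction ",
             reaction, ")", call. = FALSE)
      out <- unlist(lapply(out, function(a)
        lapply(p, function(b) union(a, b))), recursive = FALSE)
    }
    return(out)
  }
  stop("unsupported gene association element <", tag, "> (reaction ",
       reaction, ")", call. = FALSE)
}

#' Serialize a ReactionCatalog to JSON
#'
#' Writes reactions (with their enzyme ids and subsystem), the enzyme-to-gene
#' map and the gene-free reaction list to a JSON file.
#'
#' @param catalog a [ReactionCatalog-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCatalogJSON <- function(catalog, path) {
  obj <- list(
    reactions = lapply(seq_len(nrow(catalog@reactions)), function(i) {
      rid <- catalog@reactions$reaction_id[i]
      list(id = rid,
           subsystem = catalog@reactions$subsystem[i],
           enzymes = as.list(catalog@rxnEnzymes[[rid]]))
    }),
    enzymes = lapply(catalog@enzymes, as.list),
    gene_free_reactions = as.list(catalog@geneFree))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
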