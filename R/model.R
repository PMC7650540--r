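#' Construct a genome-scale metabolic model
#'
#' A lightweight stoichiometric container: metabolites live in bracketed
#' compartments (`"glc[e]"`, `"pyr[c]"`), reactions carry flux bounds, a
#' gene-association string and a subsystem label. Exchange reactions follow
#' the usual convention of a single extracellular metabolite with negative
#' stoichiometry, so uptake is a negative flux.
#'
#' @param id model identifier.
#' @param stoich named list: one entry per reaction (names are reaction ids),
#'   each a named numeric vector mapping metabolite id to coefficient
#'   (negative = consumed).
#' @param lb,ub numeric flux bounds, recycled to the number of reactions.
#' @param gpr character gene-association strings (boolean `and`/`or` syntax),
#'   recycled; `""` means no gene support.
#' @param subsystem character subsystem labels, recycled.
#' @param biomass id of the designated biomass reaction, or `NULL`.
#' @return an object of class `metabolic_model` with elements `id`,
#'   `metabolites` (data.frame id/compartment), `reactions` (data.frame
#'   id/lb/ub/gpr/subsystem), `stoich` (named list) and `biomass_id`.
#' @examples
#' m <- metabolic_model("toy",
#'   stoich = list(
#'     EX_glc = c("glc[e]" = -1),
#'     T_glc  = c("glc[e]" = -1, "glc[c]" = 1),
#'     BIOMASS = c("glc[c]" = -1)),
#'   lb = c(-10, -1000, 0), ub = 1000, biomass = "BIOMASS")
#' reaction_classes(m)
#' @export
metabolic_model <- function(id, stoich, lb = -1000, ub = 1000, gpr = "",
                            subsystem = "", biomass = NULL) {
  if (length(stoich) == 0L) stop("model must contain at least one reaction")
  rids <- names(stoich)
  if (is.null(rids) || anyNA(rids) || any(rids == ""))
    stop("every reaction needs an id (names of 'stoich')")
  if (anyDuplicated(rids)) stop("duplicate reaction ids: ",
                                paste(unique(rids[duplicated(rids)]), collapse = ", "))
  n <- length(stoich)
  lb <- rep_len(as.numeric(lb), n); ub <- rep_len(as.numeric(ub), n)
  if (any(lb > ub))
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(rids[lb > ub], collapse = ", "))
  gpr <- rep_len(as.character(gpr), n)
  subsystem <- rep_len(as.character(subsystem), n)
  bad <- vapply(stoich, function(s) is.null(names(s)) || any(names(s) == ""), logical(1))
  if (any(bad)) stop("unnamed stoichiometry in reaction(s): ",
                     paste(rids[bad], collapse = ", "))
  mets <- sort(unique(unlist(lapply(stoich, names), use.names = FALSE)))
  if (!is.null(biomass) && !biomass %in% rids)
    stop("biomass reaction '", biomass, "' not among reactions")
  obj <- structure(list(
    id = id,
    metabolites = data.frame(id = mets, compartment = met_compartment(mets),
                             stringsAsFactors = FALSE),
    reactions = data.frame(id = rids, lb = lb, ub = ub, gpr = gpr,
                           subsystem = subsystem, stringsAsFactors = FALSE),
    stoich = stoich,
    biomass_id = biomass
  ), class = "metabolic_model")
  obj
}

#' @export
print.metabolic_model <- function(x, ...) {
  cl <- reaction_classes(x)
  cat("<metabolic_model> ", x$id, "\n",
      "  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      " (", sum(cl == "metabolic"), " metabolic, ",
      sum(cl == "transporter"), " transporter, ",
      sum(cl == "exchange"), " exchange)\n",
      "  biomass: ", if (is.null(x$biomass_id)) "<unset>" else x$biomass_id,
      "\n", sep = "")
  invisible(x)
}

#' Parse the compartment of metabolite ids
#'
#' Compartments are bracketed suffixes (`"[c]"`, `"[e]"`); ids without a
#' parseable suffix are assigned to the cytosol `"c"`.
#'
#' @param met_ids character metabolite ids.
#' @return character compartment codes.
#' @keywords internal
met_compartment <- function(met_ids) {
  comp <- sub("^.*\\[([^][]+)\\]$", "\\1", met_ids)
  comp[comp == met_ids] <- "c"
  comp
}

#' @export
reaction_ids <- function(model) model$reactions$id

#' Stoichiometric matrix of a model
#' @param model a [metabolic_model()].
#' @return sparse metabolites-by-reactions matrix.
#' @export
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rids <- model$reactions$id
  ii <- unlist(lapply(model$stoich, function(s) match(names(s), mets)),
               use.names = FALSE)
  jj <- rep(seq_along(rids), lengths(model$stoich))
  xx <- unlist(model$stoich, use.names = FALSE)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(mets), length(rids)),
                       dimnames = list(mets, rids))
}

#' Classify every reaction of a model
#'
#' Rule: the designated biomass reaction is `biomass`; a reaction touching a
#' single metabolite is an `exchange` (boundary) reaction; a non-exchange
#' reaction whose participants span at least two compartments is a
#' `transporter`; everything else is `metabolic`. Metabolite ids without a
#' parseable compartment suffix count as cytosolic, so such reactions fall
#' through to `metabolic`.
#'
#' @param model a [metabolic_model()].
#' @return named character vector over reaction ids with values in
#'   `c("metabolic", "transporter", "exchange", "biomass")`.
#' @export
reaction_classes <- function(model) {
  out <- vapply(model$stoich, function(s) {
    if (length(s) == 1L) return("exchange")
    if (length(unique(met_compartment(names(s)))) >= 2L) return("transporter")
    "metabolic"
  }, character(1))
  if (!is.null(model$biomass_id)) out[model$biomass_id] <- "biomass"
  out
}

#' Exchange reaction ids of a model
#' @param model a [metabolic_model()].
#' @return character vector of exchange reaction ids.
#' @export
exchange_ids <- function(model) {
  names(which(reaction_classes(model) == "exchange"))
}

#' Metabolite exchanged by each exchange reaction
#' @keywords internal
exchange_metabolites <- function(model) {
  ex <- exchange_ids(model)
  setNames(vapply(model$stoich[ex], function(s) names(s)[1], character(1)), ex)
}

#' Add reactions to a model
#'
#' @param model a [metabolic_model()].
#' @inheritParams metabolic_model
#' @return the extended model; adding an already-present reaction id is an
#'   error.
#' @export
add_reactions <- function(model, stoich, lb = -1000, ub = 1000, gpr = "",
                          subsystem = "") {
  if (length(stoich) == 0L) return(model)
  clash <- intersect(names(stoich), model$reactions$id)
  if (length(clash)) stop("reaction(s) already present: ",
                          paste(clash, collapse = ", "))
  n <- length(stoich)
  metabolic_model(model$id,
                  stoich = c(model$stoich, stoich),
                  lb = c(model$reactions$lb, rep_len(lb, n)),
                  ub = c(model$reactions$ub, rep_len(ub, n)),
                  gpr = c(model$reactions$gpr, rep_len(gpr, n)),
                  subsystem = c(model$reactions$subsystem, rep_len(subsystem, n)),
                  biomass = model$biomass_id)
}

#' Remove reactions from a model
#' @param model a [metabolic_model()].
#' @param ids reaction ids to drop (silently ignores absent ids).
#' @return the reduced model.
#' @export
remove_reactions <- function(model, ids) {
  keep <- !model$reactions$id %in% ids
  if (all(keep)) return(model)
  bm <- model$biomass_id
  if (!is.null(bm) && !bm %in% model$reactions$id[keep]) bm <- NULL
  metabolic_model(model$id, stoich = model$stoich[keep],
                  lb = model$reactions$lb[keep], ub = model$reactions$ub[keep],
                  gpr = model$reactions$gpr[keep],
                  subsystem = model$reactions$subsystem[keep],
                  biomass = bm)
}

#' Reaction census of a model
#'
#' Counts reactions by class, the style of census usually printed for a
#' reconstruction (total reactions excluding exchanges and biomass, total
#' transporters, reactions without gene support).
#'
#' @param model a [metabolic_model()].
#' @return data.frame with one row: `total_reactions` (metabolic +
#'   transporter), `metabolic`, `transporters`, `exchanges`,
#'   `without_gpr` (metabolic/transporter reactions with empty
#'   gene-association).
#' @export
model_census <- function(model) {
  cl <- reaction_classes(model)
  inner <- cl %in% c("metabolic", "transporter")
  data.frame(
    model = model$id,
    total_reactions = sum(inner),
    metabolic = sum(cl == "metabolic"),
    transporters = sum(cl == "transporter"),
    exchanges = sum(cl == "exchange"),
    without_gpr = sum(inner & model$reactions$gpr == ""),
    stringsAsFactors = FALSE
  )
}

# --- SBML Level 3 (+ fbc-style bounds/objective) IO ------------------------

sbml_core_ns <- "http://www.sbml.org/sbml/level3/version1/core"
sbml_fbc_ns <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_id <- function(x, prefix) {
  paste0(prefix, gsub("[^A-Za-z0-9_]", "_", x))
}

#' Write a model as SBML Level 3
#'
#' Emits SBML L3V1 with fbc-style flux bound parameters, an active flux
#' objective marking the biomass reaction, and gene associations plus
#' subsystems in reaction notes. [read_sbml()] round-trips ids,
#' stoichiometry, bounds and gene associations losslessly.
#'
#' @param model a [metabolic_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = sbml_core_ns, "xmlns:fbc" = sbml_fbc_ns,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_id(model$id, "M_"),
                             name = model$id, "fbc:strict" = "true")
  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cmp in unique(model$metabolites$compartment))
    xml2::xml_add_child(comps, "compartment", id = cmp, constant = "true")
  sps <- xml2::xml_add_child(mdl, "listOfSpecies")
  met_sid <- setNames(sbml_id(model$metabolites$id, "M_"), model$metabolites$id)
  for (i in seq_len(nrow(model$metabolites)))
    xml2::xml_add_child(sps, "species",
      id = met_sid[[i]], name = model$metabolites$id[i],
      compartment = model$metabolites$compartment[i],
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  pars <- xml2::xml_add_child(mdl, "listOfParameters")
  rxn_sid <- setNames(sbml_id(model$reactions$id, "R_"), model$reactions$id)
  for (i in seq_len(nrow(model$reactions))) {
    xml2::xml_add_child(pars, "parameter", id = paste0(rxn_sid[[i]], "_lb"),
                        value = format(model$reactions$lb[i], digits = 17),
                        constant = "true")
    xml2::xml_add_child(pars, "parameter", id = paste0(rxn_sid[[i]], "_ub"),
                        value = format(model$reactions$ub[i], digits = 17),
                        constant = "true")
  }
  rxns <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    s <- model$stoich[[rid]]
    rx <- xml2::xml_add_child(rxns, "reaction", id = rxn_sid[[i]], name = rid,
      reversible = tolower(model$reactions$lb[i] < 0), fast = "false",
      "fbc:lowerFluxBound" = paste0(rxn_sid[[i]], "_lb"),
      "fbc:upperFluxBound" = paste0(rxn_sid[[i]], "_ub"))
    notes <- xml2::xml_add_child(rx, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p",
      paste0("GENE_ASSOCIATION: ", model$reactions$gpr[i]))
    xml2::xml_add_child(body, "p",
      paste0("SUBSYSTEM: ", model$reactions$subsystem[i]))
    rea <- xml2::xml_add_child(rx, "listOfReactants")
    pro <- xml2::xml_add_child(rx, "listOfProducts")
    for (k in seq_along(s)) {
      parent <- if (s[k] < 0) rea else pro
      xml2::xml_add_child(parent, "speciesReference",
        species = met_sid[[names(s)[k]]],
        stoichiometry = format(abs(s[k]), digits = 17), constant = "true")
    }
  }
  if (!is.null(model$biomass_id)) {
    objs <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                                "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lof <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lof, "fbc:fluxObjective",
      "fbc:reaction" = rxn_sid[[model$biomass_id]], "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an SBML Level 3 model
#'
#' Parses the SBML subset written by [write_sbml()] (also tolerant of plain
#' L3 core with bound parameters). Malformed XML raises a parse error naming
#' the offending element; a model without a flux objective loads with a
#' warning and an unset biomass reaction; a reaction whose lower bound
#' exceeds its upper bound is a validation error.
#'
#' @param path SBML file.
#' @return a [metabolic_model()].
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse error in '", path,
                                           "': ", conditionMessage(e)))
  mdl <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(mdl, "xml_missing"))
    stop("SBML parse error in '", path, "': element path /sbml/model not found")
  model_id <- xml2::xml_attr(mdl, "name")
  if (is.na(model_id)) model_id <- xml2::xml_attr(mdl, "id")

  sp <- xml2::xml_find_all(mdl, ".//*[local-name()='species']")
  met_name <- setNames(xml2::xml_attr(sp, "name"), xml2::xml_attr(sp, "id"))
  miss <- is.na(met_name)
  met_name[miss] <- names(met_name)[miss]

  par <- xml2::xml_find_all(mdl, ".//*[local-name()='parameter']")
  par_val <- setNames(as.numeric(xml2::xml_attr(par, "value")),
                      xml2::xml_attr(par, "id"))

  rxns <- xml2::xml_find_all(mdl,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rxns) == 0L)
    stop("SBML parse error in '", path, "': no reactions under ",
         "/sbml/model/listOfReactions")
  stoich <- vector("list", length(rxns))
  rid <- lb <- ub <- gpr <- subsys <- character(length(rxns))
  lb <- ub <- numeric(length(rxns))
  sid2rid <- character(0)
  for (i in seq_along(rxns)) {
    rx <- rxns[[i]]
    sid <- xml2::xml_attr(rx, "id")
    nm <- xml2::xml_attr(rx, "name")
    rid[i] <- if (is.na(nm)) sid else nm
    sid2rid[sid] <- rid[i]
    lbp <- xml2::xml_attr(rx, "lowerFluxBound")
    ubp <- xml2::xml_attr(rx, "upperFluxBound")
    lb[i] <- if (!is.na(lbp) && lbp %in% names(par_val)) par_val[[lbp]] else -1000
    ub[i] <- if (!is.na(ubp) && ubp %in% names(par_val)) par_val[[ubp]] else 1000
    reac <- xml2::xml_find_all(rx,
      ".//*[local-name()='listOfReactants']/*[local-name()='speciesReference']")
    prod <- xml2::xml_find_all(rx,
      ".//*[local-name()='listOfProducts']/*[local-name()='speciesReference']")
    sref <- function(nodes, sign) {
      if (length(nodes) == 0L) return(numeric(0))
      setNames(sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
               met_name[xml2::xml_attr(nodes, "species")])
    }
    s <- c(sref(reac, -1), sref(prod, 1))
    if (length(s) == 0L)
      stop("SBML parse error in '", path, "': reaction '", sid,
           "' has no participants")
    stoich[[i]] <- s
    ps <- xml2::xml_text(xml2::xml_find_all(rx,
      ".//*[local-name()='notes']//*[local-name()='p']"))
    g <- sub("^GENE_ASSOCIATION: ?", "", grep("^GENE_ASSOCIATION:", ps, value = TRUE))
    ss <- sub("^SUBSYSTEM: ?", "", grep("^SUBSYSTEM:", ps, value = TRUE))
    gpr[i] <- if (length(g)) g[1] else ""
    subsys[i] <- if (length(ss)) ss[1] else ""
  }
  names(stoich) <- rid

  fo <- xml2::xml_find_first(mdl, ".//*[local-name()='fluxObjective']")
  biomass <- NULL
  if (!inherits(fo, "xml_missing")) {
    bsid <- xml2::xml_attr(fo, "reaction")
    if (bsid %in% names(sid2rid)) biomass <- sid2rid[[bsid]]
  }
  if (is.null(biomass))
    warning("no flux objective in '", path, "'; biomass reaction unset")
  metabolic_model(model_id, stoich = stoich, lb = lb, ub = ub, gpr = gpr,
                  subsystem = subsys, biomass = biomass)
}
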