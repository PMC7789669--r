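#' Construct a metabolic model
#'
#' A small constraint-based model: metabolites, reactions with stoichiometry
#' and flux bounds (mmol gdw^-1 h^-1), optional gene-association labels, an
#' `insertable` flag for reactions that are present in the reconstruction
#' but disabled until explicitly enabled, and a biomass objective. Exchange
#' reactions follow the usual convention: a single extracellular metabolite
#' on the substrate side, negative flux = uptake.
#'
#' @param reactions A tibble with columns `id`, `stoichiometry` (list column
#'   of named numeric vectors; negative = consumed), `lb`, `ub`, `genes`
#'   (character, `""` if none) and `insertable` (logical). Insertable
#'   reactions keep their stated bounds in `enabled_lb`/`enabled_ub` and are
#'   clamped to zero until [enable_insertable()].
#' @param metabolites Character vector of declared metabolite IDs.
#' @param objective Reaction ID to maximize (the biomass reaction).
#' @return A `metabolic_model`.
#' @export
metabolic_model <- function(reactions, metabolites, objective) {
  reactions <- tibble::as_tibble(reactions)
  required <- c("id", "stoichiometry", "lb", "ub", "genes", "insertable")
  stopifnot(all(required %in% names(reactions)))
  if (anyDuplicated(reactions$id)) {
    abort("duplicate reaction IDs", class = "anaerodesign_model_error")
  }
  for (i in seq_len(nrow(reactions))) {
    st <- reactions$stoichiometry[[i]]
    unknown <- setdiff(names(st), metabolites)
    if (length(unknown) > 0) {
      abort(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                    reactions$id[i], paste(unknown, collapse = ", ")),
            class = "anaerodesign_model_error", reaction = reactions$id[i])
    }
    if (reactions$lb[i] > reactions$ub[i]) {
      abort(sprintf("reaction '%s' has inverted bounds", reactions$id[i]),
            class = "anaerodesign_model_error", reaction = reactions$id[i])
    }
  }
  if (!objective %in% reactions$id) {
    abort(sprintf("objective reaction '%s' not in model", objective),
          class = "anaerodesign_model_error")
  }
  if (!"enabled_lb" %in% names(reactions)) {
    reactions$enabled_lb <- reactions$lb
    reactions$enabled_ub <- reactions$ub
    reactions$lb[reactions$insertable] <- 0
    reactions$ub[reactions$insertable] <- 0
  }
  structure(list(reactions = reactions, metabolites = metabolites,
                 objective = objective),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d reactions (%d insertable), %d metabolites, objective '%s'\n",
              nrow(x$reactions), sum(x$reactions$insertable),
              length(x$metabolites), x$objective))
  invisible(x)
}

# Dense stoichiometric matrix, metabolites x reactions.
stoichiometry_matrix <- function(model) {
  S <- matrix(0, nrow = length(model$metabolites), ncol = nrow(model$reactions),
              dimnames = list(model$metabolites, model$reactions$id))
  for (i in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[i]]
    S[names(st), i] <- st
  }
  S
}

#' Exchange reactions of a model
#'
#' A reaction is treated as an exchange when it involves exactly one
#' metabolite (the boundary convention of the tabular format).
#'
#' @param model A `metabolic_model`.
#' @return Character vector of exchange reaction IDs.
#' @export
exchange_reactions <- function(model) {
  model$reactions$id[vapply(model$reactions$stoichiometry, length, 1L) == 1L]
}

#' Enable insertable reactions
#'
#' Restores the stated bounds of the named insertable reactions (e.g. the
#' denitrification set of the toy model).
#'
#' @param model A `metabolic_model`.
#' @param ids Reaction IDs to enable; default: all insertable reactions.
#' @return The modified model.
#' @export
enable_insertable <- function(model, ids = NULL) {
  stopifnot(inherits(model, "metabolic_model"))
  ids <- ids %||% model$reactions$id[model$reactions$insertable]
  unknown <- setdiff(ids, model$reactions$id)
  if (length(unknown) > 0) {
    abort(sprintf("unknown reaction(s): %s", paste(unknown, collapse = ", ")),
          class = "anaerodesign_model_error")
  }
  sel <- model$reactions$id %in% ids
  model$reactions$lb[sel] <- model$reactions$enabled_lb[sel]
  model$reactions$ub[sel] <- model$reactions$enabled_ub[sel]
  model
}

# ---- tabular reaction format -------------------------------------------

parse_equation <- function(eq, id) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) > 2) {
    abort(sprintf("reaction '%s': malformed equation", id),
          class = "anaerodesign_model_error", reaction = id)
  }
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric())
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    out <- numeric(length(terms))
    nm <- character(length(terms))
    for (i in seq_along(terms)) {
      parts <- strsplit(terms[i], "\\s+")[[1]]
      if (length(parts) == 1) {
        out[i] <- sign; nm[i] <- parts[1]
      } else if (length(parts) == 2) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coef)) {
          abort(sprintf("reaction '%s': bad coefficient '%s'", id, parts[1]),
                class = "anaerodesign_model_error", reaction = id)
        }
        out[i] <- sign * coef; nm[i] <- parts[2]
      } else {
        abort(sprintf("reaction '%s': bad term '%s'", id, terms[i]),
              class = "anaerodesign_model_error", reaction = id)
      }
    }
    setNames(out, nm)
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- if (length(sides) == 2) parse_side(sides[2], 1) else numeric()
  collapse_coefficients(c(lhs, rhs))
}

# Sum repeated metabolites into one coefficient each, keeping first-seen order.
collapse_coefficients <- function(st) {
  if (length(st) == 0) return(numeric())
  agg <- tapply(st, names(st), sum)
  setNames(as.numeric(agg), names(agg))[unique(names(st))]
}

format_equation <- function(st) {
  side <- function(v) paste(sprintf("%g %s", abs(v), names(v)), collapse = " + ")
  lhs <- st[st < 0]; rhs <- st[st > 0]
  paste0(if (length(lhs)) side(lhs) else "", " -> ",
         if (length(rhs)) side(rhs) else "") |> trimws()
}

#' Read a metabolic model from the tabular reaction format
#'
#' Tab-separated with header
#' `reaction_id  equation  lower  upper  genes  flags`, equations written
#' `"1 A + 2 B -> 1 C"` (an empty side marks an exchange). `flags` may
#' contain `insertable` and/or `objective`, comma-separated.
#'
#' @param file Path to the reaction table.
#' @param objective Objective reaction ID; defaults to the reaction flagged
#'   `objective` in the file.
#' @return A `metabolic_model`.
#' @export
read_reaction_table <- function(file, objective = NULL) {
  raw <- readr::read_tsv(file, col_types = "ccddcc", progress = FALSE)
  required <- c("reaction_id", "equation", "lower", "upper", "genes", "flags")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("reaction table is missing column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "anaerodesign_model_error")
  }
  raw$genes[is.na(raw$genes)] <- ""
  raw$flags[is.na(raw$flags)] <- ""
  st <- lapply(seq_len(nrow(raw)),
               function(i) parse_equation(raw$equation[i], raw$reaction_id[i]))
  flags <- strsplit(raw$flags, ",", fixed = TRUE)
  insertable <- vapply(flags, function(f) "insertable" %in% trimws(f), logical(1))
  obj_flag <- vapply(flags, function(f) "objective" %in% trimws(f), logical(1))
  objective <- objective %||% raw$reaction_id[which(obj_flag)[1]]
  if (is.na(objective)) {
    abort("no objective reaction flagged or supplied",
          class = "anaerodesign_model_error")
  }
  metabolic_model(
    reactions = tibble::tibble(id = raw$reaction_id, stoichiometry = st,
                               lb = raw$lower, ub = raw$upper,
                               genes = raw$genes, insertable = insertable),
    metabolites = sort(unique(unlist(lapply(st, names)))),
    objective = objective
  )
}

#' Write a metabolic model in the tabular reaction format
#'
#' @param model A `metabolic_model`.
#' @param file Output path.
#' @return `file`, invisibly. Insertable reactions are written with their
#'   enabled bounds, so a write/read round-trip reproduces the model.
#' @export
write_reaction_table <- function(model, file) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  flags <- ifelse(rx$insertable, "insertable", "")
  flags <- ifelse(rx$id == model$objective,
                  ifelse(nzchar(flags), paste0(flags, ",objective"), "objective"),
                  flags)
  out <- tibble::tibble(
    reaction_id = rx$id,
    equation = vapply(rx$stoichiometry, format_equation, character(1)),
    lower = rx$enabled_lb, upper = rx$enabled_ub,
    genes = rx$genes, flags = flags
  )
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}

#' Read a metabolic model from an SBML file
#'
#' Minimal SBML level-3 (fbc) reader: species, reactions with
#' reactant/product stoichiometries, flux bounds via fbc bound parameters
#' (falling back to +/-1000), gene-association text and the active fbc
#' objective. Intended for small curated models; not a complete SBML
#' implementation.
#'
#' @param file Path to an SBML document.
#' @param objective Objective reaction ID override.
#' @return A `metabolic_model`.
#' @export
read_sbml_model <- function(file, objective = NULL) {
  doc <- xml2::read_xml(file)
  species <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  mets <- xml2::xml_attr(species, "id")

  params <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  pvals <- setNames(as.numeric(xml2::xml_attr(params, "value")),
                    xml2::xml_attr(params, "id"))

  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  get_refs <- function(node, tag, sign) {
    if (inherits(node, "xml_missing")) return(numeric())
    refs <- xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", tag))
    if (length(refs) == 0) return(numeric())
    sp <- xml2::xml_attr(refs, "species")
    coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    coef[is.na(coef)] <- 1
    setNames(sign * coef, sp)
  }
  ids <- xml2::xml_attr(rx_nodes, "id")
  st <- vector("list", length(rx_nodes))
  lb <- ub <- numeric(length(rx_nodes))
  genes <- character(length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    node <- rx_nodes[[i]]
    reac <- get_refs(xml2::xml_find_first(node, ".//*[local-name()='listOfReactants']"),
                     "speciesReference", -1)
    prod <- get_refs(xml2::xml_find_first(node, ".//*[local-name()='listOfProducts']"),
                     "speciesReference", 1)
    st[[i]] <- collapse_coefficients(c(reac, prod))
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb[i] <- if (!is.na(lb_ref) && lb_ref %in% names(pvals)) pvals[[lb_ref]]
             else if (rev) -1000 else 0
    ub[i] <- if (!is.na(ub_ref) && ub_ref %in% names(pvals)) pvals[[ub_ref]] else 1000
    ga <- xml2::xml_find_first(node, ".//*[local-name()='geneProductRef']")
    genes[i] <- if (inherits(ga, "xml_missing")) "" else
      xml2::xml_attr(ga, "geneProduct") %||% ""
  }
  if (is.null(objective)) {
    fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
    if (!inherits(fo, "xml_missing")) objective <- xml2::xml_attr(fo, "reaction")
  }
  if (is.null(objective) || is.na(objective)) {
    abort("SBML model declares no flux objective; supply one",
          class = "anaerodesign_model_error")
  }
  metabolic_model(
    reactions = tibble::tibble(id = ids, stoichiometry = st, lb = lb, ub = ub,
                               genes = genes, insertable = FALSE),
    metabolites = mets, objective = objective
  )
}

#' Load a metabolic model from a tabular or SBML source
#'
#' Dispatches on file content: XML documents go through [read_sbml_model()],
#' anything else through [read_reaction_table()].
#'
#' @inheritParams read_reaction_table
#' @return A `metabolic_model`.
#' @export
load_model <- function(file, objective = NULL) {
  first <- readLines(file, n = 1L, warn = FALSE)
  if (length(first) > 0 && grepl("^\\s*<\\?xml|^\\s*<sbml", first)) {
    read_sbml_model(file, objective)
  } else {
    read_reaction_table(file, objective)
  }
}
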