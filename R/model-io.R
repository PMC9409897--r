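# Model readers/writers.
#
# Native schema "fluxprint-model/1" (JSON): a single document with
# compartments, genes, metabolites, reactions (decimal-string bounds) and the
# objective. An equivalent 3-file TSV dialect (metabolites.tsv, reactions.tsv,
# genes.tsv) serialises stoichiometry as "met:coef;met:coef". A best-effort
# importer for the standard systems-biology XML exchange format is provided
# for externally distributed models.

MODEL_SCHEMA <- "fluxprint-model/1"

#' Save a metabolic model
#'
#' Writes the canonical form: records sorted by id, empty annotation fields
#' omitted, bounds as decimal strings (so load∘save is an exact round-trip).
#'
#' @param model A valid `metabolic_model`.
#' @param path Output file (JSON) or directory (TSV dialect).
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") save_model_json(model, path) else save_model_tsv(model, path)
  invisible(path)
}

canonicalize <- function(model) {
  model$metabolites <- arrange(model$metabolites, .data$id)
  model$reactions <- arrange(model$reactions, .data$id)
  model$genes <- arrange(model$genes, .data$id)
  model$reactions$stoichiometry <- lapply(
    model$reactions$stoichiometry,
    function(st) st[order(names(st))]
  )
  model
}

save_model_json <- function(model, path) {
  model <- canonicalize(model)
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    rec <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) rec$formula <- m$formula
    if (!identical(m$compound_class, "unknown")) rec$compound_class <- m$compound_class
    ann <- m$annotations[[1]]
    if (length(ann)) rec$annotations <- as.list(ann)
    rec
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    rec <- list(
      id = r$id, name = r$name,
      stoichiometry = as.list(r$stoichiometry[[1]]),
      lower_bound = r$lower_bound, upper_bound = r$upper_bound
    )
    if (nzchar(r$gpr)) rec$gpr <- r$gpr
    if (!is.na(r$category)) rec$category <- r$category
    if (!is.na(r$subsystem)) rec$subsystem <- r$subsystem
    if (!is.na(r$ec)) rec$ec <- r$ec
    if (!is.na(r$provenance)) rec$provenance <- r$provenance
    rec
  })
  doc <- list(
    schema = MODEL_SCHEMA, id = model$id,
    compartments = as.list(model$compartments),
    genes = lapply(model$genes$id, function(g) list(id = g)),
    metabolites = mets, reactions = rxns,
    objective = model$objective
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

save_model_tsv <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  model <- canonicalize(model)
  mets <- model$metabolites %>%
    mutate(annotations = map_chr(.data$annotations, function(a) {
      if (!length(a)) "" else paste(names(a), unname(a), sep = "=", collapse = ";")
    }))
  readr::write_tsv(mets, file.path(dir, "metabolites.tsv"))
  rxns <- model$reactions %>%
    mutate(stoichiometry = map_chr(.data$stoichiometry, function(st) {
      paste(names(st), format_bound(unname(st)), sep = ":", collapse = ";")
    }))
  readr::write_tsv(rxns, file.path(dir, "reactions.tsv"))
  readr::write_tsv(model$genes, file.path(dir, "genes.tsv"))
  meta <- tibble(
    key = c("schema", "id", "objective", "compartments"),
    value = c(
      MODEL_SCHEMA, model$id, model$objective,
      paste(names(model$compartments), unname(model$compartments), sep = "=", collapse = ";")
    )
  )
  readr::write_tsv(meta, file.path(dir, "model.tsv"))
}

#' Load a metabolic model
#'
#' @param path File (JSON / XML exchange format) or directory (TSV dialect).
#' @param format `"json"`, `"tsv"` or `"sbml-import"`; guessed from `path`
#'   when omitted.
#' @param check Validate after loading (dangling references etc. become
#'   errors listing the offending ids).
#' @return A `metabolic_model`.
#' @export
load_model <- function(path, format = c("guess", "json", "tsv", "sbml-import"),
                       check = TRUE) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (dir.exists(path)) {
      "tsv"
    } else if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml-import"
    } else {
      "json"
    }
  }
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  switch(format,
    json = load_model_json(path, check = check),
    tsv = load_model_tsv(path, check = check),
    `sbml-import` = read_sbml_model(path, check = check)
  )
}

load_model_json <- function(path, check = TRUE) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$schema) || !identical(doc$schema, MODEL_SCHEMA)) {
    stop("parse error in ", path, ": missing or unsupported schema field (expected '",
      MODEL_SCHEMA, "')",
      call. = FALSE
    )
  }
  need <- function(rec, field, what, i) {
    if (is.null(rec[[field]])) {
      stop("parse error in ", path, ": ", what, " record ", i,
        " lacks required field '", field, "'",
        call. = FALSE
      )
    }
    rec[[field]]
  }
  mets <- bind_rows(lapply(seq_along(doc$metabolites), function(i) {
    m <- doc$metabolites[[i]]
    metabolite(
      id = need(m, "id", "metabolite", i),
      name = m$name %||% m$id,
      compartment = m$compartment %||% guess_compartment(m$id),
      formula = m$formula %||% NA_character_,
      compound_class = m$compound_class %||% "unknown",
      annotations = unlist(m$annotations) %||% character()
    )
  }))
  rxns <- bind_rows(lapply(seq_along(doc$reactions), function(i) {
    r <- doc$reactions[[i]]
    st <- need(r, "stoichiometry", "reaction", i)
    stv <- vapply(st, as.numeric, numeric(1))
    if (!length(stv)) {
      stop("parse error in ", path, ": reaction '", r$id %||% i,
        "' has empty stoichiometry",
        call. = FALSE
      )
    }
    reaction(
      id = need(r, "id", "reaction", i), stoichiometry = stv,
      lower_bound = as.character(r$lower_bound %||% -BIG_M),
      upper_bound = as.character(r$upper_bound %||% BIG_M),
      gpr = r$gpr %||% "", category = r$category %||% NA_character_,
      subsystem = r$subsystem %||% NA_character_, name = r$name %||% r$id,
      ec = r$ec %||% NA_character_, provenance = r$provenance %||% NA_character_
    )
  }))
  genes <- tibble(id = map_chr(doc$genes, "id"))
  model <- metabolic_model(
    id = doc$id %||% "model",
    metabolites = mets, reactions = rxns,
    compartments = unlist(doc$compartments),
    genes = if (nrow(genes)) genes else NULL,
    objective = doc$objective %||% NULL,
    check = FALSE
  )
  if (check) stop_on_issues(model, path)
  model
}

stop_on_issues <- function(model, path) {
  issues <- validate_model(model)
  if (nrow(issues)) {
    stop(
      "validation error in ", path, ": ",
      paste(issues$message, collapse = "; "),
      call. = FALSE
    )
  }
  invisible(model)
}

parse_stoich_string <- function(s, id) {
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) {
    stop("parse error: reaction '", id, "' has malformed stoichiometry '", s, "'",
      call. = FALSE
    )
  }
  setNames(
    vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
    vapply(kv, `[[`, character(1), 1)
  )
}

load_model_tsv <- function(dir, check = TRUE) {
  files <- file.path(dir, c("model.tsv", "metabolites.tsv", "reactions.tsv", "genes.tsv"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("parse error: TSV model directory lacks ", paste(basename(missing), collapse = ", "),
      call. = FALSE
    )
  }
  meta <- readr::read_tsv(files[1], col_types = "cc")
  kv <- setNames(meta$value, meta$key)
  mets_raw <- readr::read_tsv(files[2], col_types = readr::cols(.default = "c"))
  mets <- mets_raw %>%
    mutate(annotations = lapply(.data$annotations, function(a) {
      if (is.na(a) || !nzchar(a)) return(character())
      pr <- strsplit(strsplit(a, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
      setNames(vapply(pr, `[[`, character(1), 2), vapply(pr, `[[`, character(1), 1))
    }))
  rxns_raw <- readr::read_tsv(files[3], col_types = readr::cols(.default = "c"))
  rxns <- rxns_raw %>%
    mutate(stoichiometry = map2(.data$stoichiometry, .data$id, parse_stoich_string))
  genes <- readr::read_tsv(files[4], col_types = "c")
  cmp_pairs <- strsplit(strsplit(kv[["compartments"]], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  compartments <- setNames(
    vapply(cmp_pairs, `[[`, character(1), 2),
    vapply(cmp_pairs, `[[`, character(1), 1)
  )
  model <- metabolic_model(
    id = kv[["id"]], metabolites = mets, reactions = rxns,
    compartments = compartments, genes = genes,
    objective = kv[["objective"]], check = FALSE
  )
  if (check) stop_on_issues(model, dir)
  model
}

#' Import a model from the standard systems-biology XML exchange format
#'
#' Best-effort, level/version tolerant import: species become metabolites
#' (boundary species are dropped and their reactions become exchanges),
#' reactant/product lists become stoichiometry, flux bounds are taken from
#' `fbc` attributes or kinetic-law parameters when present (else big-M
#' defaults), and GPRs from `fbc:geneProductAssociation` or legacy
#' `GENE_ASSOCIATION` notes.
#'
#' @param path XML file.
#' @param check Validate after import.
#' @param compartment_map Optional named character remapping compartment ids.
#' @return A `metabolic_model`.
#' @export
read_sbml_model <- function(path, check = TRUE, compartment_map = NULL) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model_node <- xml2::xml_find_first(doc, ".//model")
  if (is.na(model_node)) stop("parse error in ", path, ": no <model> element", call. = FALSE)
  mid <- xml2::xml_attr(model_node, "id")

  cnodes <- xml2::xml_find_all(model_node, ".//listOfCompartments/compartment")
  compartments <- setNames(
    ifelse(is.na(xml2::xml_attr(cnodes, "name")), xml2::xml_attr(cnodes, "id"),
      xml2::xml_attr(cnodes, "name")
    ),
    xml2::xml_attr(cnodes, "id")
  )
  if (!is.null(compartment_map)) {
    names(compartments) <- ifelse(
      names(compartments) %in% names(compartment_map),
      compartment_map[names(compartments)], names(compartments)
    )
  }

  snodes <- xml2::xml_find_all(model_node, ".//listOfSpecies/species")
  boundary <- xml2::xml_attr(snodes, "boundaryCondition") %in% c("true", "1")
  sp_id <- xml2::xml_attr(snodes, "id")
  mets <- bind_rows(lapply(which(!boundary), function(i) {
    metabolite(
      id = sp_id[i],
      name = xml2::xml_attr(snodes[i], "name") %||% sp_id[i],
      compartment = xml2::xml_attr(snodes[i], "compartment"),
      formula = xml2::xml_attr(snodes[i], "chemicalFormula") %||% NA_character_
    )
  }))
  boundary_ids <- sp_id[boundary]

  gp_nodes <- xml2::xml_find_all(model_node, ".//listOfGeneProducts/geneProduct")
  gene_labels <- setNames(
    ifelse(is.na(xml2::xml_attr(gp_nodes, "label")), xml2::xml_attr(gp_nodes, "id"),
      xml2::xml_attr(gp_nodes, "label")
    ),
    xml2::xml_attr(gp_nodes, "id")
  )

  # flux-bound parameters declared at model level (fbc style)
  pnodes <- xml2::xml_find_all(model_node, ".//listOfParameters/parameter")
  params <- setNames(
    as.numeric(xml2::xml_attr(pnodes, "value")),
    xml2::xml_attr(pnodes, "id")
  )

  rnodes <- xml2::xml_find_all(model_node, ".//listOfReactions/reaction")
  rxns <- bind_rows(lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    sref <- function(xpath, sign) {
      nodes <- xml2::xml_find_all(rn, xpath)
      if (!length(nodes)) return(numeric())
      coef <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      coef[is.na(coef)] <- 1
      setNames(sign * coef, xml2::xml_attr(nodes, "species"))
    }
    st <- c(sref("./listOfReactants/speciesReference", -1),
      sref("./listOfProducts/speciesReference", +1)
    )
    st <- st[!names(st) %in% boundary_ids]
    if (!length(st)) return(empty_reactions())
    st <- tapply(st, names(st), sum)
    st <- setNames(as.numeric(st), names(st))
    st <- st[st != 0]
    if (!length(st)) return(empty_reactions())
    rev <- !identical(xml2::xml_attr(rn, "reversible"), "false")
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(params)) params[[lb_ref]] else NA
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(params)) params[[ub_ref]] else NA
    for (pn in xml2::xml_find_all(rn, ".//kineticLaw//parameter")) {
      pid <- toupper(xml2::xml_attr(pn, "id"))
      val <- as.numeric(xml2::xml_attr(pn, "value"))
      if (pid == "LOWER_BOUND" && is.na(lb)) lb <- val
      if (pid == "UPPER_BOUND" && is.na(ub)) ub <- val
    }
    if (is.na(lb)) lb <- if (rev) -BIG_M else 0
    if (is.na(ub)) ub <- BIG_M
    gpr <- ""
    gpa <- xml2::xml_find_first(rn, "./geneProductAssociation")
    if (!is.na(gpa)) {
      gpr <- sbml_gpa_to_string(gpa, gene_labels)
    } else {
      notes <- xml2::xml_text(xml2::xml_find_first(rn, "./notes"))
      m <- regmatches(notes, regexpr("GENE_ASSOCIATION:[^<\n]*", notes))
      if (length(m) && !is.na(m)) gpr <- trimws(sub("GENE_ASSOCIATION:", "", m))
    }
    reaction(
      id = rid, stoichiometry = st, lower_bound = lb, upper_bound = ub,
      gpr = gpr, name = xml2::xml_attr(rn, "name") %||% rid,
      provenance = "sbml-import"
    )
  }))
  model <- metabolic_model(
    id = mid %||% "sbml-model", metabolites = mets, reactions = rxns,
    compartments = compartments, check = FALSE
  )
  if (check) stop_on_issues(model, path)
  model
}

sbml_gpa_to_string <- function(node, gene_labels) {
  walk <- function(n) {
    nm <- xml2::xml_name(n)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(n, "geneProduct")
      return(if (ref %in% names(gene_labels)) gene_labels[[ref]] else ref)
    }
    kids <- xml2::xml_children(n)
    parts <- vapply(kids, walk, character(1))
    if (nm == "and") paste0("(", paste(parts, collapse = " and "), ")")
    else if (nm == "or") paste0("(", paste(parts, collapse = " or "), ")")
    else paste(parts, collapse = " ")
  }
  kids <- xml2::xml_children(node)
  if (!length(kids)) return("")
  trimws(walk(kids[[1]]))
}
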