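# Metabolic model container.
#
# A `metabolic_model` is a list with tibble components:
#   id           model id/version string
#   compartments named character: suffix -> human-readable name
#   genes        tibble(id)
#   metabolites  tibble(id, name, formula, compartment, compound_class,
#                       annotations <list of named character>)
#   reactions    tibble(id, name, stoichiometry <list of named numeric>,
#                       lower_bound, upper_bound (decimal strings),
#                       gpr, category, subsystem, ec, provenance)
#   objective    reaction id (defaults to the biomass reaction)
#
# Flux bounds are carried as decimal strings and parsed to doubles only at
# solve time, so file round-trips are exact.

REACTION_CATEGORIES <- c("enzymatic", "transport", "exchange", "spontaneous", "biomass")

# Compound classes observed in fungal exometabolome annotation work; features
# without a database match stay "unknown".
COMPOUND_CLASSES <- c(
  "alkaloids", "benzene and substituted derivatives",
  "cinnamic acids and derivatives", "fatty acyls", "flavonoids",
  "glycerolipids", "glycerophospholipids", "hydroxy acids and derivatives",
  "imidazopyrimidines", "indoles and derivatives", "inorganic acid compounds",
  "keto acids and derivatives", "nucleosides", "organic acids and derivatives",
  "organic compounds", "organic nitrogen compounds", "organic oxygen compounds",
  "organohalogen compounds", "organooxygen compounds", "prenol lipids",
  "sphingolipids", "steroids and steroid derivatives", "sterol lipids",
  "unknown"
)

# Shortest decimal string that parses back to exactly the same double.
format_bound <- function(x) {
  vapply(x, function(v) {
    if (is.character(v)) return(v)
    v <- as.numeric(v)
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g", width = -1)
      if (as.numeric(s) == v) return(s)
    }
    formatC(v, digits = 17, format = "g", width = -1)
  }, character(1))
}

#' Construct a metabolite record
#'
#' @param id Unique metabolite id; by convention carries a compartment suffix
#'   (`_c` cytosol, `_e` extracellular).
#' @param name Free-text name.
#' @param compartment Compartment identifier (must be declared in the model).
#' @param formula Elemental formula string, or `NA`.
#' @param compound_class Class label (see `COMPOUND_CLASSES`); default "unknown".
#' @param annotations Named character vector of database cross-references
#'   (e.g. `c(kegg = "C00836", inchi = "InChI=...")`).
#' @return One-row tibble.
#' @export
metabolite <- function(id, name = id, compartment = guess_compartment(id),
                       formula = NA_character_, compound_class = "unknown",
                       annotations = character()) {
  tibble(
    id = id, name = name, formula = as.character(formula),
    compartment = compartment, compound_class = compound_class,
    annotations = list(annotations)
  )
}

guess_compartment <- function(id) {
  m <- regmatches(id, regexpr("_([a-z0-9]+)$", id))
  if (length(m) && nzchar(m)) sub("^_", "", m) else "c"
}

#' Construct a reaction record
#'
#' @param id Unique reaction id.
#' @param stoichiometry Named numeric vector, metabolite id -> signed
#'   coefficient (negative = consumed).
#' @param lower_bound,upper_bound Flux bounds in mmol/gDW/h (numeric or
#'   decimal string; stored as decimal strings).
#' @param gpr GPR string (empty = no gene association).
#' @param category One of enzymatic, transport, exchange, spontaneous,
#'   biomass, or `NA` to infer later.
#' @param subsystem Pathway label, e.g. "Sphingolipid biosynthesis".
#' @param name Free-text name.
#' @param ec EC number annotation, or `NA`.
#' @param provenance Origin tag (e.g. "footprint", "gap-fill").
#' @return One-row tibble.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -BIG_M, upper_bound = BIG_M,
                     gpr = "", category = NA_character_, subsystem = NA_character_,
                     name = id, ec = NA_character_, provenance = NA_character_) {
  stopifnot(length(stoichiometry) > 0, !is.null(names(stoichiometry)))
  tibble(
    id = id, name = name, stoichiometry = list(stoichiometry),
    lower_bound = format_bound(lower_bound), upper_bound = format_bound(upper_bound),
    gpr = gpr, category = category, subsystem = subsystem, ec = ec,
    provenance = provenance
  )
}

empty_metabolites <- function() {
  tibble(
    id = character(), name = character(), formula = character(),
    compartment = character(), compound_class = character(),
    annotations = list()
  )
}

empty_reactions <- function() {
  tibble(
    id = character(), name = character(), stoichiometry = list(),
    lower_bound = character(), upper_bound = character(), gpr = character(),
    category = character(), subsystem = character(), ec = character(),
    provenance = character()
  )
}

normalize_met_tbl <- function(metabolites) {
  defaults <- empty_metabolites()
  metabolites <- as_tibble(metabolites)
  for (col in names(defaults)) {
    if (!col %in% names(metabolites)) {
      metabolites[[col]] <- if (col == "annotations") {
        rep(list(character()), nrow(metabolites))
      } else if (col == "compound_class") {
        rep("unknown", nrow(metabolites))
      } else if (col == "name") {
        metabolites$id
      } else if (col == "compartment") {
        vapply(metabolites$id, guess_compartment, character(1), USE.NAMES = FALSE)
      } else {
        rep(NA_character_, nrow(metabolites))
      }
    }
  }
  metabolites[names(defaults)]
}

normalize_rxn_tbl <- function(reactions) {
  defaults <- empty_reactions()
  reactions <- as_tibble(reactions)
  for (col in names(defaults)) {
    if (!col %in% names(reactions)) {
      reactions[[col]] <- switch(col,
        name = reactions$id,
        lower_bound = rep(format_bound(-BIG_M), nrow(reactions)),
        upper_bound = rep(format_bound(BIG_M), nrow(reactions)),
        gpr = rep("", nrow(reactions)),
        rep(NA_character_, nrow(reactions))
      )
    }
  }
  reactions$lower_bound <- format_bound(reactions$lower_bound)
  reactions$upper_bound <- format_bound(reactions$upper_bound)
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions[names(defaults)]
}

#' Construct a metabolic model
#'
#' Assembles and validates a genome-scale (or toy) metabolic model. Genes are
#' derived from GPR expressions when not given; the objective defaults to the
#' unique biomass-category reaction.
#'
#' @param id Model id string.
#' @param metabolites Tibble of metabolite records ([metabolite()] rows).
#' @param reactions Tibble of reaction records ([reaction()] rows).
#' @param compartments Named character, suffix -> name. Defaults to the
#'   compartments referenced by the metabolites.
#' @param genes Tibble with column `id`, or `NULL` to derive from GPRs.
#' @param objective Objective reaction id, or `NULL` for the biomass reaction.
#' @param infer_categories Infer missing reaction category labels with
#'   [classify_reaction()] rules.
#' @param check Validate the assembled model and abort on issues.
#' @return A `metabolic_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, compartments = NULL,
                            genes = NULL, objective = NULL,
                            infer_categories = TRUE, check = TRUE) {
  metabolites <- normalize_met_tbl(metabolites)
  reactions <- normalize_rxn_tbl(reactions)
  if (is.null(compartments)) {
    cmp <- sort(unique(metabolites$compartment))
    known <- c(c = "cytosol", e = "extracellular", m = "mitochondrion", x = "peroxisome")
    compartments <- setNames(
      ifelse(cmp %in% names(known), known[cmp], cmp), cmp
    )
  }
  if (is.null(genes)) {
    gids <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
    genes <- tibble(id = gids)
  } else {
    genes <- as_tibble(genes)["id"]
  }
  model <- structure(
    list(
      id = id, compartments = compartments, genes = genes,
      metabolites = metabolites, reactions = reactions,
      objective = objective
    ),
    class = "metabolic_model"
  )
  if (infer_categories && anyNA(model$reactions$category)) {
    miss <- which(is.na(model$reactions$category))
    model$reactions$category[miss] <- vapply(
      miss, function(i) infer_category(model$reactions$stoichiometry[[i]], model),
      character(1)
    )
  }
  if (is.null(model$objective)) {
    bio <- model$reactions$id[model$reactions$category == "biomass"]
    model$objective <- if (length(bio) == 1L) bio else NA_character_
  }
  if (check) {
    issues <- validate_model(model)
    if (nrow(issues)) {
      stop(
        "invalid model '", id, "': ",
        paste(utils::head(issues$message, 5L), collapse = "; "),
        if (nrow(issues) > 5L) sprintf(" (and %d more)", nrow(issues) - 5L) else "",
        call. = FALSE
      )
    }
  }
  model
}

#' @export
print.metabolic_model <- function(x, ...) {
  st <- compute_model_stats(x)
  cat(sprintf(
    "<metabolic_model> %s: %d genes, %d metabolites, %d reactions\n",
    x$id, st$n_genes, st$n_metabolites, st$n_reactions
  ))
  cat("  objective:", x$objective, "\n")
  invisible(x)
}

rxn_bounds <- function(model) {
  cbind(
    lb = as.numeric(model$reactions$lower_bound),
    ub = as.numeric(model$reactions$upper_bound)
  )
}

# Dense stoichiometric matrix S (metabolites x reactions).
stoich_matrix <- function(model) {
  mets <- model$metabolites$id
  rxns <- model$reactions$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
    dimnames = list(mets, rxns)
  )
  for (j in seq_along(rxns)) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  S
}

base_species <- function(ids, compartments) {
  suffix <- paste0("_(", paste(names(compartments), collapse = "|"), ")$")
  sub(suffix, "", ids)
}

# Category inference rules; explicit labels in input files take precedence.
infer_category <- function(stoich, model, gpr = "", is_objective = FALSE,
                           spontaneous_flag = FALSE) {
  if (is_objective) return("biomass")
  if (length(stoich) == 1L) return("exchange")
  mets <- names(stoich)
  cons <- mets[stoich < 0]
  prod <- mets[stoich > 0]
  if (length(cons) && length(prod)) {
    bs_cons <- sort(base_species(cons, model$compartments))
    bs_prod <- sort(base_species(prod, model$compartments))
    if (identical(bs_cons, bs_prod)) {
      cmp <- model$metabolites$compartment[match(mets, model$metabolites$id)]
      if (length(unique(cmp[!is.na(cmp)])) > 1L) return("transport")
    }
  }
  if (spontaneous_flag && !nzchar(gpr)) return("spontaneous")
  "enzymatic"
}

#' Classify a reaction
#'
#' Applies the standard category rules: a reaction touching exactly one
#' metabolite is an exchange (boundary) reaction; one whose consumed and
#' produced base species are identical but sit in different compartments is a
#' transport; the model objective flagged as biomass is biomass; a reaction
#' explicitly flagged spontaneous with no gene association is spontaneous;
#' anything else is enzymatic. Explicit labels in input files take precedence;
#' this function infers absent labels and audits present ones.
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Reaction id.
#' @return Category string.
#' @export
classify_reaction <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction '", reaction_id, "'", call. = FALSE)
  infer_category(
    model$reactions$stoichiometry[[i]], model,
    gpr = model$reactions$gpr[i],
    is_objective = identical(model$reactions$category[i], "biomass"),
    spontaneous_flag = identical(model$reactions$category[i], "spontaneous")
  )
}

#' Audit stored reaction categories against the classification rules
#'
#' @param model A `metabolic_model`.
#' @return Tibble of disagreements (reaction, stored, inferred); zero rows if
#'   labels and rules agree everywhere.
#' @export
audit_categories <- function(model) {
  inferred <- vapply(model$reactions$id, classify_reaction,
    character(1),
    model = model, USE.NAMES = FALSE
  )
  tibble(
    reaction = model$reactions$id,
    stored = model$reactions$category,
    inferred = inferred
  ) %>% filter(!is.na(.data$stored), .data$stored != .data$inferred)
}

#' Descriptive model statistics
#'
#' Counts genes, metabolites and reactions, with a per-category reaction
#' breakdown. Category counts always sum to the reaction total.
#'
#' @param model A `metabolic_model`.
#' @return A `model_stats` list: `n_genes`, `n_metabolites`, `n_reactions`,
#'   and `categories` (named integer vector over the five categories).
#' @export
compute_model_stats <- function(model) {
  cats <- table(factor(model$reactions$category, levels = REACTION_CATEGORIES))
  structure(
    list(
      model_id = model$id,
      n_genes = nrow(model$genes),
      n_metabolites = nrow(model$metabolites),
      n_reactions = nrow(model$reactions),
      categories = setNames(as.integer(cats), REACTION_CATEGORIES)
    ),
    class = "model_stats"
  )
}

#' @export
print.model_stats <- function(x, ...) {
  cat(sprintf(
    "<model_stats> %s\n  genes: %d  metabolites: %d  reactions: %d\n",
    x$model_id, x$n_genes, x$n_metabolites, x$n_reactions
  ))
  for (k in names(x$categories)) cat(sprintf("    %-12s %d\n", k, x$categories[[k]]))
  invisible(x)
}

#' @method tidy model_stats
#' @export
tidy.model_stats <- function(x, ...) {
  tibble(
    model = x$model_id,
    statistic = c(
      "n_genes", "n_metabolites", "n_reactions",
      paste0("n_", names(x$categories))
    ),
    value = c(x$n_genes, x$n_metabolites, x$n_reactions, unname(x$categories))
  )
}

#' Audit declared counts against computed statistics
#'
#' Published model tables occasionally disagree with themselves (a category
#' breakdown that does not sum to the declared reaction total). This audit
#' reports such inconsistencies between externally declared counts and the
#' statistics computed from the model — it never silently resolves them.
#'
#' @param stats A `model_stats` (from [compute_model_stats()]).
#' @param declared Named numeric vector of declared counts; recognised names
#'   are `n_genes`, `n_metabolites`, `n_reactions` and `n_<category>`.
#' @return Tibble(statistic, declared, computed, discrepancy); zero rows if
#'   everything agrees.
#' @export
audit_declared_counts <- function(stats, declared) {
  computed <- tidy.model_stats(stats)
  tibble(
    statistic = names(declared),
    declared = as.numeric(declared)
  ) %>%
    left_join(computed[c("statistic", "value")], by = "statistic") %>%
    rename(computed = "value") %>%
    mutate(discrepancy = .data$computed - .data$declared) %>%
    filter(is.na(.data$computed) | .data$discrepancy != 0)
}

#' Validate a metabolic model
#'
#' Checks every structural invariant and returns issues as data rather than
#' raising: dangling stoichiometry or GPR references, duplicate ids, bound
#' violations (lower > upper), orphan metabolites appearing in no reaction,
#' missing or multiple biomass reactions, unresolved objective, and
#' compartments outside the declared set.
#'
#' @param model A `metabolic_model` (possibly invalid).
#' @return Tibble(type, ids, message); zero rows iff all invariants hold.
#' @export
validate_model <- function(model) {
  issues <- list()
  add <- function(type, ids, message) {
    issues[[length(issues) + 1L]] <<- tibble(
      type = type, ids = list(ids), message = message
    )
  }
  dup_m <- unique(model$metabolites$id[duplicated(model$metabolites$id)])
  if (length(dup_m)) add("duplicate_metabolite", dup_m, paste("duplicate metabolite ids:", paste(dup_m, collapse = ", ")))
  dup_r <- unique(model$reactions$id[duplicated(model$reactions$id)])
  if (length(dup_r)) add("duplicate_reaction", dup_r, paste("duplicate reaction ids:", paste(dup_r, collapse = ", ")))
  dup_g <- unique(model$genes$id[duplicated(model$genes$id)])
  if (length(dup_g)) add("duplicate_gene", dup_g, paste("duplicate gene ids:", paste(dup_g, collapse = ", ")))

  used_mets <- character()
  for (i in seq_len(nrow(model$reactions))) {
    st <- model$reactions$stoichiometry[[i]]
    rid <- model$reactions$id[i]
    if (!length(st)) add("empty_stoichiometry", rid, paste0("reaction ", rid, " has empty stoichiometry"))
    dangling <- setdiff(names(st), model$metabolites$id)
    if (length(dangling)) {
      add("dangling_metabolite", dangling, paste0(
        "reaction ", rid, " references undeclared metabolites: ",
        paste(dangling, collapse = ", ")
      ))
    }
    used_mets <- c(used_mets, names(st))
    gg <- tryCatch(gpr_genes(model$reactions$gpr[i]), error = function(e) {
      add("malformed_gpr", rid, conditionMessage(e))
      character()
    })
    dang_g <- setdiff(gg, model$genes$id)
    if (length(dang_g)) {
      add("dangling_gene", dang_g, paste0(
        "reaction ", rid, " GPR references undeclared genes: ",
        paste(dang_g, collapse = ", ")
      ))
    }
  }
  b <- rxn_bounds(model)
  bad <- which(b[, "lb"] > b[, "ub"])
  for (i in bad) {
    add("bound_violation", model$reactions$id[i], paste0(
      "reaction ", model$reactions$id[i], " has lower_bound > upper_bound"
    ))
  }
  orphan <- setdiff(model$metabolites$id, unique(used_mets))
  if (length(orphan)) add("orphan_metabolite", orphan, paste("metabolites in no reaction:", paste(orphan, collapse = ", ")))
  bad_cmp <- setdiff(unique(model$metabolites$compartment), names(model$compartments))
  if (length(bad_cmp)) add("undeclared_compartment", bad_cmp, paste("undeclared compartments:", paste(bad_cmp, collapse = ", ")))
  n_bio <- sum(model$reactions$category == "biomass", na.rm = TRUE)
  if (n_bio > 1L) {
    add(
      "multiple_biomass", model$reactions$id[which(model$reactions$category == "biomass")],
      sprintf("%d biomass reactions declared (expected exactly one)", n_bio)
    )
  }
  if (!is.na(model$objective) && !model$objective %in% model$reactions$id) {
    add("missing_objective", model$objective, paste0("objective reaction '", model$objective, "' not in model"))
  }
  if (length(issues)) bind_rows(issues) else tibble(type = character(), ids = list(), message = character())
}
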