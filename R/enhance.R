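# Model enhancement: footprint-metabolite incorporation, gap-filling against
# a universal reaction set, GPR updates, and model diffing.

#' Incorporate footprint metabolites into a model
#'
#' Exometabolome (metabolic footprint) records are matched against existing
#' model metabolites by external identifier with precedence
#' InChI > KEGG > ChEBI > PubChem > case-folded name (first match wins; all
#' candidate matches are logged). Unmatched records become new extracellular
#' metabolites with an exchange reaction; when a cytosolic counterpart
#' already exists, a transport reaction links the two compartments. All
#' additions carry provenance `"footprint"`.
#'
#' @param model A `metabolic_model`.
#' @param records Tibble of footprint records with columns `name` and at
#'   least one of `formula`, `inchi`, `kegg`, `chebi`, `pubchem`; optional
#'   `mw`, `class`, `compartment` (default `"e"`).
#' @return List: `model` (enhanced), `matches` (per-record log: record,
#'   matched, matched_by, metabolite/action), `rejected` (records with no
#'   identifying field).
#' @export
incorporate_footprint_metabolites <- function(model, records) {
  records <- as_tibble(records)
  for (col in c("formula", "inchi", "kegg", "chebi", "pubchem", "class", "compartment")) {
    if (!col %in% names(records)) records[[col]] <- NA_character_
  }
  records$compartment[is.na(records$compartment)] <- "e"
  if (!"e" %in% names(model$compartments)) {
    model$compartments <- c(model$compartments, e = "extracellular")
  }

  ann_tbl <- function(key) {
    vals <- map_chr(model$metabolites$annotations, function(a) {
      if (key %in% names(a)) a[[key]] else NA_character_
    })
    tibble(
      key = vals, id = model$metabolites$id,
      compartment = model$metabolites$compartment
    ) %>% filter(!is.na(.data$key))
  }
  lookups <- list(
    inchi = ann_tbl("inchi"), kegg = ann_tbl("kegg"),
    chebi = ann_tbl("chebi"), pubchem = ann_tbl("pubchem"),
    name = tibble(
      key = tolower(model$metabolites$name), id = model$metabolites$id,
      compartment = model$metabolites$compartment
    )
  )
  # among multiple hits prefer one in the record's target compartment
  find_match <- function(key, value, cmp) {
    if (is.na(value)) return(NA_character_)
    hits <- lookups[[key]][lookups[[key]]$key == value, ]
    if (!nrow(hits)) return(NA_character_)
    in_cmp <- hits$id[hits$compartment == cmp]
    if (length(in_cmp)) in_cmp[1] else hits$id[1]
  }

  logs <- list()
  rejected <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (all(is.na(c(rec$formula, rec$inchi, rec$kegg, rec$chebi, rec$pubchem)))) {
      rejected[[length(rejected) + 1L]] <- mutate(rec, reason = "no identifying field (formula/InChI/external id)")
      next
    }
    hit <- NULL
    matched_by <- NA_character_
    queries <- c(
      inchi = rec$inchi, kegg = rec$kegg, chebi = rec$chebi,
      pubchem = rec$pubchem, name = tolower(rec$name)
    )
    for (key in names(queries)) {
      h <- find_match(key, queries[[key]], rec$compartment)
      if (!is.na(h)) {
        hit <- h
        matched_by <- key
        break
      }
    }
    if (!is.null(hit)) {
      hit_cmp <- model$metabolites$compartment[match(hit, model$metabolites$id)]
      if (identical(hit_cmp, rec$compartment)) {
        logs[[length(logs) + 1L]] <- tibble(
          record = rec$name, matched = TRUE, matched_by = matched_by,
          metabolite = hit, action = "matched existing metabolite"
        )
        next
      }
      # matched an intracellular species: the footprint observation is
      # extracellular, so add the boundary species, its exchange, and a
      # transport reaction linking the two
      base <- gsub("^_+|_+$", "", gsub("[^a-z0-9]+", "_", tolower(rec$name)))
      new_id <- paste0(base, "_", rec$compartment)
      k <- 1L
      while (new_id %in% model$metabolites$id) {
        k <- k + 1L
        new_id <- paste0(base, k, "_", rec$compartment)
      }
      hit_row <- model$metabolites[match(hit, model$metabolites$id), ]
      model$metabolites <- bind_rows(
        model$metabolites,
        metabolite(new_id,
          name = hit_row$name, compartment = rec$compartment,
          formula = hit_row$formula, compound_class = hit_row$compound_class,
          annotations = hit_row$annotations[[1]]
        )
      )
      model <- add_exchange(model, new_id, lb = -BIG_M, ub = BIG_M, provenance = "footprint")
      tid <- paste0("T_", base)
      if (!tid %in% model$reactions$id) {
        model$reactions <- bind_rows(
          model$reactions,
          reaction(tid,
            stoichiometry = setNames(c(-1, 1), c(hit, new_id)),
            lower_bound = -BIG_M, upper_bound = BIG_M,
            category = "transport", provenance = "footprint"
          )
        )
      }
      logs[[length(logs) + 1L]] <- tibble(
        record = rec$name, matched = TRUE, matched_by = matched_by,
        metabolite = new_id,
        action = "matched intracellular species; added exchange + transport"
      )
      next
    }
    # new extracellular metabolite + exchange (+ transport when a cytosolic
    # counterpart is present)
    base <- gsub("[^a-z0-9]+", "_", tolower(rec$name))
    base <- gsub("^_+|_+$", "", base)
    new_id <- paste0(base, "_", rec$compartment)
    k <- 1L
    while (new_id %in% model$metabolites$id) {
      k <- k + 1L
      new_id <- paste0(base, k, "_", rec$compartment)
    }
    ann <- c(
      inchi = rec$inchi, kegg = rec$kegg, chebi = rec$chebi,
      pubchem = rec$pubchem
    )
    ann <- ann[!is.na(ann)]
    model$metabolites <- bind_rows(
      model$metabolites,
      metabolite(new_id,
        name = rec$name, compartment = rec$compartment,
        formula = rec$formula,
        compound_class = if (is.na(rec$class)) "unknown" else rec$class,
        annotations = ann
      )
    )
    model <- add_exchange(model, new_id, lb = -BIG_M, ub = BIG_M, provenance = "footprint")
    logs[[length(logs) + 1L]] <- tibble(
      record = rec$name, matched = FALSE, matched_by = NA_character_,
      metabolite = new_id, action = "added metabolite + exchange"
    )
  }
  list(
    model = model,
    matches = if (length(logs)) bind_rows(logs) else {
      tibble(
        record = character(), matched = logical(), matched_by = character(),
        metabolite = character(), action = character()
      )
    },
    rejected = if (length(rejected)) bind_rows(rejected) else tibble()
  )
}

target_flux <- function(model, target) {
  if (target %in% model$reactions$id) {
    sol <- solve_fba(model, objective = target)
  } else if (target %in% model$metabolites$id) {
    dm <- paste0("DM_", target)
    if (!dm %in% model$reactions$id) {
      model <- add_demand(model, target)
    }
    sol <- solve_fba(model, objective = dm)
  } else {
    stop("gap-fill target '", target, "' is neither a reaction nor a metabolite", call. = FALSE)
  }
  if (sol$status == "optimal") sol$objective_value else 0
}

add_demand <- function(model, metabolite_id, provenance = "added-for-screen") {
  dm <- paste0("DM_", metabolite_id)
  if (dm %in% model$reactions$id) return(model)
  model$reactions <- bind_rows(
    model$reactions,
    reaction(dm,
      stoichiometry = setNames(-1, metabolite_id),
      lower_bound = 0, upper_bound = BIG_M, category = "exchange",
      provenance = provenance
    )
  )
  model
}

add_universe_reactions <- function(model, universe, ids) {
  keep <- universe$reactions[universe$reactions$id %in% ids, ]
  new_mets <- setdiff(
    unique(unlist(lapply(keep$stoichiometry, names))),
    model$metabolites$id
  )
  if (length(new_mets)) {
    extra <- universe$metabolites[universe$metabolites$id %in% new_mets, ]
    plain <- setdiff(new_mets, extra$id)
    if (length(plain)) extra <- bind_rows(extra, bind_rows(lapply(plain, metabolite)))
    model$metabolites <- bind_rows(model$metabolites, extra)
    new_cmp <- setdiff(unique(extra$compartment), names(model$compartments))
    if (length(new_cmp)) {
      model$compartments <- c(model$compartments, setNames(new_cmp, new_cmp))
    }
  }
  keep$provenance <- "gap-fill"
  model$reactions <- bind_rows(model$reactions, keep)
  new_genes <- setdiff(unique(unlist(lapply(keep$gpr, gpr_genes))), model$genes$id)
  if (length(new_genes)) model$genes <- bind_rows(model$genes, tibble(id = new_genes))
  model
}

#' Gap-fill a model against a universal reaction set
#'
#' Finds a set of candidate reactions whose addition makes the target
#' (metabolite production or biomass flux) achievable at rate >= `epsilon`.
#' The default procedure is deterministic and greedy: open every universe
#' reaction, confirm achievability, then remove candidates one at a time in
#' lexicographic id order whenever removal keeps the target achievable,
#' repeating until no single candidate can be dropped — the returned set is
#' therefore irreducible. With `exact = TRUE` the minimum-cardinality set is
#' found by subset enumeration in increasing size (practical for universes
#' up to ~12 reactions).
#'
#' @param model A `metabolic_model` in which the target is currently
#'   unachievable (otherwise the empty set is returned).
#' @param universe A `metabolic_model` (or list with `reactions`,
#'   `metabolites` tibbles) of candidate reactions; ids must not clash with
#'   the model's.
#' @param target Reaction id (flux target, e.g. biomass) or metabolite id
#'   (production target via a demand reaction).
#' @param epsilon Minimal target flux that counts as achieved
#'   (mmol/gDW/h; deliberately larger than the 1e-10 reporting threshold so
#'   numerical noise is never "filled").
#' @param exact Search for a cardinality-minimal set by enumeration.
#' @return A `gap_fill_result`: `added` (ordered reaction ids), `flux`
#'   achieved, `iterations`, `status` (`"filled"`, `"already-achievable"`,
#'   `"unfillable"`), and `model` with the additions applied.
#' @export
gap_fill <- function(model, universe, target, epsilon = 1e-6, exact = FALSE) {
  if (!nrow(universe$reactions)) stop("universal reaction set is empty", call. = FALSE)
  base_flux <- target_flux(model, target)
  if (base_flux >= epsilon) {
    return(structure(
      list(
        added = character(), flux = base_flux, iterations = 0L,
        status = "already-achievable", model = model
      ),
      class = "gap_fill_result"
    ))
  }
  clash <- intersect(universe$reactions$id, model$reactions$id)
  if (length(clash)) {
    stop("universe reaction ids clash with the model: ", paste(clash, collapse = ", "),
      call. = FALSE
    )
  }
  uids <- sort(universe$reactions$id)
  flux_with <- function(ids) target_flux(add_universe_reactions(model, universe, ids), target)
  full_flux <- flux_with(uids)
  iterations <- 1L
  if (full_flux < epsilon) {
    dead <- dead_end_metabolites(add_universe_reactions(model, universe, uids))
    return(structure(
      list(
        added = character(), flux = full_flux, iterations = iterations,
        status = "unfillable", model = model, dead_ends = dead
      ),
      class = "gap_fill_result"
    ))
  }
  if (exact) {
    for (k in seq_along(uids)) {
      combos <- utils::combn(uids, k, simplify = FALSE)
      for (set in combos) {
        iterations <- iterations + 1L
        if (flux_with(set) >= epsilon) {
          final <- add_universe_reactions(model, universe, set)
          return(structure(
            list(
              added = set, flux = flux_with(set), iterations = iterations,
              status = "filled", model = final
            ),
            class = "gap_fill_result"
          ))
        }
      }
    }
  }
  # greedy removal from the full set, lexicographic order, until irreducible
  current <- uids
  repeat {
    removed_any <- FALSE
    for (r in current) {
      trial <- setdiff(current, r)
      iterations <- iterations + 1L
      if (flux_with(trial) >= epsilon) {
        current <- trial
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  final <- add_universe_reactions(model, universe, current)
  structure(
    list(
      added = current, flux = flux_with(current), iterations = iterations,
      status = "filled", model = final
    ),
    class = "gap_fill_result"
  )
}

#' @export
print.gap_fill_result <- function(x, ...) {
  cat(
    "<gap_fill_result>", x$status, "- added", length(x$added), "reaction(s)",
    if (length(x$added)) paste0("[", paste(x$added, collapse = ", "), "]") else "",
    sprintf("flux %.4g\n", x$flux)
  )
  invisible(x)
}

#' @method glance gap_fill_result
#' @export
glance.gap_fill_result <- function(x, ...) {
  tibble(
    status = x$status, n_added = length(x$added), flux = x$flux,
    iterations = x$iterations
  )
}

# Metabolites that are consumed but never produced (or vice versa) under the
# current reversibility pattern; a coarse dead-end diagnostic for unfillable
# targets.
dead_end_metabolites <- function(model) {
  S <- stoich_matrix(model)
  b <- rxn_bounds(model)
  producible <- consumable <- rep(FALSE, nrow(S))
  for (j in seq_len(ncol(S))) {
    col <- S[, j]
    if (b[j, "ub"] > 0) {
      producible <- producible | col > 0
      consumable <- consumable | col < 0
    }
    if (b[j, "lb"] < 0) {
      producible <- producible | col < 0
      consumable <- consumable | col > 0
    }
  }
  rownames(S)[!(producible & consumable)]
}

#' Merge GPR updates into a model
#'
#' Replaces the GPR of each listed reaction; genes newly referenced are
#' added to the model gene set. Malformed GPR strings are skipped with a
#' per-row error in the change log.
#'
#' @param model A `metabolic_model`.
#' @param gpr_table Tibble with columns `reaction`, `gpr`.
#' @return List: `model`, `log` (reaction, old, new, status).
#' @export
merge_gpr_updates <- function(model, gpr_table) {
  gpr_table <- as_tibble(gpr_table)
  logs <- list()
  for (i in seq_len(nrow(gpr_table))) {
    rid <- gpr_table$reaction[i]
    j <- match(rid, model$reactions$id)
    if (is.na(j)) {
      logs[[i]] <- tibble(reaction = rid, old = NA, new = gpr_table$gpr[i], status = "unknown reaction; skipped")
      next
    }
    new_genes <- tryCatch(gpr_genes(gpr_table$gpr[i]), error = function(e) e)
    if (inherits(new_genes, "error")) {
      logs[[i]] <- tibble(
        reaction = rid, old = model$reactions$gpr[j], new = gpr_table$gpr[i],
        status = paste("malformed GPR; skipped:", conditionMessage(new_genes))
      )
      next
    }
    logs[[i]] <- tibble(
      reaction = rid, old = model$reactions$gpr[j], new = gpr_table$gpr[i],
      status = "updated"
    )
    model$reactions$gpr[j] <- gpr_table$gpr[i]
    add <- setdiff(new_genes, model$genes$id)
    if (length(add)) model$genes <- bind_rows(model$genes, tibble(id = add))
  }
  list(model = model, log = if (length(logs)) bind_rows(logs) else tibble())
}

#' Diff two metabolic models
#'
#' Set differences of gene, metabolite and reaction ids. Antisymmetric:
#' the new items of `diff_models(a, b)` are the removed items of
#' `diff_models(b, a)`.
#'
#' @param old,new `metabolic_model`s.
#' @return A `model_diff` list of id vectors (`new_genes`, `removed_genes`,
#'   ... ) with a `summary` tibble of counts.
#' @export
diff_models <- function(old, new) {
  d <- list(
    new_genes = setdiff(new$genes$id, old$genes$id),
    removed_genes = setdiff(old$genes$id, new$genes$id),
    new_metabolites = setdiff(new$metabolites$id, old$metabolites$id),
    removed_metabolites = setdiff(old$metabolites$id, new$metabolites$id),
    new_reactions = setdiff(new$reactions$id, old$reactions$id),
    removed_reactions = setdiff(old$reactions$id, new$reactions$id)
  )
  d$summary <- tibble(
    item = c("genes", "metabolites", "reactions"),
    n_new = c(length(d$new_genes), length(d$new_metabolites), length(d$new_reactions)),
    n_removed = c(
      length(d$removed_genes), length(d$removed_metabolites),
      length(d$removed_reactions)
    )
  )
  structure(d, class = "model_diff")
}

#' @export
print.model_diff <- function(x, ...) {
  cat("<model_diff>\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy model_diff
#' @export
tidy.model_diff <- function(x, ...) x$summary
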