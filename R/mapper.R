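# Subsystem extraction and omics overlay: project DAMs and differentially
# expressed genes onto pathway subnetworks (e.g. glycerolipid or sphingolipid
# metabolism) and report the per-reaction response.

#' Extract a subsystem subnetwork from a model
#'
#' Collects every reaction labelled with the subsystem, the metabolites they
#' touch, the genes in their GPRs, and the metabolite-reaction edges implied
#' by stoichiometry. Ordering is deterministic (sorted by id).
#'
#' @param model A `metabolic_model`.
#' @param subsystem Subsystem label; unknown labels raise an error listing
#'   the available ones.
#' @return A `subnetwork_view`: `subsystem`, `reactions` (tibble with ec,
#'   gpr, stoichiometry), `metabolites` (tibble), `genes` (character),
#'   `edges` tibble (metabolite, reaction, coefficient, role).
#' @export
extract_subsystem <- function(model, subsystem) {
  available <- sort(unique(stats::na.omit(model$reactions$subsystem)))
  if (!subsystem %in% available) {
    stop(
      "unknown subsystem '", subsystem, "'; available: ",
      paste(available, collapse = ", "),
      call. = FALSE
    )
  }
  rxns <- model$reactions %>%
    filter(.data$subsystem == !!subsystem) %>%
    arrange(.data$id)
  met_ids <- sort(unique(unlist(lapply(rxns$stoichiometry, names))))
  mets <- model$metabolites %>%
    filter(.data$id %in% met_ids) %>%
    arrange(.data$id)
  genes <- sort(unique(unlist(lapply(rxns$gpr, gpr_genes))))
  edges <- bind_rows(lapply(seq_len(nrow(rxns)), function(i) {
    st <- rxns$stoichiometry[[i]]
    tibble(
      metabolite = names(st), reaction = rxns$id[i],
      coefficient = as.numeric(st),
      role = if_else(st < 0, "substrate", "product")
    )
  })) %>% arrange(.data$reaction, .data$metabolite)
  structure(
    list(
      subsystem = subsystem, reactions = rxns, metabolites = mets,
      genes = genes, edges = edges
    ),
    class = "subnetwork_view"
  )
}

#' @export
print.subnetwork_view <- function(x, ...) {
  cat(sprintf(
    "<subnetwork_view> '%s': %d reactions, %d metabolites, %d genes\n",
    x$subsystem, nrow(x$reactions), nrow(x$metabolites), length(x$genes)
  ))
  invisible(x)
}

strip_name <- function(x) gsub("[^a-z0-9]+", "", tolower(trimws(x)))

match_dam_to_metabolites <- function(dams, metabolites) {
  # external-id first, then case-folded punctuation-stripped name; lipid
  # shorthand matches verbatim after whitespace normalisation
  ann_keys <- c("kegg", "chebi", "pubchem", "inchi")
  lookup <- list()
  for (key in ann_keys) {
    vals <- map_chr(metabolites$annotations, function(a) {
      if (key %in% names(a)) a[[key]] else NA_character_
    })
    lookup[[key]] <- setNames(metabolites$id, vals)[!is.na(vals)]
  }
  by_name <- setNames(metabolites$id, strip_name(metabolites$name))
  by_id <- setNames(metabolites$id, metabolites$id)
  vapply(seq_len(nrow(dams)), function(i) {
    rec <- dams[i, ]
    for (key in ann_keys) {
      if (key %in% names(rec) && !is.na(rec[[key]])) {
        hit <- lookup[[key]][rec[[key]]]
        if (!is.na(hit)) return(unname(hit))
      }
    }
    if (rec$metabolite %in% names(by_id)) return(rec$metabolite)
    hit <- by_name[strip_name(rec$metabolite)]
    if (!is.na(hit)) return(unname(hit))
    NA_character_
  }, character(1))
}

#' Overlay DAM and DEG data on a subnetwork
#'
#' Metabolites gain the log2 fold change and significance of matching DAM
#' records (matched by external id, then normalised name); reactions gain an
#' expression value obtained by numeric GPR evaluation of gene log2 fold
#' changes (OR = max across isozymes, AND = min across complex subunits).
#' Elements without matching data are marked absent (`NA`), never
#' zero-filled, and unmatched input records are reported.
#'
#' @param subnet A `subnetwork_view`.
#' @param dams Flagged DAM tibble (any comparisons; filtered by
#'   `comparison`).
#' @param degs DEG tibble (gene, log2_fold_change, comparison).
#' @param comparison Comparison label to overlay.
#' @return An `annotated_subnetwork`: the view plus `metabolite_overlay`,
#'   `reaction_overlay`, and `unmatched` (list of unmatched dam/deg record
#'   tibbles).
#' @export
overlay_omics <- function(subnet, dams, degs, comparison) {
  dams <- filter(as_tibble(dams), .data$comparison == !!comparison)
  degs <- filter(as_tibble(degs), .data$comparison == !!comparison)
  dam_target <- if (nrow(dams)) {
    match_dam_to_metabolites(dams, subnet$metabolites)
  } else {
    character()
  }
  matched_dams <- !is.na(dam_target)
  metabolite_overlay <- subnet$metabolites["id"] %>%
    rename(metabolite = "id") %>%
    left_join(
      tibble(
        metabolite = dam_target[matched_dams],
        dam_log2fc = dams$log2_fold_change[matched_dams],
        dam_significant = if ("significant" %in% names(dams)) {
          dams$significant[matched_dams]
        } else {
          NA
        },
        dam_record = dams$metabolite[matched_dams]
      ) %>% distinct(.data$metabolite, .keep_all = TRUE),
      by = "metabolite"
    ) %>%
    mutate(comparison = !!comparison)

  deg_values <- setNames(degs$log2_fold_change, degs$gene)
  matched_genes <- intersect(subnet$genes, degs$gene)
  reaction_overlay <- tibble(
    reaction = subnet$reactions$id,
    comparison = comparison,
    expression_log2fc = vapply(subnet$reactions$gpr, function(g) {
      evaluate_gpr(g, deg_values, mode = "numeric", quiet = TRUE)
    }, numeric(1), USE.NAMES = FALSE)
  ) %>%
    mutate(direction = dplyr::case_when(
      is.na(.data$expression_log2fc) ~ NA_character_,
      .data$expression_log2fc < 0 ~ "down",
      TRUE ~ "up"
    ))

  structure(
    c(
      unclass(subnet),
      list(
        metabolite_overlay = metabolite_overlay,
        reaction_overlay = reaction_overlay,
        comparison = comparison,
        unmatched = list(
          dams = dams[!matched_dams, , drop = FALSE],
          degs = filter(degs, !.data$gene %in% subnet$genes)
        ),
        matched_counts = c(
          dams = sum(matched_dams),
          degs = length(matched_genes)
        )
      )
    ),
    class = c("annotated_subnetwork", "subnetwork_view")
  )
}

#' Tabular pathway-response report
#'
#' One row per subnetwork reaction: EC number, gene ids, per-comparison
#' expression overlay, and the DAM status of substrates and products. A
#' reaction is flagged `concordant` in a comparison when its expression
#' direction matches the direction of a significant product DAM, and
#' `inconsistent_across_comparisons` when its expression overlay changes
#' direction or drops below the fold-change threshold (0.5 in |log2|)
#' between comparisons. Rows are sorted by the optional `pathway_order`
#' reaction annotation when present, else by id.
#'
#' @param annotated One `annotated_subnetwork`, or a list of them (same
#'   subsystem, different comparisons).
#' @param lfc_threshold |log2 FC| below which an expression overlay counts
#'   as weak.
#' @return Tibble, one row per reaction x comparison, plus the
#'   cross-comparison consistency flag.
#' @export
report_pathway_response <- function(annotated, lfc_threshold = 0.5) {
  views <- if (inherits(annotated, "annotated_subnetwork")) list(annotated) else annotated
  stopifnot(length(views) >= 1L)
  base <- views[[1]]
  rows <- bind_rows(lapply(views, function(v) {
    dam_status <- v$metabolite_overlay
    rxn_rows <- lapply(seq_len(nrow(v$reactions)), function(i) {
      rid <- v$reactions$id[i]
      st <- v$reactions$stoichiometry[[i]]
      subs <- names(st)[st < 0]
      prods <- names(st)[st > 0]
      ds <- filter(dam_status, .data$metabolite %in% subs, !is.na(.data$dam_log2fc))
      dp <- filter(dam_status, .data$metabolite %in% prods, !is.na(.data$dam_log2fc))
      expr <- v$reaction_overlay$expression_log2fc[v$reaction_overlay$reaction == rid]
      tibble(
        reaction = rid,
        ec = v$reactions$ec[i],
        genes = paste(gpr_genes(v$reactions$gpr[i]), collapse = ";"),
        comparison = v$comparison,
        expression_log2fc = expr,
        expression_direction = dplyr::case_when(
          is.na(expr) ~ NA_character_,
          abs(expr) < lfc_threshold ~ "weak",
          expr > 0 ~ "up",
          TRUE ~ "down"
        ),
        substrate_dams = paste(ds$dam_record[ds$dam_significant %in% TRUE], collapse = ";"),
        product_dams = paste(dp$dam_record[dp$dam_significant %in% TRUE], collapse = ";"),
        concordant = {
          sig_dirs <- sign(dp$dam_log2fc[dp$dam_significant %in% TRUE])
          !is.na(expr) && length(sig_dirs) > 0 && any(sig_dirs == sign(expr))
        }
      )
    })
    bind_rows(rxn_rows)
  }))
  consistency <- rows %>%
    group_by(.data$reaction) %>%
    summarise(
      inconsistent_across_comparisons = dplyr::n_distinct(
        .data$expression_direction[!is.na(.data$expression_direction)]
      ) > 1L,
      .groups = "drop"
    )
  rows <- left_join(rows, consistency, by = "reaction")
  ord <- if ("pathway_order" %in% names(base$reactions)) {
    base$reactions$id[order(base$reactions$pathway_order)]
  } else {
    sort(unique(rows$reaction))
  }
  rows %>% arrange(match(.data$reaction, ord), .data$comparison)
}

#' Export a subnetwork as node/edge tables
#'
#' @param subnet A `subnetwork_view`.
#' @return List of two tibbles, `nodes` (id, type) and `edges`
#'   (from, to, coefficient), suitable for external graph tools.
#' @export
subnetwork_graph <- function(subnet) {
  nodes <- bind_rows(
    tibble(id = subnet$metabolites$id, type = "metabolite"),
    tibble(id = subnet$reactions$id, type = "reaction")
  )
  edges <- subnet$edges %>%
    mutate(
      from = if_else(.data$role == "substrate", .data$metabolite, .data$reaction),
      to = if_else(.data$role == "substrate", .data$reaction, .data$metabolite)
    ) %>%
    select("from", "to", "coefficient")
  list(nodes = nodes, edges = edges)
}
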