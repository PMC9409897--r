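# Seeded generators for every input type the pipeline consumes: toy
# metabolic networks with documented analytic optima, gapped models with
# known minimal repairs, LC-MS-like feature tables with planted fold-change
# effects, and matched DEG tables. All generators are bit-reproducible under
# a fixed seed and self-validate at construction.

#' Generate a toy metabolic model with a documented optimum
#'
#' Templates:
#' * `chain`: single uptake-limited linear path; max biomass = uptake (10).
#' * `branch`: two substrates coupled 2:1 into biomass; max biomass = 5.
#' * `competing-secretion`: a product drain competing with biomass for one
#'   substrate; max product secretion = uptake - growth floor.
#' * `sphingo-mini`: a minimal de novo sphingolipid pathway — serine +
#'   palmitoyl-CoA condense to 3-ketodihydrosphingosine, reduced to
#'   sphinganine, hydroxylated to phytosphingosine or N-acylated to ceramide
#'   and deacylated to sphingosine — rooted in glucose uptake, with GPRs
#'   suitable for expression overlay.
#'
#' The analytic optimum and template name are attached as attributes
#' `analytic_optimum` and `template`.
#'
#' @param template Template name.
#' @param seed Unused for these deterministic templates; kept for interface
#'   symmetry with the other generators.
#' @return A `metabolic_model`.
#' @export
make_toy_model <- function(template = c("chain", "branch", "competing-secretion", "sphingo-mini"),
                           seed = NULL) {
  template <- match.arg(template)
  model <- switch(template,
    chain = {
      mets <- bind_rows(
        metabolite("A_e", formula = "C6H12O6"),
        metabolite("A_c", formula = "C6H12O6")
      )
      rxns <- bind_rows(
        reaction("EX_A", c(A_e = -1), -10, BIG_M, category = "exchange"),
        reaction("T_A", c(A_e = -1, A_c = 1), 0, BIG_M),
        reaction("BIOMASS", c(A_c = -1), 0, BIG_M, category = "biomass")
      )
      m <- metabolic_model("toy-chain", mets, rxns)
      attr(m, "analytic_optimum") <- 10
      m
    },
    branch = {
      mets <- bind_rows(
        metabolite("A_e", formula = "C6H12O6"), metabolite("A_c", formula = "C6H12O6"),
        metabolite("B_e", formula = "C5H10O5"), metabolite("B_c", formula = "C5H10O5")
      )
      rxns <- bind_rows(
        reaction("EX_A", c(A_e = -1), -10, BIG_M, category = "exchange"),
        reaction("EX_B", c(B_e = -1), -10, BIG_M, category = "exchange"),
        reaction("T_A", c(A_e = -1, A_c = 1), 0, BIG_M),
        reaction("T_B", c(B_e = -1, B_c = 1), 0, BIG_M),
        reaction("BIOMASS", c(A_c = -2, B_c = -1), 0, BIG_M, category = "biomass")
      )
      m <- metabolic_model("toy-branch", mets, rxns)
      # biomass limited by A: min(10/2, 10/1)
      attr(m, "analytic_optimum") <- 5
      m
    },
    `competing-secretion` = {
      mets <- bind_rows(
        metabolite("A_e", formula = "C6H12O6"), metabolite("A_c", formula = "C6H12O6"),
        metabolite("P_c", formula = "C3H6O3"), metabolite("P_e", formula = "C3H6O3")
      )
      rxns <- bind_rows(
        reaction("EX_A", c(A_e = -1), -10, BIG_M, category = "exchange"),
        reaction("T_A", c(A_e = -1, A_c = 1), 0, BIG_M),
        reaction("BIOMASS", c(A_c = -1), 0, BIG_M, category = "biomass"),
        reaction("PSYN", c(A_c = -1, P_c = 1), 0, BIG_M, gpr = "g_psyn"),
        reaction("T_P", c(P_c = -1, P_e = 1), 0, BIG_M),
        reaction("EX_P", c(P_e = -1), 0, BIG_M, category = "exchange")
      )
      m <- metabolic_model("toy-competing", mets, rxns)
      # max P secretion at biomass floor g is (10 - g); 9 at the default floor 1
      attr(m, "analytic_optimum") <- 9
      m
    },
    `sphingo-mini` = make_sphingo_mini()
  )
  attr(model, "template") <- template
  model
}

make_sphingo_mini <- function() {
  sphingo <- "Sphingolipid biosynthesis"
  mets <- bind_rows(
    metabolite("glc_e", name = "D-glucose", formula = "C6H12O6",
      annotations = c(kegg = "C00031")
    ),
    metabolite("glc_c", name = "D-glucose", formula = "C6H12O6",
      annotations = c(kegg = "C00031")
    ),
    metabolite("nh4_e", name = "ammonium", formula = "H4N"),
    metabolite("nh4_c", name = "ammonium", formula = "H4N"),
    metabolite("pi_e", name = "phosphate", formula = "HO4P"),
    metabolite("so4_e", name = "sulphate", formula = "O4S"),
    metabolite("h2o_e", name = "water", formula = "H2O"),
    metabolite("h_e", name = "proton", formula = "H"),
    metabolite("co2_c", name = "carbon dioxide", formula = "CO2"),
    metabolite("co2_e", name = "carbon dioxide", formula = "CO2"),
    metabolite("ser_c", name = "L-serine", formula = "C3H7NO3",
      annotations = c(kegg = "C00065")
    ),
    metabolite("palmcoa_c", name = "palmitoyl-CoA", formula = "C37H66N7O17P3S",
      annotations = c(kegg = "C00154")
    ),
    metabolite("kdhs_c", name = "3-ketodihydrosphingosine", formula = "C18H37NO2",
      compound_class = "sphingolipids", annotations = c(kegg = "C02934")
    ),
    metabolite("sphinganine_c", name = "sphinganine", formula = "C18H39NO2",
      compound_class = "sphingolipids", annotations = c(kegg = "C00836")
    ),
    metabolite("phytosphingosine_c", name = "phytosphingosine", formula = "C18H39NO3",
      compound_class = "sphingolipids", annotations = c(kegg = "C12144")
    ),
    metabolite("ceramide_c", name = "ceramide", formula = "C34H69NO3",
      compound_class = "sphingolipids", annotations = c(kegg = "C00195")
    ),
    metabolite("sphingosine_c", name = "sphingosine", formula = "C18H39NO2",
      compound_class = "sphingolipids", annotations = c(kegg = "C00319")
    )
  )
  rxns <- bind_rows(
    reaction("EX_glc", c(glc_e = -1), -10, BIG_M, category = "exchange"),
    reaction("EX_nh4", c(nh4_e = -1), -BIG_M, BIG_M, category = "exchange"),
    reaction("EX_pi", c(pi_e = -1), -BIG_M, BIG_M, category = "exchange"),
    reaction("EX_so4", c(so4_e = -1), -BIG_M, BIG_M, category = "exchange"),
    reaction("EX_h2o", c(h2o_e = -1), -BIG_M, BIG_M, category = "exchange"),
    reaction("EX_h", c(h_e = -1), -BIG_M, BIG_M, category = "exchange"),
    reaction("EX_co2", c(co2_e = -1), 0, BIG_M, category = "exchange"),
    reaction("T_glc", c(glc_e = -1, glc_c = 1), 0, BIG_M, name = "glucose transport"),
    reaction("T_nh4", c(nh4_e = -1, nh4_c = 1), 0, BIG_M, name = "ammonium transport"),
    reaction("T_co2", c(co2_c = -1, co2_e = 1), 0, BIG_M, name = "CO2 transport"),
    reaction("BIOMASS", c(glc_c = -1), 0, BIG_M,
      category = "biomass", name = "biomass synthesis"
    ),
    reaction("SERSYN", c(glc_c = -1, nh4_c = -1, ser_c = 1, co2_c = 3), 0, BIG_M,
      gpr = "g_ser1", subsystem = "Amino acid metabolism",
      name = "serine synthesis (lumped)"
    ),
    reaction("PALMSYN", c(glc_c = -1, palmcoa_c = 1), 0, BIG_M,
      gpr = "g_fas1 and g_fas2", subsystem = "Fatty acid biosynthesis",
      name = "palmitoyl-CoA synthesis (lumped)"
    ),
    reaction("SPT", c(ser_c = -1, palmcoa_c = -1, kdhs_c = 1, co2_c = 1), 0, BIG_M,
      gpr = "g_lcb1 and g_lcb2", subsystem = sphingo, ec = "2.3.1.50",
      name = "serine palmitoyltransferase"
    ),
    reaction("KDSR", c(kdhs_c = -1, sphinganine_c = 1), 0, BIG_M,
      gpr = "Unigene1223", subsystem = sphingo, ec = "1.1.1.102",
      name = "3-dehydrosphinganine reductase"
    ),
    reaction("SUR2", c(sphinganine_c = -1, phytosphingosine_c = 1), 0, BIG_M,
      gpr = "Unigene564", subsystem = sphingo, ec = "1.14.18.5",
      name = "sphinganine C4-monooxygenase"
    ),
    reaction("CERS", c(sphinganine_c = -1, palmcoa_c = -1, ceramide_c = 1), 0, BIG_M,
      gpr = "g_lag1 or g_lac1", subsystem = sphingo, ec = "2.3.1.24",
      name = "ceramide synthase"
    ),
    reaction("CDASE", c(ceramide_c = -1, sphingosine_c = 1), 0, BIG_M,
      gpr = "Unigene9056 or Unigene9552", subsystem = sphingo, ec = "3.5.1.23",
      name = "ceramidase"
    )
  )
  m <- metabolic_model("sphingo-mini", mets, rxns)
  # under glucose at 25 with growth floor 1: 24 glc spare; sphinganine costs
  # 2 glc (serine + palmitoyl-CoA), ceramide/sphingosine 3 glc
  attr(m, "analytic_optimum") <- c(
    sphinganine_c = 12, phytosphingosine_c = 12,
    ceramide_c = 8, sphingosine_c = 8
  )
  m
}

#' Generate a random flux-balance instance
#'
#' Small random stoichiometric networks (<= 15 reactions) used to
#' property-test the LP engine against independent solvers. Every instance
#' is feasible (zero flux satisfies all constraints).
#'
#' @param seed Integer seed.
#' @param max_reactions Upper bound on the number of reactions.
#' @return List: `model` (a `metabolic_model`; objective reaction in
#'   `$objective`), `S`, `lb`, `ub`, `obj` (the raw LP view).
#' @export
make_random_network <- function(seed, max_reactions = 15) {
  withr::with_seed(seed, {
    n_m <- sample(3:8, 1)
    n_r <- sample(4:max_reactions, 1)
    S <- matrix(0, n_m, n_r)
    for (j in seq_len(n_r)) {
      nz <- sample(seq_len(min(3, n_m)), 1)
      idx <- sample(n_m, nz)
      S[idx, j] <- sample(c(-2, -1, 1, 2), nz, replace = TRUE)
    }
    lb <- ifelse(runif(n_r) < 0.3, -round(runif(n_r, 1, 10), 1), 0)
    ub <- round(runif(n_r, 1, 10), 1)
    obj_j <- sample(n_r, 1)
    used <- rowSums(S != 0) > 0
    S <- S[used, , drop = FALSE]
    n_m <- nrow(S)
    met_ids <- sprintf("M%02d_c", seq_len(n_m))
    rxn_ids <- sprintf("R%02d", seq_len(n_r))
    rownames(S) <- met_ids
    colnames(S) <- rxn_ids
    mets <- bind_rows(lapply(met_ids, metabolite))
    rxns <- bind_rows(lapply(seq_len(n_r), function(j) {
      st <- S[, j]
      st <- st[st != 0]
      reaction(rxn_ids[j], stoichiometry = st, lower_bound = lb[j], upper_bound = ub[j])
    }))
    model <- metabolic_model(
      sprintf("random-%d", seed), mets, rxns,
      objective = rxn_ids[obj_j], check = TRUE
    )
    obj <- numeric(n_r)
    obj[obj_j] <- 1
    list(model = model, S = S, lb = lb, ub = ub, obj = obj)
  })
}

#' Generate a gapped model with a known minimal repair set
#'
#' Removes `n_gaps` individually essential reactions (seeded choice) from a
#' working model and builds a universal candidate set containing exactly the
#' removed reactions plus `n_decoys` decoy reactions over fresh dead-end
#' metabolites. Construction self-verifies: the gapped model fails the
#' target, decoys alone never restore it, and the removed set does.
#'
#' @param base A working `metabolic_model` (target achievable).
#' @param n_gaps Number of reactions to remove (each essential on its own,
#'   so the minimal repair is exactly the removed set).
#' @param n_decoys Number of decoy reactions in the universe.
#' @param seed Integer seed.
#' @param target Target (reaction or metabolite id); default the biomass
#'   objective.
#' @param epsilon Achievability threshold (mmol/gDW/h).
#' @return A `gapped_model_truth`: `model` (gapped), `universe`,
#'   `repair` (removed reaction ids), `target`, `seed`.
#' @export
make_gapped_model <- function(base, n_gaps = 1, n_decoys = 5, seed = 1,
                              target = base$objective, epsilon = 1e-6) {
  base_val <- target_flux(base, target)
  if (base_val < epsilon) stop("base model does not achieve the target", call. = FALSE)
  candidates <- base$reactions$id[
    base$reactions$category %in% c("enzymatic", "transport") &
      base$reactions$id != target
  ]
  essential <- candidates[vapply(candidates, function(r) {
    m <- base
    m$reactions <- filter(m$reactions, .data$id != r)
    target_flux(m, target) < epsilon
  }, logical(1))]
  if (length(essential) < n_gaps) {
    stop("model has only ", length(essential), " removable essential reaction(s)", call. = FALSE)
  }
  withr::with_seed(seed, {
    gaps <- sort(sample(essential, n_gaps))
    gapped <- base
    removed <- filter(gapped$reactions, .data$id %in% gaps)
    gapped$reactions <- filter(gapped$reactions, !.data$id %in% gaps)
    decoy_mets <- list()
    decoy_rxns <- list()
    for (k in seq_len(n_decoys)) {
      a <- sprintf("decoy%d_a_c", k)
      b <- sprintf("decoy%d_b_c", k)
      decoy_mets[[2 * k - 1]] <- metabolite(a)
      decoy_mets[[2 * k]] <- metabolite(b)
      decoy_rxns[[k]] <- reaction(
        sprintf("DECOY%02d", k),
        stoichiometry = setNames(c(-1, 1), c(a, b)),
        lower_bound = 0, upper_bound = BIG_M
      )
    }
    universe <- list(
      id = "universe",
      metabolites = bind_rows(decoy_mets),
      reactions = bind_rows(c(list(removed), decoy_rxns))
    )
    # generation-time verification of the planted truth
    stopifnot(target_flux(gapped, target) < epsilon)
    decoy_ids <- vapply(decoy_rxns, function(r) r$id, character(1))
    stopifnot(target_flux(add_universe_reactions(gapped, universe, decoy_ids), target) < epsilon)
    stopifnot(target_flux(add_universe_reactions(gapped, universe, gaps), target) >= epsilon)
    structure(
      list(
        model = gapped, universe = universe, repair = gaps,
        target = target, seed = seed
      ),
      class = "gapped_model_truth"
    )
  })
}

#' Generate a feature-intensity table with planted differential effects
#'
#' Log-normal intensities: `log2(intensity) ~ Normal(mu_feature +
#' condition_effect, sigma)` with per-feature baselines around a 1e5 median
#' intensity (typical LC-MS peak-area magnitudes). For each non-reference
#' condition, `n_dams_per_pair` distinct features receive a +/-
#' `effect_log2fc` shift in that condition; all other feature-condition
#' effects are zero. Compound classes are drawn from the standard annotation
#' vocabulary (including "sphingolipids" and "unknown").
#'
#' @param n_features Number of features.
#' @param conditions Condition labels; `reference` must be among them.
#' @param replicates Biological replicates per condition (default 3).
#' @param n_dams_per_pair Planted DAMs per non-reference condition.
#' @param effect_log2fc Planted |log2 fold change|.
#' @param sigma Replicate noise sd on the log2 scale.
#' @param seed Integer seed (bit-reproducible output).
#' @param reference Reference condition (denominator of fold changes).
#' @return A `feature_table_truth`: `table` (a `feature_table`),
#'   `effects` (features x conditions matrix of planted log2 shifts),
#'   `truth` tibble (feature, comparison, true_log2fc, true_dam) for every
#'   ordered pair of conditions vs the reference and the non-reference pair,
#'   plus `sigma`, `effect_log2fc`, `seed`.
#' @export
make_feature_table <- function(n_features = 400, conditions = c("C5", "C6", "C12"),
                               replicates = 3, n_dams_per_pair = 40,
                               effect_log2fc = 2, sigma = 0.3, seed = 1,
                               reference = "C6") {
  stopifnot(reference %in% conditions, sigma > 0, n_dams_per_pair <= n_features)
  withr::with_seed(seed, {
    feats <- sprintf("F%04d", seq_len(n_features))
    mu <- rnorm(n_features, mean = log2(1e5), sd = 1.5)
    effects <- matrix(0, n_features, length(conditions),
      dimnames = list(feats, conditions)
    )
    others <- setdiff(conditions, reference)
    pool <- sample(feats)
    used <- 0L
    planted <- list()
    for (cond in others) {
      if (used + n_dams_per_pair > n_features) {
        stop("not enough features to plant disjoint effects", call. = FALSE)
      }
      take <- pool[(used + 1L):(used + n_dams_per_pair)]
      used <- used + n_dams_per_pair
      signs <- sample(c(-1, 1), length(take), replace = TRUE)
      effects[take, cond] <- signs * effect_log2fc
      planted[[cond]] <- take
    }
    samples <- paste0(
      rep(conditions, each = replicates), "_r",
      rep(seq_len(replicates), times = length(conditions))
    )
    design <- tibble(
      sample = samples,
      condition = rep(conditions, each = replicates),
      replicate = rep(seq_len(replicates), times = length(conditions))
    )
    x <- matrix(0, n_features, length(samples), dimnames = list(feats, samples))
    for (s in seq_along(samples)) {
      cond <- design$condition[s]
      x[, s] <- 2^(mu + effects[, cond] + rnorm(n_features, 0, sigma))
    }
    classes <- sample(COMPOUND_CLASSES, n_features,
      replace = TRUE,
      prob = c(rep(1, length(COMPOUND_CLASSES) - 1), 12)
    )
    features <- tibble(
      feature = feats,
      mz = round(runif(n_features, 50, 1000), 4),
      rt = round(runif(n_features, 0, 33), 2),
      name = feats, class = classes
    )
    ft <- feature_table(x, design, features)
    pairs <- c(
      lapply(others, function(a) c(a, reference)),
      if (length(others) == 2) list(others) else NULL
    )
    truth <- bind_rows(lapply(pairs, function(pr) {
      lfc <- effects[, pr[1]] - effects[, pr[2]]
      tibble(
        feature = feats,
        comparison = paste0(pr[1], " vs ", pr[2]),
        true_log2fc = as.numeric(lfc),
        true_dam = abs(lfc) > 0
      )
    }))
    structure(
      list(
        table = ft, effects = effects, truth = truth,
        sigma = sigma, effect_log2fc = effect_log2fc, seed = seed
      ),
      class = "feature_table_truth"
    )
  })
}

#' Generate a differential-expression table matched to a model subsystem
#'
#' Assigns planted log2 fold changes to the genes of a subsystem's reactions
#' (`upregulated_fraction` of them get `+effect_log2fc`, the rest stay at
#' background) and Normal(0, 0.1) background values to all other model
#' genes.
#'
#' @param model A `metabolic_model`.
#' @param subsystem Subsystem whose genes receive the effect.
#' @param upregulated_fraction Fraction of subsystem genes upregulated.
#' @param effect_log2fc Planted log2 fold change.
#' @param seed Integer seed.
#' @param comparison Comparison label for the records.
#' @return Tibble: gene, log2_fold_change, comparison, direction, planted.
#' @export
make_deg_table <- function(model, subsystem, upregulated_fraction = 1,
                           effect_log2fc = 2, seed = 1,
                           comparison = "C5 vs C6") {
  in_sub <- model$reactions$subsystem %in% subsystem
  sub_genes <- sort(unique(unlist(lapply(model$reactions$gpr[in_sub], gpr_genes))))
  if (!length(sub_genes)) stop("subsystem '", subsystem, "' has no associated genes", call. = FALSE)
  all_genes <- model$genes$id
  withr::with_seed(seed, {
    n_up <- round(upregulated_fraction * length(sub_genes))
    up <- if (n_up > 0) sort(sample(sub_genes, n_up)) else character()
    lfc <- setNames(rnorm(length(all_genes), 0, 0.1), all_genes)
    lfc[up] <- effect_log2fc
    tibble(
      gene = all_genes,
      log2_fold_change = as.numeric(lfc),
      comparison = comparison,
      direction = if_else(lfc < 0, "down", "up"),
      planted = all_genes %in% up
    )
  })
}
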