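# Footprint incorporation, gap-filling, GPR merges, model diffs.

test_that("footprint records matching existing metabolites add nothing", {
  m <- make_toy_model("sphingo-mini")
  rec <- tibble::tibble(name = "glucose (matched)", kegg = "C00031", formula = "C6H12O6")
  out <- incorporate_footprint_metabolites(m, rec)
  expect_identical(nrow(out$model$metabolites), nrow(m$metabolites))
  expect_identical(nrow(out$model$reactions), nrow(m$reactions))
  expect_true(out$matches$matched)
  expect_identical(out$matches$matched_by, "kegg")
})

test_that("novel and intracellular-matched records add the right elements", {
  m <- make_toy_model("sphingo-mini")
  rec <- tibble::tibble(
    name = c("ceramide", "myriocin"),
    formula = c("C34H69NO3", "C21H39NO6"),
    class = c("sphingolipids", "sphingolipids")
  )
  out <- incorporate_footprint_metabolites(m, rec)
  d <- diff_models(m, out$model)
  # ceramide matches the cytosolic species by name: the extracellular
  # observation gains a boundary species, exchange and transport; myriocin is
  # novel: metabolite + exchange only
  expect_setequal(d$new_metabolites, c("ceramide_e", "myriocin_e"))
  expect_setequal(
    d$new_reactions,
    c("EX_ceramide_e", "T_ceramide", "EX_myriocin_e")
  )
  expect_true(all(out$matches$matched == c(TRUE, FALSE)))
  # provenance recorded on every addition
  added <- out$model$reactions[out$model$reactions$id %in% d$new_reactions, ]
  expect_true(all(added$provenance == "footprint"))
})

test_that("records without any identifying field are rejected with a reason", {
  m <- make_toy_model("sphingo-mini")
  out <- incorporate_footprint_metabolites(m, tibble::tibble(name = "mystery"))
  expect_identical(nrow(out$rejected), 1L)
  expect_match(out$rejected$reason, "identifying")
  expect_identical(nrow(out$model$metabolites), nrow(m$metabolites))
})

test_that("gap-fill returns the empty set when the target is already achievable", {
  m <- make_toy_model("sphingo-mini")
  gt <- make_gapped_model(m, n_gaps = 1, seed = 3)
  res <- gap_fill(m, gt$universe, "BIOMASS")
  expect_identical(res$status, "already-achievable")
  expect_identical(res$added, character())
})

test_that("gap-fill recovers a single deleted essential among decoys", {
  m <- make_toy_model("sphingo-mini")
  gt <- make_gapped_model(m, n_gaps = 1, n_decoys = 5, seed = 11)
  res <- gap_fill(gt$model, gt$universe, gt$target)
  expect_identical(res$status, "filled")
  expect_identical(sort(res$added), gt$repair)
  # brute force over singletons agrees
  singles <- gt$universe$reactions$id
  hits <- singles[vapply(singles, function(r) {
    fluxprint:::target_flux(
      fluxprint:::add_universe_reactions(gt$model, gt$universe, r), gt$target
    ) >= 1e-6
  }, logical(1))]
  expect_identical(sort(hits), gt$repair)
})

test_that("gap-fill is irreducible and exact mode matches the exhaustive oracle", {
  m <- make_toy_model("sphingo-mini")
  for (seed in c(2, 5, 9)) {
    gt <- make_gapped_model(m, n_gaps = 2, n_decoys = 6, seed = seed, target = "sphingosine_c")
    res <- gap_fill(gt$model, gt$universe, gt$target)
    expect_identical(res$status, "filled")
    # irreducibility: dropping any one added reaction breaks the target
    for (r in res$added) {
      rest <- setdiff(res$added, r)
      flux <- fluxprint:::target_flux(
        fluxprint:::add_universe_reactions(gt$model, gt$universe, rest), gt$target
      )
      expect_lt(flux, 1e-6)
    }
    # exhaustive oracle: smallest achieving subset over the whole universe
    uids <- gt$universe$reactions$id
    best <- NULL
    for (k in seq_along(uids)) {
      for (set in utils::combn(uids, k, simplify = FALSE)) {
        flux <- fluxprint:::target_flux(
          fluxprint:::add_universe_reactions(gt$model, gt$universe, set), gt$target
        )
        if (flux >= 1e-6) {
          best <- set
          break
        }
      }
      if (!is.null(best)) break
    }
    exact <- gap_fill(gt$model, gt$universe, gt$target, exact = TRUE)
    expect_identical(length(exact$added), length(best))
    expect_gte(length(res$added), length(exact$added))
    expect_identical(sort(exact$added), gt$repair) # independent essentials
  }
})

test_that("an unfillable target is reported with dead-end diagnostics", {
  m <- make_toy_model("sphingo-mini")
  m$metabolites <- dplyr::bind_rows(m$metabolites, metabolite("unreachable_c"))
  m$reactions <- dplyr::bind_rows(
    m$reactions,
    reaction("USE_U", c(unreachable_c = -1, co2_c = 1), 0, 1000)
  )
  universe <- list(
    metabolites = dplyr::bind_rows(metabolite("dx_c"), metabolite("dy_c")),
    reactions = reaction("DEC1", c(dx_c = -1, dy_c = 1), 0, 1000)
  )
  res <- gap_fill(m, universe, "unreachable_c")
  expect_identical(res$status, "unfillable")
  expect_true("unreachable_c" %in% res$dead_ends)
})

test_that("GPR merges add newly referenced genes and log changes", {
  m <- make_toy_model("sphingo-mini")
  out0 <- merge_gpr_updates(m, tibble::tibble(reaction = character(), gpr = character()))
  expect_identical(out0$model$genes, m$genes)

  upd <- tibble::tibble(
    reaction = c("SPT", "KDSR", "NOPE", "CDASE"),
    gpr = c(
      "(g_lcb1 and g_lcb2) or g_new1", "Unigene1223 or g_new2",
      "g_x", "Unigene9056 or (("
    )
  )
  out <- merge_gpr_updates(m, upd)
  d <- diff_models(m, out$model)
  expect_setequal(d$new_genes, c("g_new1", "g_new2"))
  expect_identical(out$log$status[out$log$reaction == "NOPE"], "unknown reaction; skipped")
  expect_match(out$log$status[out$log$reaction == "CDASE"], "malformed")
  # the malformed row left the reaction untouched
  expect_identical(
    out$model$reactions$gpr[out$model$reactions$id == "CDASE"],
    m$reactions$gpr[m$reactions$id == "CDASE"]
  )
})

test_that("model diff is empty on identity and antisymmetric", {
  a <- make_toy_model("sphingo-mini")
  d0 <- diff_models(a, a)
  expect_identical(sum(d0$summary$n_new) + sum(d0$summary$n_removed), 0L)

  gt <- make_gapped_model(a, n_gaps = 1, seed = 4)
  b <- gt$model
  dab <- diff_models(a, b)
  dba <- diff_models(b, a)
  expect_identical(dab$new_reactions, dba$removed_reactions)
  expect_identical(dab$removed_reactions, dba$new_reactions)
  expect_identical(dab$removed_reactions, gt$repair)
})

test_that("enhancement never reduces maximal biomass flux", {
  m <- make_toy_model("sphingo-mini")
  before <- solve_fba(m)$objective_value
  rec <- tibble::tibble(name = "adenosine", formula = "C10H13N5O4", kegg = "C00212")
  out <- incorporate_footprint_metabolites(m, rec)
  after <- solve_fba(out$model)$objective_value
  expect_gte(after, before - 1e-9)

  gt <- make_gapped_model(m, n_gaps = 1, seed = 6)
  res <- gap_fill(gt$model, gt$universe, gt$target)
  expect_gte(
    solve_fba(res$model)$objective_value,
    solve_fba(gt$model)$objective_value - 1e-9
  )
})
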