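# Flux balance analysis engine.

test_that("a linear chain is uptake-limited", {
  sol <- solve_fba(chain_model(10))
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-9)
})

test_that("nothing in means nothing out", {
  m <- chain_model(0)
  sol <- solve_fba(m)
  expect_equal(sol$objective_value, 0, tolerance = 1e-12)
})

test_that("branched 2:1 coupling matches the hand optimum and the LP oracle", {
  m <- branch_model(10, 10)
  sol <- solve_fba(m)
  expect_equal(sol$objective_value, 5, tolerance = 1e-9) # limited by 2 A per biomass
  S <- fluxprint:::stoich_matrix(m)
  b <- fluxprint:::rxn_bounds(m)
  obj <- as.numeric(m$reactions$id == "BIOMASS")
  orac <- oracle_lp(S, b[, "lb"], b[, "ub"], obj)
  expect_identical(orac$status, "optimal")
  expect_equal(sol$objective_value, orac$objective, tolerance = 1e-9)
})

test_that("objectives match the independent HiGHS oracle on random networks", {
  insts <- lapply(1:12, function(s) make_random_network(seed = 1000 + s))
  mine <- lapply(insts, function(i) solve_fba(i$model, objective = i$model$objective))
  orac <- oracle_lp_batch(insts)
  for (k in seq_along(insts)) {
    status_o <- orac[[k]]$status
    expect_identical(mine[[k]]$status, status_o, info = paste("instance", k))
    if (status_o == "optimal") {
      rel <- abs(mine[[k]]$objective_value - orac[[k]]$objective) /
        max(1, abs(orac[[k]]$objective))
      expect_lt(rel, 1e-6)
      expect_lte(mine[[k]]$residual, 1e-9)
    }
  }
})

test_that("objectives also match boot::simplex where that solver converges", {
  checked <- 0L
  for (s in 1:12) {
    i <- make_random_network(seed = 2000 + s)
    orac <- oracle_lp_boot(i$S, i$lb, i$ub, i$obj)
    if (is.null(orac)) next
    mine <- solve_fba(i$model, objective = i$model$objective)
    expect_identical(mine$status, orac$status)
    if (orac$status == "optimal") {
      expect_equal(mine$objective_value, orac$objective, tolerance = 1e-6)
    }
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})

test_that("optimal solutions satisfy mass balance and bounds within tolerance", {
  for (s in c(7, 8, 9)) {
    i <- make_random_network(seed = 3000 + s)
    sol <- solve_fba(i$model, objective = i$model$objective)
    if (sol$status != "optimal") next
    S <- fluxprint:::stoich_matrix(i$model)
    v <- sol$fluxes$flux
    expect_lte(max(abs(S %*% v)), 1e-9)
    b <- fluxprint:::rxn_bounds(i$model)
    expect_true(all(v >= b[, "lb"] - 1e-9 & v <= b[, "ub"] + 1e-9))
  }
})

test_that("maximal growth is non-decreasing in uptake rate", {
  rates <- vapply(c(0, 1, 2.5, 5, 10, 20), function(u) {
    solve_fba(chain_model(u))$objective_value
  }, numeric(1))
  expect_true(all(diff(rates) >= -1e-9))
  m <- make_toy_model("sphingo-mini")
  rates2 <- vapply(c(0, 5, 10, 25), function(u) {
    simulate_growth(m, medium_spec("glc_e", u))$growth_rate
  }, numeric(1))
  expect_true(all(diff(rates2) >= -1e-9))
})

test_that("doubling all bounds doubles the optimum (LP homogeneity)", {
  for (s in 1:5) {
    i <- make_random_network(seed = 4000 + s)
    m <- i$model
    sol1 <- solve_fba(m, objective = m$objective)
    m2 <- m
    b <- fluxprint:::rxn_bounds(m)
    m2$reactions$lower_bound <- fluxprint:::format_bound(2 * b[, "lb"])
    m2$reactions$upper_bound <- fluxprint:::format_bound(2 * b[, "ub"])
    sol2 <- solve_fba(m2, objective = m2$objective)
    expect_identical(sol1$status, sol2$status)
    if (sol1$status == "optimal") {
      expect_equal(sol2$objective_value, 2 * sol1$objective_value, tolerance = 1e-8)
    }
  }
})

test_that("apply_medium opens the carbon source and closes competing carbon uptakes", {
  m <- branch_model(10, 10) # A and B both carbon-bearing
  glc <- apply_medium(m, medium_spec("A_e", 25))
  b <- fluxprint:::rxn_bounds(glc)
  expect_equal(b[match("EX_A", glc$reactions$id), "lb"], c(lb = -25))
  expect_equal(b[match("EX_B", glc$reactions$id), "lb"], c(lb = 0))
  # switching carbon source zeroes A uptake and opens B
  xyl <- apply_medium(m, medium_spec("B_e", 7))
  b2 <- fluxprint:::rxn_bounds(xyl)
  expect_equal(b2[match("EX_A", xyl$reactions$id), "lb"], c(lb = 0))
  expect_equal(b2[match("EX_B", xyl$reactions$id), "lb"], c(lb = -7))
  # secretion (upper) bounds untouched
  expect_identical(xyl$reactions$upper_bound, m$reactions$upper_bound)
})

test_that("free exchanges are opened to the big-M bound", {
  m <- make_toy_model("sphingo-mini")
  con <- apply_medium(m, medium_spec("glc_e", 25))
  b <- fluxprint:::rxn_bounds(con)
  for (rid in c("EX_nh4", "EX_pi", "EX_so4", "EX_h2o", "EX_h")) {
    expect_equal(b[match(rid, con$reactions$id), "lb"], c(lb = -1000), info = rid)
  }
})

test_that("growth reporting converts units", {
  m <- chain_model(10)
  g_h <- simulate_growth(m, medium_spec("A_e", 10))
  g_d <- simulate_growth(m, medium_spec("A_e", 10), unit = "per_day")
  expect_equal(g_d$growth_rate, 24 * g_h$growth_rate)
})

test_that("zero uptake gives zero growth when biomass needs carbon", {
  m <- make_toy_model("sphingo-mini")
  g <- simulate_growth(m, medium_spec("glc_e", 0))
  expect_equal(g$growth_rate, 0, tolerance = 1e-9)
})

test_that("capability screen applies the production threshold rule", {
  # a reaction capped so maximal secretion is 5e-11: below the 1e-10 rule
  mets <- dplyr::bind_rows(
    metabolite("glc_e", formula = "C6H12O6"), metabolite("glc_c", formula = "C6H12O6"),
    metabolite("tr_c", formula = "C10H10O2")
  )
  rxns <- dplyr::bind_rows(
    reaction("EX_glc", c(glc_e = -1), -25, 1000, category = "exchange"),
    reaction("T_glc", c(glc_e = -1, glc_c = 1), 0, 1000),
    reaction("BIOMASS", c(glc_c = -1), 0, 1000, category = "biomass"),
    reaction("TRACE", c(glc_c = -1, tr_c = 1), 0, 5e-11)
  )
  m <- metabolic_model("trace", mets, rxns)
  rep <- screen_biosynthetic_capability(m, "tr_c", medium_spec("glc_e", 25), growth_floor = 1)
  expect_identical(rep$status, "optimal")
  expect_lte(rep$rate, 5e-11 + 1e-15)
  expect_false(rep$producible)
})

test_that("orphan targets are never producible", {
  m <- make_toy_model("sphingo-mini")
  m$metabolites <- dplyr::bind_rows(m$metabolites, metabolite("orphanlipid_c"))
  rep <- screen_biosynthetic_capability(m, "orphanlipid_c")
  expect_false(rep$producible)
})

test_that("all four sphingoid targets are producible under glucose with a growth floor", {
  m <- make_toy_model("sphingo-mini")
  targets <- c("sphinganine_c", "sphingosine_c", "phytosphingosine_c", "ceramide_c")
  rep <- screen_biosynthetic_capability(m, targets, medium_spec("glc_e", 25), growth_floor = 1)
  expect_true(all(rep$producible))
  expect_equal(
    setNames(rep$rate, rep$target)[names(attr(m, "analytic_optimum"))],
    attr(m, "analytic_optimum"),
    tolerance = 1e-8
  )
})

test_that("capability screen production competes with biomass as the oracle predicts", {
  m <- make_toy_model("competing-secretion")
  rep <- screen_biosynthetic_capability(m, "P_e", medium_spec("A_e", 10), growth_floor = 1)
  # oracle: raw LP with biomass floor baked into the bounds
  con <- apply_medium(m, medium_spec("A_e", 10))
  bio <- match("BIOMASS", con$reactions$id)
  lb <- as.numeric(con$reactions$lower_bound)
  lb[bio] <- 1
  S <- fluxprint:::stoich_matrix(con)
  b <- fluxprint:::rxn_bounds(con)
  obj <- as.numeric(con$reactions$id == "EX_P")
  orac <- oracle_lp(S, lb, b[, "ub"], obj)
  expect_equal(rep$rate, orac$objective, tolerance = 1e-8)
})

test_that("an infeasible growth floor is diagnosed for all targets", {
  m <- make_toy_model("sphingo-mini")
  rep <- screen_biosynthetic_capability(m, "sphinganine_c",
    medium_spec("glc_e", 0.5),
    growth_floor = 1
  )
  expect_identical(rep$status, "infeasible")
  expect_false(rep$producible)
  expect_match(attr(rep, "diagnostic"), "infeasible")
})
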