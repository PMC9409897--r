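# Flux balance analysis: growth simulation on defined media and
# biosynthetic-capability screening.
#
# Sign convention (standard in constraint-based modelling): an exchange
# reaction is written `1 met_e ->` so negative flux is uptake and positive
# flux secretion.

FBA_FEAS_TOL <- 1e-9
PRODUCTION_THRESHOLD <- 1e-10 # below this a screened rate counts as no production

#' Define a growth medium
#'
#' A single limiting carbon source plus freely exchanged inorganic nutrients.
#' By default ammonium, phosphate, sulphate, water and protons are
#' unconstrained; every other carbon-bearing uptake is closed by
#' [apply_medium()].
#'
#' @param carbon_source Extracellular metabolite id (e.g. `"glc_e"`).
#' @param uptake_rate Maximal uptake, mmol/gDW/h (non-negative).
#' @param free_exchanges Metabolite ids whose exchange is unconstrained.
#' @return A `medium_spec`.
#' @export
medium_spec <- function(carbon_source, uptake_rate = 25,
                        free_exchanges = c("nh4_e", "pi_e", "so4_e", "h2o_e", "h_e")) {
  stopifnot(is.character(carbon_source), length(carbon_source) == 1L, uptake_rate >= 0)
  structure(
    list(
      carbon_source = carbon_source, uptake_rate = uptake_rate,
      free_exchanges = free_exchanges
    ),
    class = "medium_spec"
  )
}

# Number of atoms of `element` in an elemental formula string.
count_element <- function(formula, element = "C") {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    total <- 0
    for (t in toks) {
      el <- gsub("[0-9]", "", t)
      if (el == element) {
        cnt <- gsub("[^0-9]", "", t)
        total <- total + if (nzchar(cnt)) as.numeric(cnt) else 1
      }
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

exchange_info <- function(model) {
  idx <- which(model$reactions$category == "exchange")
  met <- vapply(idx, function(i) names(model$reactions$stoichiometry[[i]])[1], character(1))
  tibble(index = idx, reaction = model$reactions$id[idx], metabolite = met)
}

#' Apply a medium specification to a model
#'
#' Sets the carbon-source exchange lower bound to `-uptake_rate`, closes the
#' uptake (lower bound 0) of every other carbon-bearing exchange, opens the
#' listed free exchanges to `-1000`, and leaves all secretion (upper) bounds
#' untouched. Metabolites without an elemental formula are treated as
#' carbon-free (their uptake stays as modelled). If the carbon source has no
#' exchange reaction one is synthesised (provenance `"added-for-medium"`).
#'
#' @param model A `metabolic_model`.
#' @param medium A [medium_spec()].
#' @return The constrained model.
#' @export
apply_medium <- function(model, medium) {
  stopifnot(inherits(medium, "medium_spec"))
  ex <- exchange_info(model)
  if (!medium$carbon_source %in% ex$metabolite) {
    if (!medium$carbon_source %in% model$metabolites$id) {
      stop(
        "carbon source '", medium$carbon_source,
        "' is not a model metabolite and no exchange reaction can be synthesised",
        call. = FALSE
      )
    }
    model <- add_exchange(model, medium$carbon_source, provenance = "added-for-medium")
    ex <- exchange_info(model)
  }
  formulas <- model$metabolites$formula[match(ex$metabolite, model$metabolites$id)]
  ncarbon <- count_element(formulas, "C")
  carbon_bearing <- !is.na(ncarbon) & ncarbon > 0
  lb <- as.numeric(model$reactions$lower_bound)
  lb[ex$index[carbon_bearing]] <- 0
  lb[ex$index[ex$metabolite %in% medium$free_exchanges]] <- -BIG_M
  lb[ex$index[ex$metabolite == medium$carbon_source]] <- -medium$uptake_rate
  model$reactions$lower_bound <- format_bound(lb)
  model
}

add_exchange <- function(model, metabolite_id, lb = 0, ub = BIG_M,
                         provenance = NA_character_) {
  rid <- paste0("EX_", metabolite_id)
  if (rid %in% model$reactions$id) return(model)
  model$reactions <- bind_rows(
    model$reactions,
    reaction(rid,
      stoichiometry = setNames(-1, metabolite_id),
      lower_bound = lb, upper_bound = ub, category = "exchange",
      provenance = provenance
    )
  )
  model
}

#' Solve a flux balance analysis problem
#'
#' Maximises (or minimises) the flux through `objective` subject to
#' steady-state mass balance `S v = 0` and the model's flux bounds. Only the
#' optimal objective value is uniquely determined; the returned flux vector
#' is one of possibly many alternate optima.
#'
#' @param model A `metabolic_model` with finite bounds.
#' @param objective Reaction id; defaults to the model objective.
#' @param maximize Direction.
#' @return A `flux_solution`: `status` (`optimal`/`infeasible`/`unbounded`),
#'   `objective_value` (mmol/gDW/h, or h^-1 for biomass) and `fluxes`
#'   (tibble reaction/flux; `NULL` unless optimal).
#' @export
solve_fba <- function(model, objective = model$objective, maximize = TRUE) {
  j <- match(objective, model$reactions$id)
  if (is.na(j)) stop("objective reaction '", objective, "' not in model", call. = FALSE)
  S <- stoich_matrix(model)
  b <- rxn_bounds(model)
  obj <- numeric(ncol(S))
  obj[j] <- 1
  res <- solve_lp_bounded(S, b[, "lb"], b[, "ub"], obj, maximize = maximize)
  if (res$status != "optimal") {
    return(structure(
      list(status = res$status, objective_value = NA_real_, fluxes = NULL),
      class = "flux_solution"
    ))
  }
  v <- res$v
  resid <- max(abs(S %*% v))
  if (resid > 1e-6) {
    warning("steady-state residual ", format(resid), " exceeds tolerance", call. = FALSE)
  }
  structure(
    list(
      status = "optimal", objective_value = res$objective,
      fluxes = tibble(reaction = model$reactions$id, flux = as.numeric(v)),
      residual = resid
    ),
    class = "flux_solution"
  )
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution>", x$status)
  if (x$status == "optimal") cat(sprintf(", objective = %.6g", x$objective_value))
  cat("\n")
  invisible(x)
}

#' @method tidy flux_solution
#' @export
tidy.flux_solution <- function(x, ...) {
  if (is.null(x$fluxes)) return(tibble(reaction = character(), flux = numeric()))
  x$fluxes
}

#' @method glance flux_solution
#' @export
glance.flux_solution <- function(x, ...) {
  tibble(
    status = x$status, objective_value = x$objective_value,
    residual = x$residual %||% NA_real_
  )
}

#' Simulate growth on a defined medium
#'
#' Applies the medium and maximises the biomass reaction. Biomass flux is
#' identified with specific growth rate (gDW-normalised convention); use
#' `unit = "per_day"` to report day^-1 (x24).
#'
#' @param model A `metabolic_model` with a biomass reaction.
#' @param medium A [medium_spec()].
#' @param unit `"per_hour"` (default) or `"per_day"`.
#' @return One-row tibble: carbon_source, uptake_rate, status, growth_rate, unit.
#' @export
simulate_growth <- function(model, medium, unit = c("per_hour", "per_day")) {
  unit <- match.arg(unit)
  constrained <- apply_medium(model, medium)
  sol <- solve_fba(constrained, objective = model$objective, maximize = TRUE)
  rate <- sol$objective_value
  if (unit == "per_day" && !is.na(rate)) rate <- rate * 24
  tibble(
    carbon_source = medium$carbon_source, uptake_rate = medium$uptake_rate,
    status = sol$status, growth_rate = rate, unit = unit
  )
}

#' Screen biosynthetic capability of target metabolites
#'
#' For each target, guarantees a secretion (demand) reaction exists
#' (synthesising one flagged `"added-for-screen"` when absent), imposes the
#' growth requirement as a lower bound on the biomass reaction, and maximises
#' target secretion under the medium. A target is producible iff the LP is
#' optimal and the maximal rate reaches 1e-10 mmol/gDW/h; rates below that
#' threshold or infeasible problems count as no production.
#'
#' @param model A `metabolic_model`.
#' @param targets Metabolite ids to screen.
#' @param medium A [medium_spec()]; default glucose at 25 mmol/gDW/h.
#' @param growth_floor Required biomass flux, h^-1 (default 1).
#' @return A `capability_report` tibble: target, status, rate, producible.
#' @export
screen_biosynthetic_capability <- function(model, targets,
                                           medium = medium_spec("glc_e", 25),
                                           growth_floor = 1) {
  missing <- setdiff(targets, model$metabolites$id)
  if (length(missing)) {
    stop("targets not in model: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  constrained <- apply_medium(model, medium)
  bio <- match(constrained$objective, constrained$reactions$id)
  lb <- as.numeric(constrained$reactions$lower_bound)
  lb[bio] <- growth_floor
  constrained$reactions$lower_bound <- format_bound(lb)

  base <- solve_fba(constrained, objective = constrained$objective)
  if (base$status != "optimal") {
    out <- tibble(
      target = targets, status = base$status,
      rate = NA_real_, producible = FALSE
    )
    attr(out, "diagnostic") <- paste0(
      "growth floor ", growth_floor,
      " h^-1 is infeasible under the medium before adding any target objective"
    )
    class(out) <- c("capability_report", class(out))
    return(out)
  }

  rows <- lapply(targets, function(tg) {
    m <- constrained
    dm_id <- paste0("DM_", tg)
    if (!dm_id %in% m$reactions$id) {
      m$reactions <- bind_rows(
        m$reactions,
        reaction(dm_id,
          stoichiometry = setNames(-1, tg), lower_bound = 0,
          upper_bound = BIG_M, category = "exchange",
          provenance = "added-for-screen"
        )
      )
    }
    sol <- solve_fba(m, objective = dm_id, maximize = TRUE)
    rate <- if (sol$status == "optimal") sol$objective_value else NA_real_
    tibble(
      target = tg, status = sol$status, rate = rate,
      producible = sol$status == "optimal" && !is.na(rate) && rate >= PRODUCTION_THRESHOLD
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("capability_report", class(out))
  out
}
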