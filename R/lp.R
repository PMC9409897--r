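# Dense two-phase simplex for the small/medium LPs that arise in
# constraint-based analysis of desk-scale networks.
#
# Deterministic by construction: Bland's smallest-index rule for entering and
# leaving variables, so repeated solves of the same instance pivot
# identically and never cycle.

LP_TOL <- 1e-9

# Maximize c'x subject to A_eq x = b_eq, A_ub x <= b_ub, x >= 0.
# b_ub must be >= 0 (callers arrange this); b_eq rows may have any sign.
simplex_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                          tol = LP_TOL) {
  n <- length(obj)
  A_eq <- if (is.null(A_eq)) matrix(0, 0, n) else A_eq
  b_eq <- if (is.null(b_eq)) numeric(0) else b_eq
  A_ub <- if (is.null(A_ub)) matrix(0, 0, n) else A_ub
  b_ub <- if (is.null(b_ub)) numeric(0) else b_ub
  flip <- b_eq < 0
  A_eq[flip, ] <- -A_eq[flip, , drop = FALSE]
  b_eq[flip] <- -b_eq[flip]
  stopifnot(all(b_ub >= -tol))
  b_ub <- pmax(b_ub, 0)

  m_eq <- nrow(A_eq)
  m_ub <- nrow(A_ub)
  m <- m_eq + m_ub
  n_slack <- m_ub
  n_art <- m_eq
  ncol_t <- n + n_slack + n_art

  # rows: eq rows then ub rows; columns: x, slacks, artificials
  A <- matrix(0, m, ncol_t)
  A[seq_len(m_eq), seq_len(n)] <- A_eq
  if (m_ub) A[m_eq + seq_len(m_ub), seq_len(n)] <- A_ub
  if (n_slack) A[m_eq + seq_len(m_ub), n + seq_len(n_slack)] <- diag(1, m_ub)
  if (n_art) A[seq_len(m_eq), n + n_slack + seq_len(n_art)] <- diag(1, m_eq)
  b <- c(b_eq, b_ub)
  basis <- integer(m)
  if (m_eq) basis[seq_len(m_eq)] <- n + n_slack + seq_len(n_art)
  if (m_ub) basis[m_eq + seq_len(m_ub)] <- n + seq_len(n_slack)

  art_cols <- if (n_art) n + n_slack + seq_len(n_art) else integer(0)
  run_phase <- function(cost, allowed, pin_artificials = FALSE) {
    # maximize cost'x over allowed columns, in-place tableau iteration
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > 20000L) {
        stop("simplex iteration limit reached; LP appears to cycle", call. = FALSE)
      }
      cb <- cost[basis]
      # reduced costs: c_j - cb' B^{-1} A_j ; maintain via explicit solve each
      # iteration (dense, small problems; clarity over speed)
      y <- tryCatch(solve(t(A[, basis, drop = FALSE]), cb), error = function(e) NULL)
      if (is.null(y)) return("singular")
      red <- cost - as.numeric(crossprod(A, y))
      red[!allowed] <- -Inf
      cand <- which(red > tol)
      if (!length(cand)) return("optimal")
      j <- cand[1L] # Bland: smallest index
      d <- tryCatch(solve(A[, basis, drop = FALSE], A[, j]), error = function(e) NULL)
      if (is.null(d)) return("singular")
      xb <- solve(A[, basis, drop = FALSE], b)
      pos <- which(d > tol)
      ratios <- if (length(pos)) xb[pos] / d[pos] else numeric(0)
      if (pin_artificials) {
        # basic artificials sit at zero and must stay there: any pivot that
        # would move them forces a degenerate ratio of 0
        pin <- which(basis %in% art_cols & abs(d) > tol)
        pos <- c(pos, pin)
        ratios <- c(ratios, rep(0, length(pin)))
      }
      if (!length(pos)) return("unbounded")
      rmin <- min(ratios)
      ties <- pos[ratios <= rmin + tol * (1 + abs(rmin))]
      leave <- ties[which.min(basis[ties])] # Bland on leaving basis index
      basis[leave] <<- j
    }
  }

  if (m == 0L) {
    # only nonnegativity: optimum is 0 unless some obj coefficient positive
    if (any(obj > tol)) return(list(status = "unbounded", objective = NA_real_, x = NULL))
    return(list(status = "optimal", objective = 0, x = numeric(n)))
  }

  allowed <- rep(TRUE, ncol_t)
  if (n_art) {
    phase1_cost <- c(rep(0, n + n_slack), rep(-1, n_art))
    st <- run_phase(phase1_cost, allowed)
    if (st != "optimal") return(list(status = "infeasible", objective = NA_real_, x = NULL))
    xb <- solve(A[, basis, drop = FALSE], b)
    if (sum(abs(xb[basis > n + n_slack])) > 1e-7) {
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    }
    # leftover artificials (degenerate / redundant rows) stay basic at zero
    # but may never re-enter
    allowed[n + n_slack + seq_len(n_art)] <- FALSE
  }
  phase2_cost <- c(obj, rep(0, n_slack), rep(0, n_art))
  st <- run_phase(phase2_cost, allowed, pin_artificials = n_art > 0)
  if (st == "unbounded") return(list(status = "unbounded", objective = NA_real_, x = NULL))
  if (st == "singular") return(list(status = "infeasible", objective = NA_real_, x = NULL))
  xb <- solve(A[, basis, drop = FALSE], b)
  x <- numeric(ncol_t)
  x[basis] <- xb
  x_out <- pmax(x[seq_len(n)], 0)
  list(status = "optimal", objective = sum(obj * x_out), x = x_out)
}

# Maximize (or minimize) c'v subject to S v = 0 and lb <= v <= ub,
# via the shift x = v - lb >= 0 with explicit upper-bound rows.
solve_lp_bounded <- function(S, lb, ub, obj, maximize = TRUE, tol = LP_TOL) {
  stopifnot(ncol(S) == length(lb), length(lb) == length(ub), length(obj) == length(lb))
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("all bounds must be finite after big-M substitution", call. = FALSE)
  }
  n <- length(obj)
  c_eff <- if (maximize) obj else -obj
  b_eq <- as.numeric(-S %*% lb)
  width <- ub - lb
  # variables at fixed value (lb == ub) contribute nothing to the search space
  A_ub <- diag(1, n)[width > 0, , drop = FALSE]
  b_ub <- width[width > 0]
  fixed <- which(width <= 0)
  if (length(fixed)) {
    # pin fixed variables via paired inequality rows x_i <= 0 (x_i >= 0 given)
    A_fix <- diag(1, n)[fixed, , drop = FALSE]
    A_ub <- rbind(A_ub, A_fix)
    b_ub <- c(b_ub, rep(0, length(fixed)))
  }
  res <- simplex_solve(c_eff, A_eq = S, b_eq = b_eq, A_ub = A_ub, b_ub = b_ub, tol = tol)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, v = NULL))
  }
  v <- res$x + lb
  objective <- sum(obj * v)
  list(status = "optimal", objective = objective, v = v)
}
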