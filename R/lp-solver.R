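# Internal LP layer.
#
# All constraint-based analyses reduce to LPs of the form
#     max/min  c'v   s.t.  A_eq v = b_eq,  A_ub v <= b_ub,  lb <= v <= ub
# with finite box bounds. They are solved by a self-contained two-phase
# dense simplex (below) using Bland's anti-cycling rule, which guarantees
# termination on the heavily degenerate problems FBA produces (knocked-out
# reactions, zero-uptake media, redundant steady-state rows). Problems are
# shifted to x = v - lb >= 0 and upper bounds carried as inequality rows.
#
# Returns list(status, x, objval) with status "optimal", "infeasible" or
# "unbounded" (the latter cannot arise from a validated model, whose bounds
# are finite).

solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_ub = NULL, b_ub = NULL,
                     lb, ub, maximize = TRUE) {
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n,
            all(is.finite(lb)), all(is.finite(ub)), all(lb <= ub))
  shift <- lb
  A <- NULL; b <- NULL; sense <- character(0)
  if (!is.null(A_eq) && nrow(A_eq) > 0) {
    A <- as.matrix(A_eq)
    b <- as.numeric(b_eq) - as.vector(A %*% shift)
    sense <- rep("=", length(b))
  }
  # upper box bounds as x_j <= ub_j - lb_j
  A <- rbind(A, diag(n))
  b <- c(b, ub - lb)
  sense <- c(sense, rep("<=", n))
  if (!is.null(A_ub) && nrow(A_ub) > 0) {
    Au <- as.matrix(A_ub)
    A <- rbind(A, Au)
    b <- c(b, as.numeric(b_ub) - as.vector(Au %*% shift))
    sense <- c(sense, rep("<=", nrow(Au)))
  }
  res <- dense_simplex(if (maximize) -obj else obj, A, b, sense)
  if (res$status != "optimal") {
    return(list(status = res$status, x = rep(NA_real_, n), objval = NA_real_))
  }
  x <- res$x[seq_len(n)] + shift
  # clip roundoff outside the box
  x <- pmin(pmax(x, lb), ub)
  list(status = "optimal", x = x, objval = sum(obj * x))
}

# Two-phase primal simplex, full tableau, Bland's rule.
# Minimises cvec'x subject to A x (sense) b, x >= 0. b may have any sign;
# rows are normalised internally. Returns list(status, x, objval).
dense_simplex <- function(cvec, A, b, sense, tol = 1e-9, max_iter = NULL) {
  m <- length(b); n <- length(cvec)
  A <- as.matrix(A)
  stopifnot(nrow(A) == m, ncol(A) == n)
  # normalise to b >= 0
  flip <- b < 0
  if (any(flip)) {
    A[flip, ] <- -A[flip, , drop = FALSE]
    b[flip] <- -b[flip]
    sense[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[sense[flip]]
  }
  n_slack <- sum(sense != "=")          # slack (<=) or surplus (>=)
  n_art <- sum(sense != "<=")           # artificials for = and >= rows
  ncol_t <- n + n_slack + n_art
  T <- matrix(0, m, ncol_t)
  T[, seq_len(n)] <- A
  basis <- integer(m)
  sl <- n; ar <- n + n_slack
  for (i in seq_len(m)) {
    if (sense[i] == "<=") {
      sl <- sl + 1L; T[i, sl] <- 1; basis[i] <- sl
    } else if (sense[i] == ">=") {
      sl <- sl + 1L; T[i, sl] <- -1
      ar <- ar + 1L; T[i, ar] <- 1; basis[i] <- ar
    } else {
      ar <- ar + 1L; T[i, ar] <- 1; basis[i] <- ar
    }
  }
  rhs <- b
  art_cols <- if (n_art > 0) (n + n_slack + 1L):ncol_t else integer(0)
  if (is.null(max_iter)) max_iter <- 50L * (m + ncol_t) + 1000L

  pivot <- function(r, j) {
    piv <- T[r, j]
    prow <- T[r, ] / piv
    prhs <- rhs[r] / piv
    f <- T[, j]; f[r] <- 0
    T <<- T - outer(f, prow)
    rhs <<- rhs - f * prhs
    T[r, ] <<- prow
    rhs[r] <<- prhs
    basis[r] <<- j
  }

  run_phase <- function(cost, allowed) {
    # Bland's rule on reduced costs rc = cost - cost[basis] %*% T
    for (it in seq_len(max_iter)) {
      cb <- cost[basis]
      rc <- cost - as.vector(cb %*% T)
      rc[basis] <- 0
      cand <- allowed[rc[allowed] < -tol]
      if (!length(cand)) return("optimal")
      j <- min(cand)                     # Bland: smallest index enters
      col <- T[, j]
      rows <- which(col > tol)
      if (!length(rows)) return("unbounded")
      ratios <- rhs[rows] / col[rows]
      rmin <- min(ratios)
      tied <- rows[ratios <= rmin + tol]
      r <- tied[which.min(basis[tied])]  # Bland: smallest basis index leaves
      pivot(r, j)
    }
    "maxiter"
  }

  # Phase 1: drive artificials to zero
  if (n_art > 0) {
    cost1 <- numeric(ncol_t); cost1[art_cols] <- 1
    st <- run_phase(cost1, seq_len(ncol_t))
    if (st != "optimal") return(list(status = "infeasible", x = NULL, objval = NA_real_))
    if (sum(rhs[basis %in% art_cols]) > 1e-7)
      return(list(status = "infeasible", x = NULL, objval = NA_real_))
    # pivot basic artificials (at zero) out where the row has support
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        jj <- which(abs(T[i, seq_len(n + n_slack)]) > tol)
        if (length(jj)) pivot(i, jj[1])
        # else: redundant row; artificial stays basic at zero and is barred
        # from re-entering below
      }
    }
  }
  # Phase 2
  cost2 <- c(cvec, numeric(n_slack + n_art))
  st <- run_phase(cost2, seq_len(n + n_slack))
  if (st == "maxiter") return(list(status = "maxiter", x = NULL, objval = NA_real_))
  if (st == "unbounded") return(list(status = "unbounded", x = NULL, objval = NA_real_))
  x <- numeric(ncol_t)
  x[basis] <- rhs
  list(status = "optimal", x = x[seq_len(n)], objval = sum(cvec * x[seq_len(n)]))
}

# Convenience: LP over a model's flux space with an arbitrary linear
# objective in flux coordinates, plus optional extra inequality rows.
model_lp <- function(model, obj, maximize = TRUE, A_ub = NULL, b_ub = NULL) {
  S <- as.matrix(build_stoich_matrix(model, sparse = FALSE))
  solve_lp(obj,
           A_eq = S, b_eq = rep(0, nrow(S)),
           A_ub = A_ub, b_ub = b_ub,
           lb = model$reactions$lower_bound,
           ub = model$reactions$upper_bound,
           maximize = maximize)
}

objective_vector <- function(model) {
  obj <- rep(0, nrow(model$reactions))
  if (length(model$objective))
    obj[reaction_index(model, names(model$objective))] <- as.numeric(model$objective)
  obj
}
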