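# ---------------------------------------------------------------------------
# LP layer
#
# All flux problems in the package are pure LPs over a box-bounded polytope
#   { v : S v = beq, lb <= v <= ub }  (optionally with extra >= rows),
# solved by the package's dense two-phase simplex (see R/simplex.R).
# Variables are shifted to x = v - lb >= 0; upper bounds become slack rows,
# extra inequality rows get surplus variables. Boundedness of the box rules
# out unbounded primal problems.
# ---------------------------------------------------------------------------

#' Solve a bounded linear program over a flux polytope
#'
#' @param obj Objective coefficients (length n).
#' @param S Equality constraint matrix (m x n); right-hand side zero unless
#'   `beq` given.
#' @param lb,ub Finite variable bounds.
#' @param maximize Logical.
#' @param beq Right-hand side of `S v = beq` (default zeros).
#' @param A_ge,b_ge Optional extra rows `A_ge v >= b_ge`.
#' @param tol Pivot/feasibility tolerance.
#' @return List with `status` (`"optimal"`, `"infeasible"` or
#'   `"iteration_limit"`), `objective` and `x` (solution in original
#'   coordinates).
#' @export
solve_lp <- function(obj, S, lb, ub, maximize = TRUE, beq = NULL,
                     A_ge = NULL, b_ge = NULL, tol = 1e-9) {
  S <- as.matrix(S)
  n <- length(lb)
  stopifnot(length(ub) == n, length(obj) == n, ncol(S) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite bounds")
  if (is.null(beq)) beq <- numeric(nrow(S))

  # drop identically-zero equality rows (unused metabolites); redundant
  # dependent rows are handled by the simplex itself
  nz <- rowSums(S != 0) > 0 | beq != 0
  S <- S[nz, , drop = FALSE]; beq <- beq[nz]

  # shift x = v - lb  =>  x >= 0, slack rows enforce x <= ub - lb
  b_eq <- beq - as.vector(S %*% lb)
  n_ge <- if (is.null(A_ge)) 0L else nrow(matrix(A_ge, ncol = n))
  if (n_ge) {
    A_ge <- matrix(A_ge, ncol = n)
    b_ge <- b_ge - as.vector(A_ge %*% lb)
  }

  m_eq <- nrow(S)
  n_tot <- n + n + n_ge   # x, slack s, surplus t
  A <- matrix(0, m_eq + n + n_ge, n_tot)
  b <- numeric(m_eq + n + n_ge)
  if (m_eq) {
    A[seq_len(m_eq), seq_len(n)] <- S
    b[seq_len(m_eq)] <- b_eq
  }
  rows_ub <- m_eq + seq_len(n)
  A[cbind(rows_ub, seq_len(n))] <- 1
  A[cbind(rows_ub, n + seq_len(n))] <- 1
  b[rows_ub] <- ub - lb
  if (n_ge) {
    rows_ge <- m_eq + n + seq_len(n_ge)
    A[rows_ge, seq_len(n)] <- A_ge
    A[cbind(rows_ge, 2L * n + seq_len(n_ge))] <- -1
    b[rows_ge] <- b_ge
  }

  cc <- numeric(n_tot)
  cc[seq_len(n)] <- if (maximize) -obj else obj
  res <- dense_simplex(cc, A, b, tol = tol)
  if (res$status != "optimal")
    return(list(status = res$status, objective = NA_real_, x = NULL))
  x <- res$y[seq_len(n)] + lb
  list(status = "optimal", objective = sum(obj * x), x = x)
}

# Assemble the LP pieces of a model once.
lp_parts <- function(model) {
  list(S = as.matrix(stoich_matrix(model)),
       lb = model$reactions$lower_bound,
       ub = model$reactions$upper_bound,
       ids = model$reactions$id)
}

objective_vector <- function(model, objective = NULL) {
  if (is.null(objective)) objective <- model$objective
  if (!length(objective)) stop("model has no objective and none was supplied")
  obj <- numeric(n_reactions(model))
  obj[rxn_index(model, names(objective))] <- objective
  obj
}
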