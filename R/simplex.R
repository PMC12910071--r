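# ---------------------------------------------------------------------------
# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Solves   min  cc' y   s.t.  A y = b,  y >= 0
# on the small dense systems produced by the flux layer (tens of variables).
# Phase 1 minimizes the sum of artificial variables from an identity start;
# basic artificials left at zero are pivoted out (or their rows dropped as
# redundant) before phase 2. Bland's rule guarantees termination on the
# degenerate bases that metabolic networks routinely produce.
# ---------------------------------------------------------------------------

dense_simplex <- function(cc, A, b, tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(cc) == n)
  neg <- b < 0
  if (any(neg)) { A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg] }

  Tb <- cbind(A, diag(m))
  xB <- b
  basis <- n + seq_len(m)

  pivot <- function(r, j) {
    piv <- Tb[r, j]
    Tb[r, ] <<- Tb[r, ] / piv
    xB[r] <<- xB[r] / piv
    upd <- which(abs(Tb[, j]) > 0 & seq_len(m) != r)
    if (length(upd)) {
      f <- Tb[upd, j]
      Tb[upd, ] <<- Tb[upd, , drop = FALSE] - outer(f, Tb[r, ])
      xB[upd] <<- xB[upd] - f * xB[r]
      Tb[upd, j] <<- 0
    }
    xB[xB < 0 & xB > -tol] <<- 0
    basis[r] <<- j
  }

  run_phase <- function(costs, allowed) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return("iteration_limit")
      red <- costs - as.vector(costs[basis] %*% Tb)
      cand <- which(allowed & red < -tol)
      if (!length(cand)) return("optimal")
      j <- cand[1]                      # Bland: smallest entering index
      col <- Tb[, j]
      rows <- which(col > tol)
      if (!length(rows)) return("unbounded")
      ratio <- xB[rows] / col[rows]
      rmin <- min(ratio)
      ties <- rows[ratio <= rmin + tol]
      r <- ties[which.min(basis[ties])] # Bland: smallest leaving basis index
      pivot(r, j)
    }
  }

  scale <- max(1, max(abs(b)))
  c1 <- c(numeric(n), rep(1, m))
  st1 <- run_phase(c1, rep(TRUE, n + m))
  if (st1 != "optimal") return(list(status = st1, y = NULL, value = NA_real_))
  if (sum(xB[basis > n]) > 1e-7 * scale)
    return(list(status = "infeasible", y = NULL, value = NA_real_))

  # drive artificials out of the basis
  art_rows <- which(basis > n)
  drop_rows <- integer(0)
  for (r in art_rows) {
    j <- which(abs(Tb[r, seq_len(n)]) > tol)[1]
    if (is.na(j)) drop_rows <- c(drop_rows, r) else pivot(r, j)
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    xB <- xB[-drop_rows]
    basis <- basis[-drop_rows]
    m <- length(basis)
  }

  c2 <- c(cc, numeric(ncol(Tb) - n))
  st2 <- run_phase(c2, c(rep(TRUE, n), rep(FALSE, ncol(Tb) - n)))
  if (st2 != "optimal") return(list(status = st2, y = NULL, value = NA_real_))
  y <- numeric(n)
  in_n <- basis <= n
  y[basis[in_n]] <- xB[in_n]
  list(status = "optimal", y = y, value = sum(cc * y))
}
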