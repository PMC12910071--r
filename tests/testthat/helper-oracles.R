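# Brute-force LP oracles: exhaustive vertex enumeration of the small
# polytope { S v = beq, lb <= v <= ub }. A vertex fixes n - rank(S) variables
# at a bound and solves for the rest; the optimum of a linear objective over
# the polytope is attained at a vertex. Independent of the package's simplex.

enumerate_vertices <- function(S, lb, ub, beq = NULL) {
  S <- as.matrix(S)
  n <- length(lb)
  if (is.null(beq)) beq <- numeric(nrow(S))
  r <- qr(S)$rank
  d <- n - r
  verts <- list()
  combs <- if (d > 0) utils::combn(n, d) else matrix(integer(0), nrow = 0, ncol = 1)
  for (ci in seq_len(ncol(combs))) {
    fixed <- combs[, ci]
    free <- setdiff(seq_len(n), fixed)
    npat <- if (d > 0) 2^d else 1
    for (pat in 0:(npat - 1)) {
      vals <- if (d > 0)
        ifelse(bitwAnd(pat, 2^(seq_len(d) - 1)) > 0, ub[fixed], lb[fixed])
      else numeric(0)
      rhs <- beq - if (d > 0) as.vector(S[, fixed, drop = FALSE] %*% vals) else 0
      sol <- tryCatch(qr.solve(S[, free, drop = FALSE], rhs),
                      error = function(e) NULL)
      if (is.null(sol)) next
      v <- numeric(n); v[fixed] <- vals; v[free] <- sol
      if (max(abs(as.vector(S %*% v) - beq)) > 1e-7) next
      if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
      verts[[length(verts) + 1L]] <- pmin(pmax(v, lb), ub)
    }
  }
  if (!length(verts)) return(NULL)
  unique(do.call(rbind, verts))
}

fba_oracle <- function(obj, S, lb, ub) {
  V <- enumerate_vertices(S, lb, ub)
  if (is.null(V)) return(NULL)
  vals <- as.vector(V %*% obj)
  list(value = max(vals), v = V[which.max(vals), ])
}

# FVA oracle: augment with a bounded surplus s = c'v - alpha*z, then take
# per-reaction extrema over the augmented polytope's vertices.
fva_oracle <- function(obj, S, lb, ub, alpha) {
  z <- fba_oracle(obj, S, lb, ub)$value
  if (alpha > 0) {
    S_aug <- rbind(cbind(S, 0), c(obj, -1))
    lb_aug <- c(lb, 0)
    ub_aug <- c(ub, max(0, (1 - alpha) * z) + 1e-9)
    beq <- c(numeric(nrow(S)), alpha * z)
    V <- enumerate_vertices(S_aug, lb_aug, ub_aug, beq)
    V <- V[, seq_along(lb), drop = FALSE]
  } else {
    V <- enumerate_vertices(S, lb, ub)
  }
  list(min = apply(V, 2, min), max = apply(V, 2, max), z = z)
}

# pFBA oracle: on the irreversible-split model with the objective pinned at
# its optimum, total flux is linear, so its minimum is at a vertex.
pfba_oracle <- function(split_model, obj_named, z) {
  S <- as.matrix(gemdiff::stoich_matrix(split_model))
  lb <- split_model$reactions$lower_bound
  ub <- split_model$reactions$upper_bound
  obj <- numeric(ncol(S))
  obj[match(names(obj_named), colnames(S))] <- obj_named
  S_aug <- rbind(S, obj)
  beq <- c(numeric(nrow(S)), z)
  V <- enumerate_vertices(S_aug, lb, ub, beq)
  tot <- rowSums(V)
  list(total = min(tot), v = V[which.min(tot), ])
}
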