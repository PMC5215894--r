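# Dense two-phase primal simplex with Bland's rule. Small, deterministic LP
# kernel used by the exemplar module; problems here are a few dozen variables,
# so a dense tableau is appropriate and cycling is excluded by Bland's rule.

# min c'x  s.t.  A x = b, x >= 0, b >= 0 (rows may be sign-flipped by caller)
lp_simplex_standard <- function(c0, A, b, tol = 1e-9, max_iter = 100000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(c0) == n, length(b) == m, all(b >= -tol))
  b <- pmax(b, 0)

  pivot_loop <- function(Tmat, basis, cost, ncols) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(T = Tmat, basis = basis, status = 3L))
      cb <- cost[basis]
      red <- drop(cb %*% Tmat[, seq_len(ncols), drop = FALSE]) - cost[seq_len(ncols)]
      red[basis] <- 0
      enter <- which(red > tol)
      if (!length(enter)) return(list(T = Tmat, basis = basis, status = 0L))
      j <- min(enter)                                # Bland's rule
      col <- Tmat[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(T = Tmat, basis = basis, status = 1L))
      ratio <- Tmat[pos, ncols + 1L] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]              # Bland tie-break
      Tmat[i, ] <- Tmat[i, ] / Tmat[i, j]
      other <- setdiff(seq_len(nrow(Tmat)), i)
      fac <- Tmat[other, j]
      nz <- other[abs(fac) > 0]
      if (length(nz)) Tmat[nz, ] <- Tmat[nz, ] - outer(Tmat[nz, j], Tmat[i, ])
      basis[i] <- j
    }
  }

  # phase 1
  Tmat <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  r1 <- pivot_loop(Tmat, basis, cost1, n + m)
  if (r1$status != 0L) return(list(status = 3L))
  xb <- r1$T[, n + m + 1L]
  if (sum(cost1[r1$basis] * xb) > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = 2L))                        # infeasible
  }
  Tmat <- r1$T; basis <- r1$basis
  # drive artificials out of the basis; drop redundant rows
  keep <- rep(TRUE, length(basis))
  for (i in seq_along(basis)) {
    if (basis[i] > n) {
      piv <- which(abs(Tmat[i, seq_len(n)]) > tol)
      if (length(piv)) {
        j <- piv[1L]
        Tmat[i, ] <- Tmat[i, ] / Tmat[i, j]
        other <- setdiff(seq_along(basis), i)
        nz <- other[abs(Tmat[other, j]) > 0]
        if (length(nz)) Tmat[nz, ] <- Tmat[nz, ] - outer(Tmat[nz, j], Tmat[i, ])
        basis[i] <- j
      } else keep[i] <- FALSE
    }
  }
  Tmat <- Tmat[keep, c(seq_len(n), n + m + 1L), drop = FALSE]
  basis <- basis[keep]
  # phase 2
  r2 <- pivot_loop(Tmat, basis, c0, n)
  if (r2$status != 0L) return(list(status = r2$status))
  x <- numeric(n)
  x[r2$basis] <- r2$T[, n + 1L]
  list(status = 0L, x = x, value = sum(c0 * x))
}

# min c'v  s.t.  E v = rhs, lower <= v <= upper (finite bounds)
lp_solve_bounded <- function(cv, E, rhs, lower, upper, tol = 1e-9) {
  n <- length(cv)
  stopifnot(ncol(E) == n, length(rhs) == nrow(E),
            all(is.finite(lower)), all(is.finite(upper)), all(lower <= upper))
  # shift x = v - lower >= 0; add slack rows for the caps x <= upper - lower
  m1 <- nrow(E)
  cap <- upper - lower
  A <- rbind(cbind(E, matrix(0, m1, n)),
             cbind(diag(n), diag(n)))
  b <- c(rhs - drop(E %*% lower), cap)
  flip <- b < 0
  if (any(flip)) { A[flip, ] <- -A[flip, , drop = FALSE]; b[flip] <- -b[flip] }
  res <- lp_simplex_standard(c(cv, rep(0, n)), A, b, tol = tol)
  if (res$status != 0L) {
    msg <- switch(as.character(res$status),
                  "1" = "linear program is unbounded",
                  "2" = "linear program is infeasible",
                  "simplex iteration cap reached")
    return(list(status = res$status, message = msg))
  }
  v <- res$x[seq_len(n)] + lower
  list(status = 0L, v = v, value = sum(cv * v), message = "optimal")
}
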