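#' Bounded-variable least squares by an active-set method
#'
#' Minimizes `||A x - b||_2` subject to `lower <= x <= upper`, where bounds may
#' be infinite. This is the numerical core of [solve_flux()]: irreversible
#' reactions get a lower bound of 0, reversible reactions are unconstrained.
#' The algorithm is the classical active-set scheme (optimize the free set by
#' unconstrained least squares, clip the step at the first bound crossing,
#' release the bound variable whose gradient most violates optimality), with
#' the least-squares subproblems solved by SVD so that rank-deficient
#' subproblems return the minimum-norm solution.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @param lower,upper numeric vectors of length n; entries may be `-Inf`/`Inf`.
#' @param tol convergence tolerance on the Karush-Kuhn-Tucker (KKT) optimality
#'   conditions, relative to the problem scale `max(1, ||A'b||_inf)`.
#' @param max_iter iteration cap; default `10 * n^2` (at least 100).
#'
#' @return list with `x`, `objective` (the residual 2-norm), `iterations`,
#'   `converged`, `deficient` (TRUE when some subproblem was rank-deficient so
#'   the reported minimizer is the minimum-norm one), and `kkt` (largest KKT
#'   violation at the solution).
#' @export
#' @examples
#' A <- matrix(c(-1, 1), 2, 1)
#' bvls_fit(A, c(-1, 1), lower = -Inf, upper = Inf)$x   # 1
#' bvls_fit(A, c(1, -1), lower = 0, upper = Inf)$x      # 0, bound active
bvls_fit <- function(A, b, lower, upper, tol = 1e-10, max_iter = NULL) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(lower > upper)) abort("lower bound exceeds upper bound")
  max_iter <- max_iter %||% max(100L, 10L * n^2)
  scale <- max(1, max(abs(crossprod(A, b))))
  kkt_tol <- tol * scale

  # state: 0 free, -1 at lower, +1 at upper
  state <- integer(n)
  x <- numeric(n)
  state[is.finite(lower)] <- -1L
  x[is.finite(lower)] <- lower[is.finite(lower)]
  at_up0 <- !is.finite(lower) & is.finite(upper)
  state[at_up0] <- 1L
  x[at_up0] <- upper[at_up0]

  deficient <- FALSE
  iter <- 0L
  capped <- FALSE

  solve_free <- function(free) {
    # min-norm LS over the free variables, bound variables held fixed
    rhs <- b - if (any(!free)) A[, !free, drop = FALSE] %*% x[!free] else 0
    Af <- A[, free, drop = FALSE]
    sv <- svd(Af)
    pos <- sv$d > max(dim(Af)) * .Machine$double.eps * max(sv$d, 1)
    if (!all(pos)) deficient <<- TRUE
    d_inv <- ifelse(pos, 1 / sv$d, 0)
    drop(sv$v %*% (d_inv * crossprod(sv$u, rhs)))
  }

  # optimize the current free set; variables that block the step get bound
  inner_optimize <- function() {
    while (any(state == 0L)) {
      iter <<- iter + 1L
      if (iter > max_iter) { capped <<- TRUE; return(invisible()) }
      free <- state == 0L
      z <- solve_free(free)
      lo_f <- lower[free]; up_f <- upper[free]
      inside <- z >= lo_f - kkt_tol & z <= up_f + kkt_tol
      if (all(inside)) {
        x[free] <<- pmin(pmax(z, lo_f), up_f)
        return(invisible())
      }
      xf <- x[free]
      dz <- z - xf
      alpha <- rep(Inf, length(z))
      hit_lo <- dz < 0 & is.finite(lo_f)
      hit_up <- dz > 0 & is.finite(up_f)
      alpha[hit_lo] <- (lo_f[hit_lo] - xf[hit_lo]) / dz[hit_lo]
      alpha[hit_up] <- (up_f[hit_up] - xf[hit_up]) / dz[hit_up]
      alpha <- pmax(alpha, 0)
      out_idx <- which(!inside)
      a <- min(alpha[out_idx], 1)
      j_block <- out_idx[which.min(alpha[out_idx])]
      xf_new <- xf + a * dz
      # bind every variable that reached its bound; the blocking variable is
      # always bound so the free set strictly shrinks
      at_lo <- is.finite(lo_f) & xf_new <= lo_f + kkt_tol & dz <= 0
      at_up <- is.finite(up_f) & xf_new >= up_f - kkt_tol & dz >= 0
      if (!any(at_lo | at_up)) {
        if (dz[j_block] < 0) at_lo[j_block] <- TRUE else at_up[j_block] <- TRUE
      }
      xf_new[at_lo] <- lo_f[at_lo]
      xf_new[at_up] <- up_f[at_up]
      x[free] <<- xf_new
      idx_free <- which(free)
      state[idx_free[at_lo]] <<- -1L
      state[idx_free[at_up]] <<- 1L
    }
    invisible()
  }

  inner_optimize()
  while (!capped) {
    r <- drop(b - A %*% x)
    g <- drop(crossprod(A, r))   # increasing x_j improves the fit when g_j > 0
    viol <- numeric(n)
    viol[state == -1L] <- pmax(g[state == -1L], 0)
    viol[state == 1L] <- pmax(-g[state == 1L], 0)
    if (!any(viol > kkt_tol)) break
    state[which.max(viol)] <- 0L
    inner_optimize()
  }

  r <- drop(b - A %*% x)
  g <- drop(crossprod(A, r))
  kkt <- max(c(0,
    abs(g[state == 0L]),
    pmax(g[state == -1L], 0),
    pmax(-g[state == 1L], 0)))
  if (capped) {
    return(list(x = x, objective = sqrt(sum(r^2)), iterations = iter,
                converged = FALSE, deficient = deficient, kkt = kkt,
                message = "iteration cap reached; returning best iterate"))
  }
  list(x = x, objective = sqrt(sum(r^2)), iterations = iter,
       converged = TRUE, deficient = deficient, kkt = kkt,
       message = "converged")
}
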