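# Shared fixtures and independent oracles, all built in code.

# toy chain network: external substrate -> A -> B, written via the parser
toy_chain_network <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  rf <- file.path(dir, "rx.tsv"); mf <- file.path(dir, "met.tsv")
  writeLines(c(
    "reaction_id\tpathway\treversible\tequation",
    "R1\tG\t0\tS -> A",
    "R2\tG\t1\tA <-> B",
    "R3\tG\t0\tB -> P"), rf)
  writeLines(c(
    "metabolite_id\tname\trole\tmeasurable\tetc_member",
    "S\tsubstrate\texternal\t0\t0",
    "A\tmet A\tinternal\t1\t0",
    "B\tmet B\tinternal\t0\t0",
    "P\tproduct\texternal\t1\t0"), mf)
  parse_network(rf, mf)
}

# reduced packaged network with one collagen-surrogate synthesis column
packaged_reduced_network <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- build_full_network()
      syn <- matrix_protein_synthesis()
      cache <<- add_synthesis_reaction(reduce_to_measured(net), syn$collagen2)
    }
    cache
  }
})

# small replicate table for two time points, one group
make_two_time_table <- function(values0, values1, metabolite = "M",
                                group = "compressed", t0 = 0, t1 = 15) {
  tibble::tibble(
    sample_id = paste0("s", seq_len(length(values0) + length(values1))),
    group = group,
    time = rep(c(t0, t1), c(length(values0), length(values1))),
    metabolite_id = metabolite,
    intensity = c(values0, values1))
}

# independent BVLS oracle: enumerate every subset of lower-bounded variables
# clamped at their bound and solve the unconstrained LS on the remainder.
# Each subproblem contributes two candidate minimizers (pivoted QR via
# lm.fit, and the SVD minimum-norm solution, which differ only when the
# subproblem is rank-deficient); the feasible minimum over all candidates is
# returned. Exponential in the bounded variables: tiny instances only.
bvls_oracle <- function(A, b, lower) {
  n <- ncol(A)
  bounded <- which(is.finite(lower))
  best <- Inf
  best_x <- NULL
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), length(bounded)))
  if (!nrow(subsets)) subsets <- data.frame(row.names = "all_free")
  ls_candidates <- function(Af, rhs) {
    qr_coef <- suppressWarnings(stats::lm.fit(Af, rhs)$coefficients)
    qr_coef[is.na(qr_coef)] <- 0
    sv <- svd(Af)
    pos <- sv$d > max(dim(Af)) * .Machine$double.eps * max(sv$d, 1)
    mn <- drop(sv$v %*% (ifelse(pos, 1 / sv$d, 0) * crossprod(sv$u, rhs)))
    list(unname(qr_coef), mn)
  }
  for (k in seq_len(nrow(subsets))) {
    clamped <- bounded[unlist(subsets[k, ])]
    free <- setdiff(seq_len(n), clamped)
    x0 <- numeric(n)
    x0[clamped] <- lower[clamped]
    cands <- if (length(free)) {
      rhs <- b - if (length(clamped)) A[, clamped, drop = FALSE] %*% x0[clamped] else 0
      ls_candidates(A[, free, drop = FALSE], rhs)
    } else list(numeric(0))
    for (sol in cands) {
      x <- x0
      x[free] <- sol
      if (any(x[bounded] < lower[bounded] - 1e-9)) next
      obj <- sqrt(sum((A %*% x - b)^2))
      if (obj < best - 1e-12) { best <- obj; best_x <- x }
    }
  }
  list(x = best_x, objective = best)
}

# independent LP oracle: enumerate candidate vertices of
# {E v = 0, lower <= v <= upper} by fixing (n - rank) variables at bounds
# and solving the equality system for the rest.
lp_vertex_oracle <- function(cv, E, lower, upper, tol = 1e-9) {
  n <- ncol(E)
  r <- qr(E)$rank
  nfix <- n - r
  best <- Inf; best_v <- NULL
  if (nfix == 0) return(list(v = rep(0, n), value = 0))
  combos <- utils::combn(n, nfix, simplify = FALSE)
  for (fix in combos) {
    free <- setdiff(seq_len(n), fix)
    Ef <- E[, free, drop = FALSE]
    if (qr(Ef)$rank < length(free)) next
    grid <- expand.grid(rep(list(1:2), nfix))
    for (g in seq_len(nrow(grid))) {
      v <- numeric(n)
      v[fix] <- ifelse(unlist(grid[g, ]) == 1, lower[fix], upper[fix])
      rhs <- -E[, fix, drop = FALSE] %*% v[fix]
      sol <- tryCatch(qr.solve(Ef, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      v[free] <- sol
      if (any(v < lower - tol) || any(v > upper + tol)) next
      if (max(abs(E %*% v)) > tol) next
      val <- sum(cv * v)
      if (val < best - 1e-12) { best <- val; best_v <- v }
    }
  }
  list(v = best_v, value = best)
}

# deterministic default simulation on the packaged reduced network
default_sim <- function(noise_cv = 0.05, seed = 1, net = packaged_reduced_network()) {
  generate_table(simulation_config(net, noise_cv = noise_cv, seed = seed))
}
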