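test_that("trivial one-reaction systems solve exactly", {
  # reversible A <-> B, delta = (-1, +1): consistent, v = 1
  A <- matrix(c(-1, 1), 2, 1)
  fit <- bvls_fit(A, c(-1, 1), lower = -Inf, upper = Inf)
  expect_equal(fit$x, 1, tolerance = 1e-10)
  expect_equal(fit$objective, 0, tolerance = 1e-10)

  # same reaction irreversible with delta = (+1, -1): bound active, v = 0
  fit2 <- bvls_fit(A, c(1, -1), lower = 0, upper = Inf)
  expect_equal(fit2$x, 0)
  expect_equal(fit2$objective^2, 2, tolerance = 1e-10)
})

test_that("BVLS matches the active-set enumeration oracle on 100 seeded instances", {
  worst_gap <- 0
  worst_kkt <- 0
  for (s in 1:100) {
    set.seed(s)
    m <- sample(3:6, 1); n <- sample(2:4, 1)
    A <- matrix(rnorm(m * n), m, n)
    b <- rnorm(m)
    w <- if (s %% 2 == 0) runif(m, 0.2, 5) else rep(1, m)
    Aw <- A * w; bw <- b * w
    lower <- ifelse(runif(n) < 0.6, 0, -Inf)
    fit <- bvls_fit(Aw, bw, lower = lower, upper = Inf)
    oracle <- bvls_oracle(Aw, bw, lower)
    worst_gap <- max(worst_gap, abs(fit$objective - oracle$objective))
    worst_kkt <- max(worst_kkt, fit$kkt)
  }
  expect_lt(worst_gap, 1e-6)
  expect_lt(worst_kkt, 1e-8)
})

test_that("BVLS agrees with quadprog on strictly convex instances", {
  skip_if_not_installed("quadprog")
  for (s in 1:25) {
    set.seed(200 + s)
    m <- 8; n <- 4
    A <- matrix(rnorm(m * n), m, n)
    b <- rnorm(m)
    lower <- ifelse(runif(n) < 0.5, 0, -Inf)
    fit <- bvls_fit(A, b, lower = lower, upper = Inf)
    D <- crossprod(A); d <- crossprod(A, b)
    bounded <- which(is.finite(lower))
    Amat <- diag(n)[, bounded, drop = FALSE]
    qp <- quadprog::solve.QP(D, d, Amat, bvec = rep(0, length(bounded)))
    expect_equal(fit$x, qp$solution, tolerance = 1e-7)
  }
})

test_that("weighting the problem rows is row-wise exact", {
  net <- packaged_reduced_network()
  sim <- default_sim(noise_cv = 0.05, seed = 3)
  acc <- compute_weights(estimate_accumulation(sim$table, "compressed", 0, 15))
  prob_u <- assemble_flux_problem(net, acc, weights = "unit")
  expect_equal(prob_u$S_w, stoich_matrix(net))

  prob <- assemble_flux_problem(net, acc)
  i <- match("PYR", prob$metabolite_id)
  expect_equal(prob$S_w[i, ], stoich_matrix(net)[i, ] * prob$weights[i])
  expect_equal(prob$delta_w[i], prob$delta[i] * prob$weights[i])
  expect_equal(dim(prob$S_w), c(48L, 39L))

  # doubling one weight doubles exactly that weighted row
  acc2 <- acc
  j <- which(acc2$metabolite_id == "PYR")
  acc2$weight[j] <- 2 * acc2$weight[j]
  prob2 <- assemble_flux_problem(net, acc2)
  expect_equal(prob2$S_w[i, ], 2 * prob$S_w[i, ])
  expect_equal(prob2$delta_w[i], 2 * prob$delta_w[i])
  other <- setdiff(seq_len(48), i)
  expect_equal(prob2$S_w[other, ], prob$S_w[other, ])
})

test_that("scaling all weights rescales the objective but not the argmin", {
  net <- packaged_reduced_network()
  sim <- default_sim(noise_cv = 0.05, seed = 4)
  acc <- compute_weights(estimate_accumulation(sim$table, "compressed", 0, 15))
  fit1 <- solve_flux(assemble_flux_problem(net, acc))
  acc2 <- acc; acc2$weight <- 3 * acc2$weight
  fit2 <- solve_flux(assemble_flux_problem(net, acc2))
  expect_equal(tidy(fit2)$flux, tidy(fit1)$flux, tolerance = 1e-8)
  expect_equal(fit2$objective, 3 * fit1$objective, tolerance = 1e-8)
})

test_that("objective never exceeds the zero-flux objective", {
  net <- packaged_reduced_network()
  for (s in 1:5) {
    sim <- default_sim(noise_cv = 0.1, seed = s)
    acc <- compute_weights(estimate_accumulation(sim$table, "compressed", 0, 15))
    prob <- assemble_flux_problem(net, acc)
    fit <- solve_flux(prob)
    expect_lte(fit$objective, sqrt(sum(prob$delta_w^2)) + 1e-9)
  }
})

test_that("the packaged reduced fit is unique: independent solves agree", {
  net <- packaged_reduced_network()
  sim <- default_sim(noise_cv = 0.05, seed = 6)
  acc <- compute_weights(estimate_accumulation(sim$table, "compressed", 0, 15))
  f1 <- solve_flux(assemble_flux_problem(net, acc))
  f2 <- solve_flux(assemble_flux_problem(net, acc), tol = 1e-12)
  expect_equal(tidy(f1)$flux, tidy(f2)$flux, tolerance = 1e-8)
  expect_false(f1$solver$deficient)
})

test_that("residual reports expose the perturbed row first", {
  # full-rank overdetermined toy: perturbing one row dominates the report
  dir <- withr::local_tempdir()
  writeLines(c("reaction_id\tpathway\treversible\tequation",
               "R1\tG\t1\tA <-> B",
               "R2\tG\t1\tB <-> C"),
             file.path(dir, "rx.tsv"))
  writeLines(c("metabolite_id\tname\trole\tmeasurable\tetc_member",
               "A\ta\tinternal\t1\t0",
               "B\tb\tinternal\t1\t0",
               "C\tc\tinternal\t1\t0"),
             file.path(dir, "met.tsv"))
  net <- parse_network(file.path(dir, "rx.tsv"), file.path(dir, "met.tsv"))
  v_true <- c(R1 = 2, R2 = 1)
  delta <- drop(stoich_matrix(net) %*% v_true)
  acc <- tibble::tibble(metabolite_id = names(delta), delta = delta,
                        variance = 1, n0 = 3, n1 = 3, weight = 1)
  fit <- solve_flux(assemble_flux_problem(net, acc))
  expect_true(all(abs(residual_report(fit)$raw) < 1e-8))

  acc$delta[acc$metabolite_id == "B"] <- acc$delta[acc$metabolite_id == "B"] + 1
  fit2 <- solve_flux(assemble_flux_problem(net, acc))
  rep2 <- residual_report(fit2)
  expect_equal(rep2$metabolite_id[1], "B")
  expect_equal(rep2$weighted, rep2$raw * rep2$weight)
})

test_that("hard zero constraints are honoured or error when infeasible", {
  net <- packaged_reduced_network()
  sim <- default_sim(noise_cv = 0.05, seed = 8)
  acc <- compute_weights(estimate_accumulation(sim$table, "compressed", 0, 15))
  fit <- solve_flux(assemble_flux_problem(net, acc, hard_zero = TRUE))
  con <- fit$residuals$constrained_zero
  scale <- max(1, max(abs(fit$residuals$raw)))
  expect_lt(max(abs(fit$residuals$raw[con])) / scale, 1e-6)
})
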