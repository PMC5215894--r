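#' Assemble the weighted bounded-variable least-squares problem
#'
#' Aligns an accumulation table with the rows of a (reduced) network and
#' builds the weighted system: row i of `S` and `delta_i` are both multiplied
#' by the weight `w_i` (the reciprocal of the accumulation variance). Rows
#' flagged `constrained_zero` get `delta = 0`; among them, the
#' electron-transport carrier rows (`lowest_weight`) receive the minimum
#' measured weight and any remaining unmeasured-internal rows the median
#' measured weight. Irreversible reactions get a lower bound of 0.
#'
#' @param net a [flux_network], typically from [reduce_to_measured()] (plus a
#'   synthesis column).
#' @param acc an `accumulation_tbl`; must cover every measurable metabolite of
#'   `net`. May be `NULL` together with `weights = "unit"` only when every
#'   metabolite is constrained (rarely useful).
#' @param weights `"inverse_variance"` (default; requires [compute_weights()]
#'   to have been applied, or applies it) or `"unit"` for an unweighted fit.
#' @param hard_zero if `TRUE`, the zero-accumulation rows are enforced (to
#'   solver tolerance) by weight escalation instead of competing with data
#'   rows; [solve_flux()] verifies them afterwards and errors if they cannot
#'   be met.
#' @return a `flux_problem`: weighted matrix `S_w`, weighted vector `delta_w`,
#'   bounds, the raw `delta` and `weight` vectors, and bookkeeping tables.
#' @export
assemble_flux_problem <- function(net, acc,
                                  weights = c("inverse_variance", "unit"),
                                  hard_zero = FALSE) {
  weights <- match.arg(weights)
  stopifnot(inherits(net, "flux_network"))
  mets <- net$metabolites
  S <- net$S
  measured <- mets$measurable & !mets$constrained_zero
  if (weights == "inverse_variance") {
    if (is.null(acc)) abort("inverse-variance weighting needs an accumulation table")
    if (all(is.na(acc$weight))) acc <- compute_weights(acc)
  }
  delta <- setNames(rep(0, nrow(mets)), mets$metabolite_id)
  w <- setNames(rep(NA_real_, nrow(mets)), mets$metabolite_id)
  if (!is.null(acc)) {
    missing_m <- setdiff(mets$metabolite_id[measured], acc$metabolite_id)
    if (length(missing_m)) {
      abort(paste0("accumulation table lacks measurable metabolite(s): ",
                   paste(missing_m, collapse = ", ")))
    }
    idx <- match(mets$metabolite_id, acc$metabolite_id)
    delta[measured] <- acc$delta[idx[measured]]
    if (weights == "inverse_variance") {
      w[measured] <- acc$weight[idx[measured]]
      if (any(!is.finite(w[measured]) | w[measured] <= 0)) {
        abort("weights must be positive and finite")
      }
    }
  }
  if (weights == "unit") {
    w[] <- 1
  } else {
    w_meas <- w[measured]
    w[mets$constrained_zero & mets$lowest_weight] <- min(w_meas)
    w[mets$constrained_zero & !mets$lowest_weight] <- stats::median(w_meas)
  }
  hard_rows <- which(mets$constrained_zero)
  if (hard_zero && length(hard_rows)) {
    w[hard_rows] <- 1e8 * max(w)
  }
  S_w <- S * w
  delta_w <- delta * w
  structure(list(
    S_w = S_w, delta_w = delta_w,
    delta = delta, weights = w,
    lower = ifelse(net$reactions$reversible, -Inf, 0),
    upper = rep(Inf, nrow(net$reactions)),
    hard_rows = if (hard_zero) hard_rows else integer(0),
    reactions = net$reactions[c("reaction_id", "pathway", "reversible")],
    metabolite_id = mets$metabolite_id,
    constrained_zero = mets$constrained_zero),
    class = "flux_problem")
}

#' Solve the weighted BVLS problem for the average flux vector
#'
#' Minimizes the weighted residual `||S_w v - delta_w||_2` over the flux
#' vector `v`, subject to `v_i >= 0` for irreversible reactions (negative flux
#' in the solution means a reversible reaction running against its drawn
#' forward direction). Any method converging to the global optimum of this
#' convex program is acceptable; the implementation is the active-set solver
#' [bvls_fit()].
#'
#' @param problem a `flux_problem` from [assemble_flux_problem()].
#' @param tol solver tolerance (KKT, relative to the problem scale).
#' @return a `flux_fit`: `flux` tibble (`reaction_id`, `pathway`, `flux`,
#'   `at_bound`), `objective` (the weighted residual norm), `residuals` tibble,
#'   and solver diagnostics. Rank-deficient problems return the minimum-norm
#'   minimizer with a warning.
#' @export
solve_flux <- function(problem, tol = 1e-10) {
  stopifnot(inherits(problem, "flux_problem"))
  fit <- bvls_fit(problem$S_w, problem$delta_w,
                  lower = problem$lower, upper = problem$upper, tol = tol)
  if (!fit$converged) {
    abort(paste0("BVLS did not converge within the iteration cap (",
                 fit$iterations, " iterations); best objective ",
                 format(fit$objective)))
  }
  if (fit$deficient) {
    warn("flux problem is rank-deficient; reporting the minimum-norm minimizer")
  }
  v <- fit$x
  raw_resid <- drop(problem$S_w %*% v) / problem$weights - problem$delta
  if (length(problem$hard_rows)) {
    viol <- max(abs(raw_resid[problem$hard_rows]))
    scale <- max(1, max(abs(problem$delta)))
    if (viol > 1e-6 * scale) {
      abort(paste0("hard zero-accumulation rows are infeasible ",
                   "(max violation ", format(viol), ")"))
    }
  }
  at_bound <- (!problem$reactions$reversible) & abs(v) <= tol * max(1, max(abs(v)))
  flux <- problem$reactions |>
    dplyr::mutate(flux = v, at_bound = at_bound)
  residuals <- tibble(
    metabolite_id = problem$metabolite_id,
    raw = raw_resid,
    weight = problem$weights,
    weighted = raw_resid * problem$weights,
    constrained_zero = problem$constrained_zero)
  structure(list(flux = flux, objective = fit$objective,
                 residuals = residuals,
                 solver = list(converged = TRUE, iterations = fit$iterations,
                               kkt = fit$kkt, tol = tol,
                               deficient = fit$deficient)),
            class = "flux_fit")
}

#' Per-metabolite residual report for a flux fit
#'
#' Raw residual (`S v - delta`) and weighted residual per metabolite, ordered
#' by decreasing absolute weighted residual so the worst-fit metabolites come
#' first.
#'
#' @param fit a `flux_fit` from [solve_flux()].
#' @return tibble ordered by `abs(weighted)` descending.
#' @export
residual_report <- function(fit) {
  stopifnot(inherits(fit, "flux_fit"))
  fit$residuals |>
    dplyr::arrange(dplyr::desc(abs(.data$weighted)))
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("<flux_fit> ", nrow(x$flux), " reactions, weighted residual norm ",
      format(x$objective, digits = 6), "\n", sep = "")
  cat("  solver: ", x$solver$iterations, " iterations, KKT ",
      format(x$solver$kkt, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Tidy a flux fit into a per-reaction tibble
#'
#' @param x a `flux_fit`.
#' @param ... unused.
#' @export
#' @exportS3Method generics::tidy
tidy.flux_fit <- function(x, ...) x$flux

#' One-row summary of a flux fit
#'
#' @param x a `flux_fit`.
#' @param ... unused.
#' @export
#' @exportS3Method generics::glance
glance.flux_fit <- function(x, ...) {
  tibble(objective = x$objective,
         n_reactions = nrow(x$flux),
         n_at_bound = sum(x$flux$at_bound),
         iterations = x$solver$iterations,
         kkt = x$solver$kkt,
         converged = x$solver$converged,
         deficient = x$solver$deficient)
}
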