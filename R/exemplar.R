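#' Synthesis-maximizing exemplar flux profile by linear programming
#'
#' Solves the linear program
#' \deqn{\min_v c^T v \quad s.t. \quad S_I v = 0,\; A v \ge 0,\; v \le 1}
#' where `c` is zero except for -1 at the synthesis column, `S_I` is the
#' submatrix of `S` over internal-metabolite rows (pathway intermediates are
#' balanced at steady state; external pools such as glucose are left
#' unconstrained), and `A` selects the irreversible reactions. A symmetric
#' lower cap of -1 is applied to reversible reactions so the program is
#' bounded in every direction (the unit upper cap alone leaves some reversible
#' cycles unbounded). Because LP optima can be degenerate, a secondary LP
#' minimizes the L1 norm of `v` at the fixed optimal objective, making the
#' reported vertex deterministic across solvers.
#'
#' @param net a [flux_network] containing the synthesis column (see
#'   [add_synthesis_reaction()]) and internal/external role assignments.
#' @param synthesis_id reaction id of the synthesis column to maximize; when
#'   `NULL` and the network has exactly one `SYN` column, that column is used.
#' @param cap unit flux cap (default 1).
#' @param tie_break apply the L1 secondary minimization (default `TRUE`).
#' @return an `exemplar_profile`: `flux` tibble, `synthesis_flux`,
#'   `feasibility` diagnostics (`max_balance_violation`, bound violations).
#' @export
max_synthesis_profile <- function(net, synthesis_id = NULL, cap = 1,
                                  tie_break = TRUE) {
  stopifnot(inherits(net, "flux_network"))
  syn_cols <- net$reactions$reaction_id[net$reactions$pathway == "SYN"]
  if (is.null(synthesis_id)) {
    if (length(syn_cols) != 1L) {
      abort("network must contain exactly one SYN column, or name synthesis_id")
    }
    synthesis_id <- syn_cols
  }
  j_syn <- match(synthesis_id, net$reactions$reaction_id)
  if (is.na(j_syn) || net$reactions$pathway[j_syn] != "SYN") {
    abort(paste0("'", synthesis_id, "' is not a SYN column of the network"))
  }
  S <- net$S
  internal <- net$metabolites$role == "internal"
  S_I <- S[internal, , drop = FALSE]
  n <- ncol(S)
  reversible <- net$reactions$reversible
  lower <- ifelse(reversible, -cap, 0)
  upper <- rep(cap, n)
  cv <- numeric(n); cv[j_syn] <- -1

  res <- lp_solve_bounded(cv, S_I, rep(0, nrow(S_I)), lower, upper)
  if (res$status == 2L) {
    abort("exemplar LP infeasible; the zero vector is always feasible, so the constraints are malformed")
  }
  if (res$status != 0L) abort(paste0("exemplar LP failed: ", res$message))
  v <- res$v
  zstar <- res$value

  if (tie_break) {
    # v = p - q, p,q >= 0; minimize sum(p + q) at the fixed optimal objective
    E <- rbind(cbind(S_I, -S_I), c(cv, -cv))
    rhs <- c(rep(0, nrow(S_I)), zstar)
    lo2 <- rep(0, 2L * n)
    hi2 <- c(upper, ifelse(reversible, cap, 0))
    r2 <- lp_solve_bounded(rep(1, 2L * n), E, rhs, lo2, hi2)
    if (r2$status == 0L) v <- r2$v[seq_len(n)] - r2$v[n + seq_len(n)]
  }

  balance <- drop(S_I %*% v)
  feas <- list(
    max_balance_violation = if (length(balance)) max(abs(balance)) else 0,
    min_irreversible = if (any(!reversible)) min(v[!reversible]) else 0,
    max_flux = max(v))
  flux <- net$reactions[c("reaction_id", "pathway", "reversible")] |>
    dplyr::mutate(flux = v)
  structure(list(flux = flux, synthesis_flux = -zstar,
                 synthesis_id = synthesis_id, cap = cap,
                 feasibility = feas),
            class = "exemplar_profile")
}

#' @export
print.exemplar_profile <- function(x, ...) {
  cat("<exemplar_profile> maximizing ", x$synthesis_id,
      ": synthesis flux ", format(x$synthesis_flux, digits = 6), "\n", sep = "")
  cat("  max steady-state violation ",
      format(x$feasibility$max_balance_violation, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.exemplar_profile <- function(x, ...) x$flux

#' @export
#' @exportS3Method generics::glance
glance.exemplar_profile <- function(x, ...) {
  tibble(synthesis_id = x$synthesis_id,
         synthesis_flux = x$synthesis_flux,
         max_balance_violation = x$feasibility$max_balance_violation,
         min_irreversible = x$feasibility$min_irreversible,
         max_flux = x$feasibility$max_flux)
}

flux_vector <- function(p) {
  if (inherits(p, c("flux_fit", "exemplar_profile"))) {
    setNames(p$flux$flux, p$flux$reaction_id)
  } else if (is.numeric(p)) p
  else abort("expected a flux_fit, exemplar_profile, or numeric vector")
}

#' Shape features of a flux profile
#'
#' Summaries used to label a profile as protein-like or lipid-like: per
#' pathway, the total absolute flux and its spread, and for each precursor
#' withdrawal point (3PG and PYR in glycolysis; AKG and OAA in the TCA cycle)
#' the activity immediately feeding the precursor (`upstream_mean`: mean flux
#' of the pathway step(s) producing it) versus the pathway segment after it
#' (`downstream_mean`: mean flux of the later steps). When a synthesis column
#' withdraws the precursor, mass balance makes the segment after the
#' withdrawal carry less flux than the step feeding it, which is the
#' signature of a profile geared toward synthesis of that precursor's
#' products. Comparing whole-segment means instead would conflate the
#' withdrawal with stoichiometric flux doubling at the triose-phosphate
#' split, so the feeding step is the faithful reference point.
#'
#' @param profile a `flux_fit`, `exemplar_profile` or named flux vector.
#' @param net the [flux_network] the profile was computed on.
#' @return list with `pathway_totals` (tibble: pathway, total absolute flux,
#'   max/min absolute flux) and `precursor_steps` (tibble: precursor, pathway,
#'   upstream/downstream mean flux as defined above; `downstream_mean` is NA
#'   when the precursor closes its pathway).
#' @export
profile_shape_features <- function(profile, net) {
  v <- flux_vector(profile)
  rx <- net$reactions
  v <- v[rx$reaction_id]
  pathway_totals <- tibble(pathway = rx$pathway, flux = v) |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(total_abs = sum(abs(.data$flux)),
                     max_abs = max(abs(.data$flux)),
                     min_abs = min(abs(.data$flux)), .groups = "drop")
  precursors <- tibble(
    precursor = c("3PG", "PYR", "AKG", "OAA"),
    pathway = c("G", "G", "TCA", "TCA"))
  steps <- purrr::pmap(precursors, function(precursor, pathway) {
    in_path <- which(rx$pathway == pathway)
    produced <- purrr::map_lgl(rx$stoichiometry[in_path], function(st) {
      precursor %in% names(st) && st[[precursor]] > 0
    })
    if (!any(produced)) return(NULL)
    split_at <- max(which(produced))
    feeders <- in_path[produced]
    dn <- in_path[in_path > in_path[split_at]]
    tibble(precursor = precursor, pathway = pathway,
           upstream_mean = mean(v[feeders]),
           downstream_mean = if (length(dn)) mean(v[dn]) else NA_real_)
  }) |> dplyr::bind_rows()
  list(pathway_totals = pathway_totals, precursor_steps = steps)
}

#' Relative distance between two flux profiles
#'
#' Returns `||v1 - v2|| / min(||v1||, ||v2||)` (the scale used to state that
#' profiles computed with differing synthesis reactions agree to within a
#' fraction of the smaller vector's norm), plus per-reaction absolute
#' differences.
#'
#' @param p1,p2 `flux_fit`/`exemplar_profile` objects or named flux vectors
#'   with the same reaction ordering.
#' @return list with `relative_distance` and a `differences` tibble.
#' @export
#' @examples
#' v <- c(A = 1, B = 2)
#' compare_profiles(v, 1.01 * v)$relative_distance  # 0.01
compare_profiles <- function(p1, p2) {
  v1 <- flux_vector(p1); v2 <- flux_vector(p2)
  if (length(v1) != length(v2) ||
      (!is.null(names(v1)) && !is.null(names(v2)) && !identical(names(v1), names(v2)))) {
    abort("profiles must share the same reaction ordering")
  }
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (min(n1, n2) == 0) abort("relative distance undefined for a zero-norm profile")
  list(
    relative_distance = sqrt(sum((v1 - v2)^2)) / min(n1, n2),
    differences = tibble(
      reaction_id = names(v1) %||% as.character(seq_along(v1)),
      flux_1 = unname(v1), flux_2 = unname(v2),
      abs_difference = abs(v1 - v2)) |>
      dplyr::arrange(dplyr::desc(.data$abs_difference)))
}
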