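cell_stats <- function(table) {
  table |>
    dplyr::group_by(.data$group, .data$time, .data$metabolite_id) |>
    dplyr::summarise(m = mean(.data$intensity),
                     se = stats::sd(.data$intensity) / sqrt(dplyr::n()),
                     n = dplyr::n(),
                     sample_id = list(.data$sample_id), .groups = "drop")
}

# one randomized copy of the table: every replicate intensity is redrawn from
# a normal centred on the cell mean, truncated to the 95% CI (m +/- 1.96 SE).
# Rejection sampling; acceptance is ~95% so the loop is short. Consumes the
# RNG stream sequentially so a single upstream seed fixes everything.
draw_randomized <- function(stats_tbl) {
  rows <- purrr::pmap(stats_tbl, function(group, time, metabolite_id, m, se, n, sample_id) {
    if (!is.finite(se) || se == 0) {
      vals <- rep(m, n)
    } else {
      half <- 1.96 * se
      vals <- numeric(n)
      for (k in seq_len(n)) {
        repeat {
          x <- stats::rnorm(1, m, se)
          if (abs(x - m) <= half) break
        }
        vals[k] <- x
      }
    }
    tibble(sample_id = sample_id, group = group, time = time,
           metabolite_id = metabolite_id, intensity = vals)
  })
  dplyr::bind_rows(rows)
}

#' Randomized copies of an intensity table
#'
#' For each (group, time, metabolite) cell, the cell mean `m` and standard
#' error `SE` give the 95% confidence interval `m +/- 1.96 SE`; every
#' replicate is replaced by an independent draw from a normal centred on `m`
#' truncated to that interval. With zero within-cell variance all draws equal
#' the mean. Deterministic given `seed`.
#'
#' @param table long intensity table.
#' @param n_sets number of randomized tables.
#' @param seed integer seed.
#' @return list of `n_sets` intensity tables.
#' @export
randomize_table <- function(table, n_sets, seed) {
  check_intensity_table(table)
  st <- cell_stats(table)
  if (any(st$n < 2L)) {
    abort("every (group, time, metabolite) cell needs at least 2 replicates")
  }
  set.seed(as.integer(seed))
  purrr::map(seq_len(n_sets), function(i) draw_randomized(st))
}

#' Randomization-based sensitivity analysis of the fluxes
#'
#' Re-runs the full estimation (accumulation, Welch weights, BVLS solve) on
#' randomized copies of the intensity table and records, per randomized set
#' and per interval, the Pearson correlation between the randomized flux
#' vector and the original one. Also retains the ensembles of randomized flux
#' vectors and accumulation vectors for [flux_metabolite_correlation()].
#'
#' @param table long intensity table.
#' @param net a reduced [flux_network] (with any synthesis column already
#'   added).
#' @param intervals list of `c(t0, t1)` pairs, one flux vector per interval.
#' @param n_sets number of randomized data sets (the histogram in the source
#'   analysis used 10000).
#' @param seed integer seed; fixes the whole stream.
#' @param group experimental group to analyze.
#' @param center passed to [estimate_accumulation()].
#' @param hard_zero passed to [assemble_flux_problem()].
#' @return a `sensitivity_result`: `correlations` tibble (set, interval,
#'   correlation), `fraction_above` (share with correlation > 0.5),
#'   `ensemble` (list per interval: reactions x sets matrix), `acc_ensemble`
#'   (metabolites x sets), `original` fits, `n_skipped`.
#' @export
sensitivity_run <- function(table, net, intervals, n_sets = 100, seed = 1,
                            group = "compressed", center = "median",
                            hard_zero = FALSE) {
  check_intensity_table(table)
  intervals <- purrr::map(intervals, function(iv) {
    stopifnot(length(iv) == 2L, iv[2] > iv[1]); as.numeric(iv)
  })
  fit_one <- function(tb, iv) {
    acc <- estimate_accumulation(tb, group, iv[1], iv[2], center = center)
    if (all(acc$variance == 0)) {
      # degenerate (noise-free) data carry no weighting information
      prob <- assemble_flux_problem(net, acc, weights = "unit",
                                    hard_zero = hard_zero)
    } else {
      prob <- assemble_flux_problem(net, compute_weights(acc),
                                    hard_zero = hard_zero)
    }
    solve_flux(prob)
  }
  originals <- purrr::map(intervals, function(iv) fit_one(table, iv))
  v_orig <- purrr::map(originals, function(f) flux_vector(f))

  st <- cell_stats(table)
  if (any(st$n < 2L)) {
    abort("every (group, time, metabolite) cell needs at least 2 replicates")
  }
  set.seed(as.integer(seed))
  n_rx <- nrow(net$reactions)
  ensemble <- purrr::map(intervals, function(iv) {
    matrix(NA_real_, n_rx, n_sets,
           dimnames = list(net$reactions$reaction_id, NULL))
  })
  first_iv <- intervals[[1]]
  acc_ids <- NULL
  acc_ensemble <- NULL
  cors <- vector("list", n_sets)
  n_skipped <- 0L
  for (s in seq_len(n_sets)) {
    tb <- draw_randomized(st)
    row_s <- purrr::imap(intervals, function(iv, k) {
      fit <- tryCatch(fit_one(tb, iv), error = function(e) NULL)
      if (is.null(fit)) return(tibble(set = s, interval = k, correlation = NA_real_))
      v <- flux_vector(fit)
      ensemble[[k]][, s] <<- v
      if (k == 1L) {
        acc <- estimate_accumulation(tb, group, iv[1], iv[2], center = center)
        if (is.null(acc_ids)) {
          acc_ids <<- acc$metabolite_id
          acc_ensemble <<- matrix(NA_real_, length(acc_ids), n_sets,
                                  dimnames = list(acc_ids, NULL))
        }
        acc_ensemble[, s] <<- acc$delta[match(acc_ids, acc$metabolite_id)]
      }
      r <- if (all(v == v_orig[[k]])) 1 else stats::cor(v, v_orig[[k]])
      tibble(set = s, interval = k, correlation = r)
    })
    row_s <- dplyr::bind_rows(row_s)
    n_skipped <- n_skipped + sum(is.na(row_s$correlation))
    cors[[s]] <- row_s
  }
  correlations <- dplyr::bind_rows(cors)
  ok <- !is.na(correlations$correlation)
  structure(list(
    correlations = correlations,
    fraction_above = mean(correlations$correlation[ok] > 0.5),
    ensemble = ensemble,
    acc_ensemble = acc_ensemble,
    original = originals,
    intervals = intervals,
    n_sets = n_sets, seed = seed, n_skipped = n_skipped),
    class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> ", x$n_sets, " randomized sets x ",
      length(x$intervals), " interval(s)\n", sep = "")
  cat("  fraction of correlations > 0.5: ",
      format(x$fraction_above, digits = 4), "\n", sep = "")
  if (x$n_skipped) cat("  skipped (solver failure): ", x$n_skipped, "\n", sep = "")
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.sensitivity_result <- function(x, ...) x$correlations

#' @export
#' @exportS3Method generics::glance
glance.sensitivity_result <- function(x, ...) {
  tibble(n_sets = x$n_sets, seed = x$seed,
         n_intervals = length(x$intervals),
         fraction_above = x$fraction_above,
         median_correlation = stats::median(x$correlations$correlation, na.rm = TRUE),
         n_skipped = x$n_skipped)
}

#' Flux-accumulation correlation matrix over the randomized ensemble
#'
#' Entry (j, i) is the Pearson correlation, across the randomized sets, of
#' reaction j's flux with metabolite i's accumulation. Rows and columns are
#' clustered hierarchically on the Euclidean distance between their
#' correlation vectors. Constant fluxes or accumulations have undefined
#' correlation; those entries are reported as 0 and flagged.
#'
#' @param result a `sensitivity_result` with at least 3 retained sets.
#' @param interval which interval's flux ensemble to use (default 1).
#' @param linkage hierarchical clustering linkage (default `"average"`).
#' @return a `flux_met_cor`: `correlation` matrix (reactions x metabolites),
#'   `row_hclust`, `col_hclust`, and `flagged` tibble of undefined entries.
#' @export
flux_metabolite_correlation <- function(result, interval = 1,
                                        linkage = "average") {
  stopifnot(inherits(result, "sensitivity_result"))
  Fm <- result$ensemble[[interval]]
  Am <- result$acc_ensemble
  keep <- colSums(is.na(Fm)) == 0 & colSums(is.na(Am)) == 0
  if (sum(keep) < 3L) abort("need at least 3 retained randomized sets")
  Fm <- Fm[, keep, drop = FALSE]; Am <- Am[, keep, drop = FALSE]
  flux_const <- apply(Fm, 1, stats::sd) == 0
  acc_const <- apply(Am, 1, stats::sd) == 0
  C <- matrix(0, nrow(Fm), nrow(Am), dimnames = list(rownames(Fm), rownames(Am)))
  if (any(!flux_const) && any(!acc_const)) {
    C[!flux_const, !acc_const] <- stats::cor(t(Fm[!flux_const, , drop = FALSE]),
                                             t(Am[!acc_const, , drop = FALSE]))
  }
  flagged <- tidyr::expand_grid(
    reaction_id = rownames(Fm)[flux_const],
    metabolite_id = rownames(Am)) |>
    dplyr::bind_rows(tidyr::expand_grid(
      reaction_id = rownames(Fm)[!flux_const],
      metabolite_id = rownames(Am)[acc_const]))
  row_h <- stats::hclust(stats::dist(C), method = linkage)
  col_h <- stats::hclust(stats::dist(t(C)), method = linkage)
  structure(list(correlation = C, row_hclust = row_h, col_hclust = col_h,
                 flagged = flagged, n_sets_used = sum(keep)),
            class = "flux_met_cor")
}

#' Correlation-distance clustering of samples
#'
#' Builds the metabolite-by-sample intensity matrix over a metabolite subset
#' (typically the ANOVA-flagged set), z-standardizes each column (sample),
#' and clusters samples with the correlation distance `1 - r` between their
#' intensity vectors. Samples with zero variance over the subset are excluded
#' with a warning.
#'
#' @param table long intensity table.
#' @param metabolite_subset nonempty character vector of metabolite ids.
#' @param linkage linkage method for [stats::hclust()] (default `"average"`).
#' @return a `sample_clustering`: `hclust` object, leaf `order` (sample ids),
#'   `distance` matrix, and the standardized `matrix` (metabolites x samples).
#' @export
cluster_samples <- function(table, metabolite_subset, linkage = "average") {
  check_intensity_table(table)
  if (!length(metabolite_subset)) abort("metabolite subset is empty")
  sub <- dplyr::filter(table, .data$metabolite_id %in% metabolite_subset)
  wide <- sub |>
    dplyr::select("sample_id", "metabolite_id", "intensity") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "intensity")
  M <- as.matrix(wide[, -1])
  rownames(M) <- wide$metabolite_id
  sdev <- apply(M, 2, stats::sd)
  if (any(sdev == 0)) {
    warn(paste0("excluding zero-variance sample(s): ",
                paste(colnames(M)[sdev == 0], collapse = ", ")))
    M <- M[, sdev > 0, drop = FALSE]
  }
  if (ncol(M) < 2L) abort("need at least two samples with variation")
  Z <- scale(M)
  D <- 1 - stats::cor(M)
  h <- stats::hclust(stats::as.dist(D), method = linkage)
  structure(list(hclust = h, order = colnames(M)[h$order],
                 distance = D, matrix = Z, linkage = linkage),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering> ", ncol(x$matrix), " samples, ",
      nrow(x$matrix), " metabolites, ", x$linkage, " linkage\n", sep = "")
  cat("  leaf order: ", paste(x$order, collapse = " "), "\n", sep = "")
  invisible(x)
}
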