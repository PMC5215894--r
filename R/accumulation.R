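#' Per-metabolite accumulation rates from a replicate intensity table
#'
#' For each metabolite, the accumulation rate over `[t0, t1]` is
#' `delta = (center(a1) - center(a0)) / (t1 - t0)`, where `a0`, `a1` are the
#' replicate intensities at the two time points and `center` is the median
#' (robust for the small n of 4-5 typical of targeted LC-MS studies) or mean.
#' The variance attached to each rate is the Welch variance of the difference
#' of means, `s0^2/n0 + s1^2/n1`, divided by `(t1 - t0)^2` so that it lives on
#' the rate scale.
#'
#' @param table long intensity table with columns `sample_id`, `group`,
#'   `time`, `metabolite_id`, `intensity`.
#' @param group experimental group to use (e.g. `"compressed"`).
#' @param t0,t1 the two time points, `t1 > t0`, in minutes.
#' @param center `"median"` (default) or `"mean"`.
#' @param lod optional limit-of-detection floor: intensities strictly below it
#'   are dropped before any computation (default `NULL`, off).
#' @return a tibble (class `accumulation_tbl`) with one row per metabolite:
#'   `metabolite_id`, `delta`, `variance`, `n0`, `n1`, `weight` (NA until
#'   [compute_weights()] is applied). The interval, group and center choice
#'   are stored as attributes.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = paste0("s", 1:6), group = "compressed",
#'   time = rep(c(0, 15), each = 3), metabolite_id = "PYR",
#'   intensity = c(1, 2, 9, 4, 5, 30))
#' estimate_accumulation(tbl, "compressed", 0, 15)$delta  # (5 - 2)/15 = 0.2
estimate_accumulation <- function(table, group, t0, t1,
                                  center = c("median", "mean"), lod = NULL) {
  center <- match.arg(center)
  check_intensity_table(table)
  if (t1 <= t0) abort("t1 must be greater than t0")
  if (!is.null(lod)) table <- dplyr::filter(table, .data$intensity >= lod)
  sub <- table |>
    dplyr::filter(.data$group == .env$group, .data$time %in% c(t0, t1))
  if (!nrow(sub)) abort("no rows for the requested group and times")
  for (tt in c(t0, t1)) {
    if (!any(sub$time == tt)) {
      abort(paste0("time point ", tt, " absent for group '", group, "'"))
    }
  }
  cfun <- if (center == "median") stats::median else base::mean
  stats_tbl <- sub |>
    dplyr::group_by(.data$metabolite_id, .data$time) |>
    dplyr::summarise(center = cfun(.data$intensity),
                     s2 = stats::var(.data$intensity),
                     n = dplyr::n(), .groups = "drop")
  incomplete <- stats_tbl |>
    dplyr::count(.data$metabolite_id) |>
    dplyr::filter(.data$n < 2L)
  if (nrow(incomplete)) {
    abort(paste0("metabolite(s) present at only one time point: ",
                 paste(incomplete$metabolite_id, collapse = ", ")))
  }
  wide <- stats_tbl |>
    tidyr::pivot_wider(names_from = "time",
                       values_from = c("center", "s2", "n"))
  c0 <- wide[[paste0("center_", t0)]]; c1 <- wide[[paste0("center_", t1)]]
  s0 <- wide[[paste0("s2_", t0)]]; s1 <- wide[[paste0("s2_", t1)]]
  n0 <- wide[[paste0("n_", t0)]]; n1 <- wide[[paste0("n_", t1)]]
  dt <- t1 - t0
  out <- tibble(
    metabolite_id = wide$metabolite_id,
    delta = (c1 - c0) / dt,
    variance = welch_variance(s0, n0, s1, n1) / dt^2,
    n0 = n0, n1 = n1,
    weight = NA_real_)
  structure(out, class = c("accumulation_tbl", class(out)),
            interval = c(t0 = t0, t1 = t1), group = group, center = center)
}

#' Welch variance of a difference of means
#'
#' `s1_sq/n1 + s2_sq/n2`: the variance of the difference in means between two
#' samples with unequal variances. Vectorized over its arguments.
#'
#' @param s1_sq,s2_sq sample variances (>= 0).
#' @param n1,n2 sample sizes (>= 2).
#' @return numeric vector of variances.
#' @export
#' @examples
#' welch_variance(4, 4, 9, 4)  # 3.25
welch_variance <- function(s1_sq, n1, s2_sq, n2) {
  if (any(n1 < 2) || any(n2 < 2)) abort("sample sizes must be at least 2")
  if (any(s1_sq < 0) || any(s2_sq < 0)) abort("variances must be nonnegative")
  s1_sq / n1 + s2_sq / n2
}

#' Inverse-variance weights for an accumulation table
#'
#' The weight of a metabolite is the reciprocal of its accumulation variance.
#' Zero variances would give infinite weight; under the default `"cap"` policy
#' they receive the maximum finite weight (preserving the "most reliable"
#' ranking), under `"epsilon"` the variance is floored at `epsilon` first.
#'
#' @param acc an `accumulation_tbl` from [estimate_accumulation()].
#' @param zero_var_policy `"cap"` (default) or `"epsilon"`.
#' @param epsilon variance floor used by the `"epsilon"` policy.
#' @return `acc` with the `weight` column filled.
#' @export
compute_weights <- function(acc, zero_var_policy = c("cap", "epsilon"),
                            epsilon = 1e-12) {
  zero_var_policy <- match.arg(zero_var_policy)
  if (!"variance" %in% names(acc)) abort("accumulation table lacks variances")
  v <- acc$variance
  if (all(v == 0)) abort("all variances are zero; data are degenerate")
  w <- ifelse(v > 0, 1 / v, NA_real_)
  if (anyNA(w)) {
    w[is.na(w)] <- switch(zero_var_policy,
                          cap = max(w, na.rm = TRUE),
                          epsilon = 1 / epsilon)
  }
  acc$weight <- w
  acc
}

#' ANOVA screen for metabolites changing over time
#'
#' Fits a per-metabolite ANOVA with time as a factor (optionally crossed with
#' group) and flags metabolites whose time effect has `p <= alpha`. Following
#' the screening use of this test, the default alpha is deliberately lenient
#' (0.15). Metabolites with no intensity variation at all get `p = 1` by
#' convention (no evidence of change) and are never flagged; metabolites with
#' fewer than two time levels are excluded with a warning.
#'
#' @param table long intensity table (see [estimate_accumulation()]).
#' @param alpha screening threshold on the time-effect p-value.
#' @param factors `"time"` for the one-factor screen or `c("time", "group")`
#'   for the two-factor variant with interaction.
#' @return tibble with `metabolite_id`, `p_time` (and `p_group`,
#'   `p_interaction` for the two-factor variant) and `flagged`.
#' @export
anova_screen <- function(table, alpha = 0.15, factors = "time") {
  check_intensity_table(table)
  stopifnot(all(factors %in% c("time", "group")))
  two_factor <- all(c("time", "group") %in% factors)
  res <- table |>
    dplyr::group_by(.data$metabolite_id) |>
    dplyr::group_map(function(d, key) {
      if (dplyr::n_distinct(d$time) < 2L) {
        warn(paste0("metabolite ", key$metabolite_id,
                    " has fewer than two time levels; excluded"))
        return(NULL)
      }
      if (stats::var(d$intensity) == 0) {
        out <- tibble(metabolite_id = key$metabolite_id, p_time = 1)
        if (two_factor) out$p_group <- 1
        return(out)
      }
      d$time_f <- factor(d$time)
      if (two_factor && dplyr::n_distinct(d$group) > 1L) {
        fit <- stats::aov(intensity ~ time_f * group, data = d)
        tab <- summary(fit)[[1]]
        p <- tab[["Pr(>F)"]]
        rn <- trimws(rownames(tab))
        tibble(metabolite_id = key$metabolite_id,
               p_time = p[rn == "time_f"],
               p_group = p[rn == "group"],
               p_interaction = p[rn == "time_f:group"])
      } else {
        fit <- stats::aov(intensity ~ time_f, data = d)
        p <- summary(fit)[[1]][["Pr(>F)"]][1]
        tibble(metabolite_id = key$metabolite_id,
               p_time = ifelse(is.na(p), 1, p))
      }
    }) |>
    dplyr::bind_rows()
  res |>
    dplyr::mutate(p_time = ifelse(is.na(.data$p_time), 1, .data$p_time),
                  flagged = .data$p_time <= alpha)
}
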