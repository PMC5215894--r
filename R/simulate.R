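#' Ground-truth flux vectors for simulation
#'
#' `protein_like` and `lipid_like` return the corresponding exemplar LP
#' solution (so the truth automatically balances every internal metabolite and
#' respects irreversibility); `random` draws uniform fluxes in `[0, 1]` for
#' irreversible and `[-1, 1]` for reversible reactions. Protein/lipid modes
#' require the network to carry the matching synthesis column.
#'
#' @param net a [flux_network]; for the protein/lipid modes it must contain a
#'   `SYN` column.
#' @param mode `"protein_like"`, `"lipid_like"` or `"random"`.
#' @param seed integer seed (used by `"random"` only).
#' @return named flux vector over the network's reactions.
#' @export
generate_true_flux <- function(net, mode = c("protein_like", "lipid_like", "random"),
                               seed = 1) {
  mode <- match.arg(mode)
  if (mode == "random") {
    set.seed(as.integer(seed))
    rev_ <- net$reactions$reversible
    v <- stats::runif(nrow(net$reactions), min = ifelse(rev_, -1, 0), max = 1)
    return(setNames(v, net$reactions$reaction_id))
  }
  prof <- max_synthesis_profile(net)
  flux_vector(prof)
}

#' Simulation configuration for replicate intensity tables
#'
#' Encodes the study design emulated by the generator: time points 0/15/30
#' minutes, control and compressed groups, 4-5 replicates per cell,
#' per-metabolite baseline intensities spanning decades (lognormal), and
#' multiplicative (CV-based) replicate noise, as LC-MS intensity noise scales
#' with signal.
#'
#' @param net a reduced [flux_network] (with synthesis column when the truth
#'   comes from an exemplar).
#' @param true_flux named list, one flux vector per group (each respecting
#'   irreversibility). Default: zero flux for `control` and the network's
#'   protein exemplar for `compressed`.
#' @param times ordered time points in minutes.
#' @param groups group labels.
#' @param n_replicates replicates per (group, time) cell.
#' @param baseline_meanlog,baseline_sdlog lognormal parameters for the
#'   per-metabolite baseline intensities (default `log(1e4)` and 1).
#' @param noise_cv per-replicate coefficient of variation (default 0.05).
#' @param target_shift fraction of baseline that the median nonzero
#'   per-interval center shift should reach; the true flux is rescaled once to
#'   meet it (default 0.2, a clearly detectable metabolomic shift). Set to
#'   `NULL` to use the flux vectors as given.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(net, true_flux = NULL,
                              times = c(0, 15, 30),
                              groups = c("control", "compressed"),
                              n_replicates = 5,
                              baseline_meanlog = log(1e4), baseline_sdlog = 1,
                              noise_cv = 0.05, target_shift = 0.2, seed = 1) {
  stopifnot(inherits(net, "flux_network"), length(times) >= 2,
            n_replicates >= 2, noise_cv >= 0)
  if (is.null(true_flux)) {
    v <- generate_true_flux(net, "protein_like")
    zero <- setNames(rep(0, length(v)), names(v))
    true_flux <- setNames(list(zero, v), c(groups[1], groups[2]))
  }
  stopifnot(all(groups %in% names(true_flux)))
  rev_ <- setNames(net$reactions$reversible, net$reactions$reaction_id)
  for (g in groups) {
    v <- true_flux[[g]]
    if (any(v[!rev_[names(v)]] < 0)) {
      abort("irreversible reactions must have nonnegative true flux")
    }
  }
  structure(list(net = net, true_flux = true_flux, times = sort(times),
                 groups = groups, n_replicates = n_replicates,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 noise_cv = noise_cv, target_shift = target_shift,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a replicate intensity table with known ground truth
#'
#' For metabolite i at time t the cell center is
#' `baseline_i + sum over elapsed intervals of (S v_group)_i * dt`; replicates
#' are `center * (1 + e)` with `e ~ N(0, noise_cv)`. The true flux is rescaled
#' once (identically for all groups) so the median nonzero per-interval center
#' shift is `target_shift` of the affected metabolite's baseline. Only
#' measurable, unconstrained metabolites are observed. Deterministic given the
#' config seed; the ground truth (scaled fluxes, true accumulation rates,
#' baselines) is returned alongside the table.
#'
#' @param cfg a `sim_config` from [simulation_config()].
#' @return list with `table` (long intensity tibble) and `truth` (list:
#'   `flux` per group, `delta` per group, `baseline`, `scale`).
#' @export
generate_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  net <- cfg$net
  mets <- net$metabolites
  observed <- mets$measurable & !mets$constrained_zero
  ids <- mets$metabolite_id[observed]
  baseline <- setNames(
    stats::rlnorm(length(ids), cfg$baseline_meanlog, cfg$baseline_sdlog), ids)
  S <- net$S[ids, , drop = FALSE]
  dts <- diff(cfg$times)

  sv <- purrr::map(cfg$true_flux[cfg$groups], function(v) {
    drop(S %*% v[colnames(S)])
  })
  scale_factor <- 1
  if (!is.null(cfg$target_shift)) {
    shifts <- abs(unlist(purrr::map(sv, function(x) {
      as.vector(outer(x, dts)) / rep(baseline, length(dts))
    })))
    shifts <- shifts[shifts > 0]
    if (length(shifts)) scale_factor <- cfg$target_shift / stats::median(shifts)
    # feasibility guard: never deplete a pool below 20% of its baseline
    worst <- max(purrr::map_dbl(sv, function(x) {
      cs <- t(apply(outer(x, dts), 1, cumsum))   # cumulative shift per time
      max(0, -sweep(cs, 1, baseline, "/"))
    }))
    if (worst > 0) scale_factor <- min(scale_factor, 0.8 / worst)
  }
  true_flux <- purrr::map(cfg$true_flux[cfg$groups], function(v) v * scale_factor)
  sv <- purrr::map(sv, function(x) x * scale_factor)

  rows <- list()
  for (g in cfg$groups) {
    centers <- baseline
    for (ti in seq_along(cfg$times)) {
      t <- cfg$times[ti]
      if (ti > 1) centers <- centers + sv[[g]] * dts[ti - 1]
      if (any(centers <= .Machine$double.eps)) {
        abort("a simulated center was driven to zero or below; lower the flux scale or raise baselines")
      }
      eps <- matrix(stats::rnorm(length(ids) * cfg$n_replicates, 0, cfg$noise_cv),
                    length(ids), cfg$n_replicates)
      for (r in seq_len(cfg$n_replicates)) {
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = paste0(g, "_t", t, "_r", r),
          group = g, time = t, metabolite_id = ids,
          intensity = centers * (1 + eps[, r]))
      }
    }
  }
  table <- dplyr::bind_rows(rows)
  truth <- list(flux = true_flux,
                delta = sv,
                baseline = baseline,
                scale = scale_factor,
                config = cfg[setdiff(names(cfg), "net")])
  list(table = table, truth = truth)
}

#' Write the packaged small fixtures used across the test-suite
#'
#' Writes deterministic fixtures into `dir`: a 3-metabolite toy network
#' (reaction + metabolite sheets), a 6-sample clustering table, a small BVLS
#' instance with its recorded solution, and a copy of the packaged
#' full-network sheets. Regeneration is byte-identical.
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
fixture_suite <- function(dir = tempfile("fluxmet_fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  writeLines(c(
    "reaction_id\tpathway\treversible\tequation",
    "R1\tG\t0\tA -> B",
    "R2\tG\t1\tB <-> C"), p("toy_reactions.tsv"))
  writeLines(c(
    "metabolite_id\tname\trole\tmeasurable\tetc_member",
    "A\tmet A\texternal\t1\t0",
    "B\tmet B\tinternal\t0\t0",
    "C\tmet C\tinternal\t1\t0"), p("toy_metabolites.tsv"))
  set.seed(73)
  base <- c(m1 = 100, m2 = 50, m3 = 200, m4 = 80)
  samples <- paste0("s", 1:6)
  tab <- tidyr::expand_grid(sample_id = samples, metabolite_id = names(base)) |>
    dplyr::mutate(group = "control", time = 0,
                  intensity = base[.data$metabolite_id] *
                    (1 + round(stats::runif(dplyr::n(), -0.3, 0.3), 3))) |>
    dplyr::select("sample_id", "group", "time", "metabolite_id", "intensity")
  readr::write_csv(tab, p("clustering_table.csv"))
  A <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  b <- c(1, -2, 0.5)
  fit <- bvls_fit(A, b, lower = c(0, -Inf), upper = c(Inf, Inf))
  readr::write_csv(tibble(x = fit$x, objective = fit$objective),
                   p("bvls_instance_solution.csv"))
  for (f in c("network_reactions.tsv", "network_metabolites.tsv")) {
    file.copy(system.file("extdata", f, package = "fluxmet"), p(f),
              overwrite = TRUE)
  }
  invisible(list.files(dir, full.names = TRUE))
}
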