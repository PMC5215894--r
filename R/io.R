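#' Read a replicate intensity table
#'
#' Long format (default): columns `sample_id`, `group`, `time` (or
#' `time_min`), `metabolite_id`, `intensity`, comma- or tab-separated by file
#' extension. Wide format: metabolites x samples with a `metabolite_id` first
#' column, plus a sample metadata sheet mapping `sample_id` to `group` and
#' `time`.
#'
#' @param path CSV/TSV file.
#' @param format `"long"` or `"wide"`.
#' @param metadata for `format = "wide"`, path to (or tibble of) the sample
#'   sheet with columns `sample_id`, `group`, `time`.
#' @return long-format intensity tibble.
#' @export
read_intensity_table <- function(path, format = c("long", "wide"),
                                 metadata = NULL) {
  format <- match.arg(format)
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  raw <- reader(path, show_col_types = FALSE)
  if (format == "long") {
    if ("time_min" %in% names(raw) && !"time" %in% names(raw)) {
      raw <- dplyr::rename(raw, time = "time_min")
    }
    return(check_intensity_table(as_tibble(raw)))
  }
  if (is.null(metadata)) abort("wide format needs a sample metadata sheet")
  meta <- if (is.character(metadata)) {
    mreader <- if (grepl("\\.tsv$", metadata)) readr::read_tsv else readr::read_csv
    mreader(metadata, show_col_types = FALSE)
  } else as_tibble(metadata)
  if ("time_min" %in% names(meta) && !"time" %in% names(meta)) {
    meta <- dplyr::rename(meta, time = "time_min")
  }
  long <- raw |>
    tidyr::pivot_longer(-"metabolite_id", names_to = "sample_id",
                        values_to = "intensity") |>
    dplyr::inner_join(meta, by = "sample_id") |>
    dplyr::select("sample_id", "group", "time", "metabolite_id", "intensity")
  check_intensity_table(long)
}

#' Write a long intensity table
#'
#' @param table long intensity tibble.
#' @param path output CSV path.
#' @export
write_intensity_table <- function(table, path) {
  check_intensity_table(table)
  readr::write_csv(table, path)
  invisible(path)
}

#' Write an accumulation table
#'
#' Columns: `metabolite_id`, `delta`, `variance`, `weight` (12 significant
#' digits).
#'
#' @param acc an `accumulation_tbl`.
#' @param path output CSV path.
#' @export
write_accumulation <- function(acc, path) {
  out <- as_tibble(acc) |>
    dplyr::mutate(dplyr::across(-"metabolite_id", function(x) signif(x, 12)))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read an accumulation table written by [write_accumulation()]
#'
#' @param path CSV path.
#' @return tibble with at least `metabolite_id`, `delta`, `variance`, `weight`.
#' @export
read_accumulation <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a flux table
#'
#' Columns: `reaction_id`, `pathway`, `flux`, `at_bound` (0/1).
#'
#' @param fit a `flux_fit` or `exemplar_profile`.
#' @param path output CSV path.
#' @export
write_flux <- function(fit, path) {
  flux <- tidy(fit)
  if (!"at_bound" %in% names(flux)) {
    flux$at_bound <- !flux$reversible & flux$flux == 0
  }
  out <- flux |>
    dplyr::mutate(flux = signif(.data$flux, 12),
                  at_bound = as.integer(.data$at_bound)) |>
    dplyr::select("reaction_id", "pathway", "flux", "at_bound")
  readr::write_csv(out, path)
  invisible(path)
}

#' Export a stoichiometric matrix as labelled CSV
#'
#' @param net a [flux_network].
#' @param path output CSV path; metabolite ids label rows, reaction ids
#'   columns.
#' @export
write_stoich_matrix <- function(net, path) {
  S <- stoich_matrix(net)
  df <- as_tibble(S, rownames = "metabolite_id")
  readr::write_csv(df, path)
  invisible(path)
}

#' Serialize a network back to its two definition sheets
#'
#' Writes the reaction TSV (equations rebuilt from the stored stoichiometry,
#' `<->` for reversible reactions) and the metabolite TSV. A parse of the
#' written files reproduces the network exactly.
#'
#' @param net a [flux_network].
#' @param reactions_file,metabolites_file output TSV paths.
#' @export
write_network_definition <- function(net, reactions_file, metabolites_file) {
  fmt_side <- function(st) {
    paste(purrr::imap_chr(st, function(coef, met) {
      if (coef == 1) met else paste(format(coef, scientific = FALSE), met)
    }), collapse = " + ")
  }
  eqs <- purrr::map2_chr(net$reactions$stoichiometry, net$reactions$reversible,
    function(st, rev_) {
      lhs <- -st[st < 0]; rhs <- st[st > 0]
      arrow <- if (rev_) "<->" else "->"
      paste(fmt_side(lhs), arrow, fmt_side(rhs))
    })
  readr::write_tsv(
    tibble(reaction_id = net$reactions$reaction_id,
           pathway = net$reactions$pathway,
           reversible = as.integer(net$reactions$reversible),
           equation = eqs),
    reactions_file)
  readr::write_tsv(
    net$metabolites |>
      dplyr::mutate(measurable = as.integer(.data$measurable),
                    etc_member = as.integer(.data$etc_member)) |>
      dplyr::select("metabolite_id", "name", "role", "measurable", "etc_member"),
    metabolites_file)
  invisible(c(reactions_file, metabolites_file))
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are keyed by the first whitespace-delimited token of each
#' header.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("reading FASTA requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Write an hclust tree as Newick text
#'
#' @param h an `hclust` object (or `sample_clustering`/`flux_met_cor` field).
#' @param path output file.
#' @export
write_dendrogram <- function(h, path) {
  if (inherits(h, "sample_clustering")) h <- h$hclust
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("writing Newick trees requires the ape package")
  }
  ape::write.tree(ape::as.phylo(h), file = path)
  invisible(path)
}

#' Run the full flux-inference pipeline
#'
#' Orchestrates the analysis end to end: accumulation and weights per
#' interval, BVLS flux fits, exemplar comparison, sensitivity analysis and
#' sample clustering, writing one CSV per stage plus a JSON manifest with
#' seeds, tolerances and file checksums. Running twice with the same
#' configuration produces identical checksums.
#'
#' @param table long intensity tibble (or path to one).
#' @param net a reduced [flux_network] with a synthesis column.
#' @param out_dir output directory; created, must not already contain a
#'   manifest (outputs are write-once per run directory).
#' @param intervals list of `c(t0, t1)` pairs.
#' @param group group to analyze.
#' @param center `"median"` or `"mean"`.
#' @param hard_zero passed to [assemble_flux_problem()].
#' @param n_sets,seed sensitivity settings.
#' @param anova_alpha screening threshold for the clustering subset.
#' @param linkage clustering linkage.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(table, net, out_dir,
                         intervals = list(c(0, 15), c(15, 30), c(0, 30)),
                         group = "compressed", center = "median",
                         hard_zero = FALSE, n_sets = 100, seed = 1,
                         anova_alpha = 0.15, linkage = "average") {
  if (is.character(table)) table <- read_intensity_table(table)
  check_intensity_table(table)
  stopifnot(inherits(net, "flux_network"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    abort("output directory already holds a manifest; outputs are write-once")
  }
  files <- character(0)
  stages <- list()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, path)
    path
  }

  fits <- list()
  for (k in seq_along(intervals)) {
    iv <- intervals[[k]]
    acc <- estimate_accumulation(table, group, iv[1], iv[2], center = center) |>
      compute_weights()
    emit(sprintf("accumulation_%g_%g.csv", iv[1], iv[2]),
         function(p) write_accumulation(acc, p))
    fit <- solve_flux(assemble_flux_problem(net, acc, hard_zero = hard_zero))
    fits[[k]] <- fit
    emit(sprintf("flux_%g_%g.csv", iv[1], iv[2]),
         function(p) write_flux(fit, p))
    stages[[paste0("interval_", k)]] <- list(
      t0 = iv[1], t1 = iv[2], objective = fit$objective,
      kkt = fit$solver$kkt, iterations = fit$solver$iterations)
  }

  exemplar <- max_synthesis_profile(net)
  emit("exemplar.csv", function(p) write_flux(exemplar, p))
  cmp <- purrr::map(fits, function(f) {
    compare_profiles(f, exemplar)$relative_distance
  })
  stages$exemplar <- list(synthesis_flux = exemplar$synthesis_flux,
                          relative_distance_to_fits = unlist(cmp))

  sens <- sensitivity_run(table, net, intervals, n_sets = n_sets, seed = seed,
                          group = group, center = center, hard_zero = hard_zero)
  emit("sensitivity_correlations.csv",
       function(p) readr::write_csv(sens$correlations, p))
  hist_data <- graphics::hist(sens$correlations$correlation,
                              breaks = seq(-1, 1, by = 0.05), plot = FALSE)
  emit("sensitivity_histogram.csv", function(p) {
    readr::write_csv(tibble(bin_left = head(hist_data$breaks, -1),
                            bin_right = hist_data$breaks[-1],
                            count = hist_data$counts), p)
  })
  stages$sensitivity <- list(n_sets = n_sets, seed = seed,
                             fraction_above = sens$fraction_above,
                             n_skipped = sens$n_skipped)

  screen <- anova_screen(table, alpha = anova_alpha)
  emit("anova_screen.csv", function(p) readr::write_csv(screen, p))
  subset_ids <- screen$metabolite_id[screen$flagged]
  if (length(subset_ids) >= 2L) {
    cl <- cluster_samples(table, subset_ids, linkage = linkage)
    emit("sample_dendrogram.nwk", function(p) write_dendrogram(cl, p))
    stages$clustering <- list(n_flagged = length(subset_ids),
                              leaf_order = cl$order)
  } else {
    stages$clustering <- list(n_flagged = length(subset_ids),
                              note = "fewer than 2 flagged metabolites; clustering skipped")
  }

  manifest <- list(
    package = "fluxmet",
    version = as.character(utils::packageVersion("fluxmet")),
    seed = seed, group = group, center = center, hard_zero = hard_zero,
    intervals = intervals, stages = stages,
    files = lapply(setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
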