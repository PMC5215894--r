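#' Stoichiometric network of central energy metabolism
#'
#' A `flux_network` holds an ordered metabolite table, an ordered reaction
#' table, and the stoichiometric matrix `S` (rows = metabolites, columns =
#' reactions, signed coefficients: negative = consumed, positive = produced).
#' The matrix view is kept consistent with the tables at all times; use
#' [stoich_matrix()] to extract it.
#'
#' @name flux_network
NULL

new_flux_network <- function(metabolites, reactions) {
  S <- matrix(0, nrow(metabolites), nrow(reactions),
              dimnames = list(metabolites$metabolite_id, reactions$reaction_id))
  for (j in seq_len(nrow(reactions))) {
    st <- reactions$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  net <- structure(list(metabolites = metabolites, reactions = reactions, S = S),
                   class = "flux_network")
  validate_flux_network(net)
}

validate_flux_network <- function(net) {
  mets <- net$metabolites; rxns <- net$reactions
  if (anyDuplicated(mets$metabolite_id)) {
    abort("duplicate metabolite id(s) in network")
  }
  if (anyDuplicated(rxns$reaction_id)) {
    abort(paste0("duplicate reaction id: ",
                 rxns$reaction_id[duplicated(rxns$reaction_id)][1]))
  }
  bad_etc <- mets$etc_member & (mets$role != "internal" | mets$measurable)
  if (any(bad_etc)) {
    abort(paste0("ETC carrier must be internal and unmeasurable: ",
                 paste(mets$metabolite_id[bad_etc], collapse = ", ")))
  }
  for (j in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[j]]
    if (!length(st) || all(st == 0)) {
      abort(paste0("reaction ", rxns$reaction_id[j], " has no nonzero coefficient"))
    }
    if (!all(names(st) %in% mets$metabolite_id)) {
      abort(paste0("reaction ", rxns$reaction_id[j],
                   " references unknown metabolite(s)"))
    }
    if (rxns$pathway[j] == "SYN" && any(st > 0)) {
      abort(paste0("synthesis reaction ", rxns$reaction_id[j],
                   " must only consume network metabolites"))
    }
  }
  net
}

parse_equation <- function(eq, known, line = NA_integer_) {
  reversible <- grepl("<->", eq, fixed = TRUE)
  arrow <- if (reversible) "<->" else "->"
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) != 2L) {
    abort(paste0("cannot parse equation", if (!is.na(line)) paste0(" at line ", line),
                 ": ", eq))
  }
  parse_side <- function(side, sign) {
    out <- numeric(0)
    for (term in strsplit(side, "+", fixed = TRUE)[[1]]) {
      term <- trimws(term)
      if (!nzchar(term)) next
      m <- regmatches(term, regexec("^(?:([0-9.]+)[ ]+)?(\\S+)$", term))[[1]]
      coef <- if (is.na(m[2]) || m[2] == "") 1 else as.numeric(m[2])
      met <- m[3]
      if (!met %in% known) {
        abort(paste0("unknown metabolite '", met, "'",
                     if (!is.na(line)) paste0(" at line ", line), " in: ", eq))
      }
      prev <- if (met %in% names(out)) out[[met]] else 0
      out[met] <- prev + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- c(lhs, rhs)
  st <- tapply(st, names(st), sum)
  st <- st[st != 0]
  list(stoichiometry = setNames(as.numeric(st), names(st)), reversible = reversible)
}

#' Parse a network definition from reaction and metabolite sheets
#'
#' Reads the plain-text network definition: a reaction TSV with columns
#' `reaction_id`, `pathway`, `reversible` (0/1), `equation` (e.g.
#' `"2 NADH + O2 -> 2 NAD"`; `"<->"` marks a reversible reaction), and a
#' metabolite TSV with columns `metabolite_id`, `name`, `role`
#' (internal/external), `measurable` (0/1), `etc_member` (0/1).
#'
#' @param reactions_file,metabolites_file paths to the two TSV sheets.
#' @return a [flux_network].
#' @export
parse_network <- function(reactions_file, metabolites_file) {
  mets <- readr::read_tsv(metabolites_file, show_col_types = FALSE,
                          col_types = "cccii")
  rx <- readr::read_tsv(reactions_file, show_col_types = FALSE,
                        col_types = "ccic")
  mets <- mets |>
    dplyr::mutate(measurable = as.logical(.data$measurable),
                  etc_member = as.logical(.data$etc_member),
                  constrained_zero = FALSE, lowest_weight = FALSE)
  if (!all(mets$role %in% c("internal", "external"))) {
    abort("metabolite role must be 'internal' or 'external'")
  }
  parsed <- purrr::imap(rx$equation, function(eq, i) {
    parse_equation(eq, known = mets$metabolite_id, line = i + 1L)
  })
  rx <- rx |>
    dplyr::mutate(
      reversible = as.logical(.data$reversible),
      stoichiometry = purrr::map(parsed, "stoichiometry"))
  arrow_rev <- purrr::map_lgl(parsed, "reversible")
  if (any(arrow_rev != rx$reversible)) {
    bad <- rx$reaction_id[arrow_rev != rx$reversible]
    abort(paste0("reversible flag disagrees with the arrow for: ",
                 paste(bad, collapse = ", ")))
  }
  new_flux_network(mets, rx)
}

#' Load the packaged network of mammalian central energy metabolism
#'
#' The packaged definition covers glycolysis (G1-G10), pyruvate processing
#' (PYP), the TCA cycle (TCA1-TCA10), the pentose phosphate pathway
#' (PPP1-PPP8), the electron transport chain (ETC1-ETC3), anaplerotic
#' reactions (AP1-AP4), and the lactate and glutamate dehydrogenases (LDH,
#' GDH): 52 metabolites by 38 reactions.
#'
#' @return a [flux_network] with 52 metabolites and 38 reactions.
#' @export
#' @examples
#' net <- build_full_network()
#' dim(stoich_matrix(net))
build_full_network <- function() {
  rf <- system.file("extdata", "network_reactions.tsv", package = "fluxmet")
  mf <- system.file("extdata", "network_metabolites.tsv", package = "fluxmet")
  if (!nzchar(rf) || !nzchar(mf)) {
    abort("packaged network definition files are missing; reinstall fluxmet")
  }
  net <- parse_network(rf, mf)
  expected <- c("G", "PYP", "TCA", "PPP", "ETC", "AP", "LDH", "GDH")
  if (!all(expected %in% net$reactions$pathway)) {
    abort("packaged network definition is corrupt: pathway group missing")
  }
  net
}

#' Extract the stoichiometric matrix
#'
#' @param net a [flux_network].
#' @return numeric matrix, rows named by metabolite id, columns by reaction id.
#' @export
stoich_matrix <- function(net) {
  stopifnot(inherits(net, "flux_network"))
  net$S
}

#' Measurable metabolite ids of a network
#'
#' @param net a [flux_network].
#' @return character vector of metabolite ids flagged measurable.
#' @export
measured_metabolites <- function(net) {
  net$metabolites$metabolite_id[net$metabolites$measurable]
}

#' Reduce a network to the measured metabolites
#'
#' Rows for unmeasured *external* metabolites (e.g. glucose, whose medium
#' concentration drowns any cellular change) are removed outright. Rows for
#' unmeasured *internal* metabolites are retained but flagged
#' `constrained_zero`: their accumulation is fixed at 0 so that pathways stay
#' connected. The electron-transport carriers (ubiquinone redox pair and the
#' gradient protons) are additionally flagged `lowest_weight`, so the solver
#' later assigns them the smallest weight among measured metabolites. All
#' reactions are retained; columns only lose the removed rows' entries.
#'
#' @param net a [flux_network].
#' @param measured_ids character vector of measured metabolite ids; defaults
#'   to the network's own `measurable` flags.
#' @return a reduced [flux_network].
#' @export
reduce_to_measured <- function(net, measured_ids = measured_metabolites(net)) {
  stopifnot(inherits(net, "flux_network"))
  if (!length(measured_ids)) abort("measured set is empty")
  unknown <- setdiff(measured_ids, net$metabolites$metabolite_id)
  if (length(unknown)) {
    abort(paste0("measured id(s) absent from the network: ",
                 paste(unknown, collapse = ", ")))
  }
  mets <- net$metabolites |>
    dplyr::mutate(measurable = .data$metabolite_id %in% measured_ids)
  drop <- !mets$measurable & mets$role == "external"
  mets <- mets |>
    dplyr::filter(!drop) |>
    dplyr::mutate(
      constrained_zero = !.data$measurable,
      lowest_weight = .data$etc_member)
  keep_ids <- mets$metabolite_id
  rx <- net$reactions |>
    dplyr::mutate(stoichiometry = purrr::map(.data$stoichiometry, function(st) {
      st[names(st) %in% keep_ids]
    }))
  empty <- purrr::map_int(rx$stoichiometry, length) == 0L
  if (any(empty)) {
    abort(paste0("reduction empties reaction(s): ",
                 paste(rx$reaction_id[empty], collapse = ", ")))
  }
  new_flux_network(mets, rx)
}

#' Append a synthesis reaction as a network column
#'
#' The synthesis column consumes the precursor metabolites (negative
#' coefficients at the precursor rows, zero elsewhere); its product lies
#' outside the network. The column is irreversible and tagged pathway `SYN`.
#'
#' @param net a [flux_network].
#' @param syn a [synthesis_reaction], e.g. from [synthesis_from_sequence()]
#'   or [lipid_synthesis_reaction()].
#' @return a [flux_network] with one extra column.
#' @export
add_synthesis_reaction <- function(net, syn) {
  stopifnot(inherits(net, "flux_network"), inherits(syn, "synthesis_reaction"))
  missing_prec <- setdiff(names(syn$coefficients), net$metabolites$metabolite_id)
  if (length(missing_prec)) {
    abort(paste0("precursor(s) not present in the network: ",
                 paste(missing_prec, collapse = ", "),
                 ". Keep precursor metabolites in the measured set."))
  }
  rid <- paste0("SYN_", syn$product_name)
  rx <- dplyr::bind_rows(
    net$reactions,
    tibble(reaction_id = rid, pathway = "SYN", reversible = FALSE,
           equation = NA_character_,
           stoichiometry = list(-syn$coefficients)))
  new_flux_network(net$metabolites, rx)
}

#' @export
print.flux_network <- function(x, ...) {
  cat("<flux_network> ", nrow(x$metabolites), " metabolites x ",
      nrow(x$reactions), " reactions\n", sep = "")
  tab <- table(x$reactions$pathway)
  cat("  pathways: ", paste(names(tab), tab, sep = ":", collapse = " "), "\n", sep = "")
  n_con <- sum(x$metabolites$constrained_zero)
  if (n_con) cat("  ", n_con, " metabolite row(s) constrained to zero accumulation\n", sep = "")
  invisible(x)
}

#' Tidy a flux network into a long coefficient table
#'
#' @param x a [flux_network].
#' @param ... unused.
#' @return tibble with one row per nonzero stoichiometric coefficient.
#' @export
#' @exportS3Method generics::tidy
tidy.flux_network <- function(x, ...) {
  x$reactions |>
    dplyr::select("reaction_id", "pathway", "reversible", "stoichiometry") |>
    dplyr::mutate(stoichiometry = purrr::map(.data$stoichiometry, function(st) {
      tibble(metabolite_id = names(st), coefficient = as.numeric(st))
    })) |>
    tidyr::unnest("stoichiometry")
}

#' One-row summary of a flux network
#'
#' @param x a [flux_network].
#' @param ... unused.
#' @return tibble with metabolite/reaction counts and the matrix rank.
#' @export
#' @exportS3Method generics::glance
glance.flux_network <- function(x, ...) {
  tibble(
    n_metabolites = nrow(x$metabolites),
    n_reactions = nrow(x$reactions),
    n_measurable = sum(x$metabolites$measurable),
    n_constrained_zero = sum(x$metabolites$constrained_zero),
    rank = qr(x$S)$rank)
}
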