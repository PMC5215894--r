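#' Residue-to-precursor mapping for biosynthesis accounting
#'
#' Maps each amino-acid residue to the central-metabolic precursor(s) its
#' biosynthetic family draws on, restricted to the four precursors tracked by
#' the network: 3-phosphoglycerate (3PG: Ser, Gly, Cys), pyruvate (PYR: Ala,
#' Val, Leu), alpha-ketoglutarate (AKG: Glu, Gln, Pro, Arg) and oxaloacetate
#' (OAA: Asp, Asn, Thr, Met, Lys). Isoleucine has a split origin and is
#' assigned half to pyruvate, half to oxaloacetate. Aromatic residues (Phe,
#' Tyr, Trp) and His have no precursor among the four and are skipped with a
#' logged count.
#'
#' @return named list: one numeric vector of precursor shares per residue.
#' @export
precursor_map <- function() {
  list(
    S = c(`3PG` = 1), G = c(`3PG` = 1), C = c(`3PG` = 1),
    A = c(PYR = 1), V = c(PYR = 1), L = c(PYR = 1),
    I = c(PYR = 0.5, OAA = 0.5),
    E = c(AKG = 1), Q = c(AKG = 1), P = c(AKG = 1), R = c(AKG = 1),
    D = c(OAA = 1), N = c(OAA = 1), T = c(OAA = 1), M = c(OAA = 1),
    K = c(OAA = 1),
    F = NULL, Y = NULL, W = NULL, H = NULL)
}

new_synthesis_reaction <- function(product_name, coefficients, normalization,
                                   n_skipped = 0L) {
  stopifnot(all(coefficients > 0))
  if (normalization == "fraction" &&
      abs(sum(coefficients) - 1) > 1e-12) {
    abort("fraction-normalized coefficients must sum to 1")
  }
  structure(list(product_name = product_name,
                 coefficients = coefficients,
                 normalization = normalization,
                 n_skipped = n_skipped),
            class = "synthesis_reaction")
}

#' Build a protein synthesis reaction from an amino-acid sequence
#'
#' Tallies each residue's precursor demand using [precursor_map()] and
#' normalizes the totals. Under `"fraction"` normalization (the default) the
#' coefficients are the ratiometric share of each precursor and sum to 1;
#' `"per_molecule"` keeps raw residue counts. Only relative proportions affect
#' the shape of a flux profile, and the unit scale keeps the exemplar flux cap
#' of 1 meaningful.
#'
#' @param seq character scalar of one-letter amino-acid codes.
#' @param product_name label for the product (e.g. `"collagen2"`).
#' @param normalization `"fraction"` or `"per_molecule"`.
#' @param mapping residue-to-precursor table, by default [precursor_map()];
#'   supply a replacement to drop in an alternative precursor assignment.
#' @return a `synthesis_reaction`: precursor coefficients, normalization tag,
#'   and the count of skipped residues (those with no precursor among
#'   3PG/PYR/AKG/OAA).
#' @export
#' @examples
#' synthesis_from_sequence("AAA", "tri-alanine")$coefficients  # PYR = 1
#' synthesis_from_sequence("SG", "ser-gly")$coefficients       # 3PG = 1
synthesis_from_sequence <- function(seq, product_name,
                                    normalization = c("fraction", "per_molecule"),
                                    mapping = precursor_map()) {
  normalization <- match.arg(normalization)
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    abort("sequence must be a nonempty character scalar")
  }
  residues <- strsplit(toupper(seq), "")[[1]]
  unknown <- !residues %in% names(mapping)
  if (any(unknown)) {
    abort(paste0("unknown residue code '", residues[which(unknown)[1]],
                 "' at position ", which(unknown)[1]))
  }
  totals <- c(`3PG` = 0, PYR = 0, AKG = 0, OAA = 0)
  n_skipped <- 0L
  for (r in residues) {
    share <- mapping[[r]]
    if (is.null(share)) n_skipped <- n_skipped + 1L
    else totals[names(share)] <- totals[names(share)] + share
  }
  if (all(totals == 0)) {
    abort("no residue maps to a tracked precursor; cannot build a synthesis reaction")
  }
  coef <- totals[totals > 0]
  if (normalization == "fraction") coef <- coef / sum(coef)
  new_synthesis_reaction(product_name, coef, normalization, n_skipped)
}

#' Lipid synthesis reaction (acetyl-CoA precursor)
#'
#' @return a `synthesis_reaction` consuming one unit of acetyl-CoA.
#' @export
lipid_synthesis_reaction <- function() {
  new_synthesis_reaction("lipid", c(ACCOA = 1), "fraction")
}

#' @export
print.synthesis_reaction <- function(x, ...) {
  cat("<synthesis_reaction> ", x$product_name, " (", x$normalization, ")\n", sep = "")
  print(round(x$coefficients, 4))
  if (x$n_skipped > 0) cat("  skipped residues (no tracked precursor):", x$n_skipped, "\n")
  invisible(x)
}

#' Synthesis reactions for the packaged matrix-protein surrogates
#'
#' Reads the packaged FASTA of composition-based synthetic surrogate
#' sequences for type II collagen, type VI collagen, aggrecan and albumin
#' (the real sequences are not distributed; the surrogates reproduce the
#' published amino-acid compositions) and returns one synthesis reaction per
#' product.
#'
#' @param normalization passed to [synthesis_from_sequence()].
#' @return named list of `synthesis_reaction` objects.
#' @export
matrix_protein_synthesis <- function(normalization = "fraction") {
  fa <- system.file("extdata", "matrix_proteins_synthetic.fasta",
                    package = "fluxmet")
  seqs <- read_fasta_sequences(fa)
  purrr::imap(seqs, function(s, nm) {
    synthesis_from_sequence(s, nm, normalization = normalization)
  })
}
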