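make_lp_toy <- function() {
  # branched 5-reaction toy: substrate S feeds A; A splits to B or C; SYN eats B
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  writeLines(c("reaction_id\tpathway\treversible\tequation",
               "R1\tG\t0\tS -> A",
               "R2\tG\t0\tA -> B",
               "R3\tG\t1\tA <-> C",
               "R4\tG\t0\tC -> W",
               "R5\tG\t0\tB -> W"),
             file.path(dir, "rx.tsv"))
  writeLines(c("metabolite_id\tname\trole\tmeasurable\tetc_member",
               "S\ts\texternal\t1\t0",
               "A\ta\tinternal\t1\t0",
               "B\tb\tinternal\t1\t0",
               "C\tc\tinternal\t1\t0",
               "W\tw\texternal\t1\t0"),
             file.path(dir, "rx_met.tsv"))
  parse_network(file.path(dir, "rx.tsv"), file.path(dir, "rx_met.tsv"))
}

test_that("a linear chain saturates the cap and a sourceless precursor gives zero", {
  net <- toy_chain_network()  # S -> A <-> B -> P, A measured
  syn <- structure(list(product_name = "demo", coefficients = c(A = 1),
                        normalization = "fraction", n_skipped = 0L),
                   class = "synthesis_reaction")
  prof <- max_synthesis_profile(add_synthesis_reaction(net, syn))
  expect_equal(prof$synthesis_flux, 1, tolerance = 1e-9)
  v <- setNames(prof$flux$flux, prof$flux$reaction_id)
  expect_equal(unname(v["R1"]), 1, tolerance = 1e-9)

  # precursor with no producing reaction: only feasible synthesis flux is 0
  dir <- withr::local_tempdir()
  writeLines(c("reaction_id\tpathway\treversible\tequation",
               "R1\tG\t0\tA -> B"),
             file.path(dir, "rx.tsv"))
  writeLines(c("metabolite_id\tname\trole\tmeasurable\tetc_member",
               "A\ta\tinternal\t1\t0",
               "B\tb\texternal\t1\t0",
               "O\to\tinternal\t1\t0"),
             file.path(dir, "met.tsv"))
  orphan_net <- parse_network(file.path(dir, "rx.tsv"), file.path(dir, "met.tsv"))
  syn2 <- structure(list(product_name = "orphan", coefficients = c(O = 1),
                         normalization = "fraction", n_skipped = 0L),
                    class = "synthesis_reaction")
  prof2 <- max_synthesis_profile(add_synthesis_reaction(orphan_net, syn2))
  expect_equal(prof2$synthesis_flux, 0, tolerance = 1e-9)
})

test_that("the LP optimum equals brute-force vertex enumeration on the branched toy", {
  net <- make_lp_toy()
  syn <- structure(list(product_name = "demo", coefficients = c(B = 1),
                        normalization = "fraction", n_skipped = 0L),
                   class = "synthesis_reaction")
  net2 <- add_synthesis_reaction(net, syn)
  prof <- max_synthesis_profile(net2, tie_break = FALSE)

  S <- stoich_matrix(net2)
  internal <- net2$metabolites$role == "internal"
  n <- ncol(S)
  cv <- numeric(n); cv[n] <- -1
  lower <- ifelse(net2$reactions$reversible, -1, 0)
  oracle <- lp_vertex_oracle(cv, S[internal, , drop = FALSE], lower, rep(1, n))
  expect_equal(-prof$synthesis_flux, oracle$value, tolerance = 1e-8)
})

test_that("exemplars on the packaged network are feasible and protein-shaped", {
  full <- build_full_network()
  syn <- matrix_protein_synthesis()
  prof <- max_synthesis_profile(add_synthesis_reaction(full, syn$collagen2))
  expect_lt(prof$feasibility$max_balance_violation, 1e-8)
  expect_gt(prof$feasibility$min_irreversible, -1e-9)
  expect_lt(prof$feasibility$max_flux, 1 + 1e-9)
  expect_gt(prof$synthesis_flux, 0)

  feats <- profile_shape_features(prof, full)
  g3pg <- feats$precursor_steps[feats$precursor_steps$precursor == "3PG", ]
  expect_gte(g3pg$upstream_mean, g3pg$downstream_mean)

  zero <- setNames(rep(0, nrow(full$reactions) + 1),
                   c(full$reactions$reaction_id, "SYN_collagen2"))
  feats0 <- profile_shape_features(zero, full)
  expect_true(all(feats0$pathway_totals$total_abs == 0))
})

test_that("doubling the cap at least doubles a cap-limited synthesis flux", {
  full <- build_full_network()
  syn <- matrix_protein_synthesis()
  net2 <- add_synthesis_reaction(full, syn$collagen2)
  p1 <- max_synthesis_profile(net2, cap = 1, tie_break = FALSE)
  p2 <- max_synthesis_profile(net2, cap = 2, tie_break = FALSE)
  expect_gte(p2$synthesis_flux + 1e-9, 2 * p1$synthesis_flux)
})

test_that("protein exemplars cluster together, away from the lipid exemplar", {
  full <- build_full_network()
  syn <- matrix_protein_synthesis()
  profs <- purrr::map(syn, function(s) {
    max_synthesis_profile(add_synthesis_reaction(full, s))$flux$flux[
      seq_len(nrow(full$reactions))]
  })
  lipid <- max_synthesis_profile(
    add_synthesis_reaction(full, lipid_synthesis_reaction()))$flux$flux[
      seq_len(nrow(full$reactions))]
  pp <- utils::combn(names(profs), 2, function(pair) {
    compare_profiles(profs[[pair[1]]], profs[[pair[2]]])$relative_distance
  })
  pl <- purrr::map_dbl(profs, function(v) {
    compare_profiles(v, lipid)$relative_distance
  })
  expect_lt(max(pp), min(pl))
})

test_that("relative distance follows its definition and rejects zero norms", {
  v <- c(A = 1, B = 2, C = -1)
  expect_equal(compare_profiles(v, v)$relative_distance, 0)
  expect_equal(compare_profiles(v, 1.01 * v)$relative_distance, 0.01,
               tolerance = 1e-12)
  set.seed(31)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(compare_profiles(a, b)$relative_distance,
               sqrt(sum((a - b)^2)) / min(sqrt(sum(a^2)), sqrt(sum(b^2))))
  expect_error(compare_profiles(a, rep(0, 5)), "zero-norm")
})
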