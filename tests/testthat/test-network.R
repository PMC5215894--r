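test_that("equation parsing follows the sign and reversibility conventions", {
  net <- toy_chain_network()
  S <- stoich_matrix(net)
  expect_equal(unname(S[c("S", "A"), "R1"]), c(-1, 1))
  expect_equal(unname(S[c("A", "B"), "R2"]), c(-1, 1))
  expect_equal(net$reactions$reversible, c(FALSE, TRUE, FALSE))

  dir <- withr::local_tempdir()
  writeLines(c("reaction_id\tpathway\treversible\tequation",
               "R1\tETC\t0\t2 NADH + O2 -> 2 NAD"),
             file.path(dir, "rx.tsv"))
  writeLines(c("metabolite_id\tname\trole\tmeasurable\tetc_member",
               "NADH\tnadh\tinternal\t1\t0",
               "NAD\tnad\tinternal\t1\t0",
               "O2\toxygen\texternal\t0\t0"),
             file.path(dir, "met.tsv"))
  net2 <- parse_network(file.path(dir, "rx.tsv"), file.path(dir, "met.tsv"))
  S2 <- stoich_matrix(net2)
  expect_equal(unname(S2[c("NADH", "O2", "NAD"), "R1"]), c(-2, -1, 2))
})

test_that("parse errors name the offending line and duplicates are rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("reaction_id\tpathway\treversible\tequation",
               "R1\tG\t0\tA -> ZZZ"),
             file.path(dir, "rx.tsv"))
  writeLines(c("metabolite_id\tname\trole\tmeasurable\tetc_member",
               "A\ta\tinternal\t1\t0"),
             file.path(dir, "met.tsv"))
  expect_error(parse_network(file.path(dir, "rx.tsv"), file.path(dir, "met.tsv")),
               "ZZZ")
  writeLines(c("reaction_id\tpathway\treversible\tequation",
               "R1\tG\t0\tA -> B",
               "R1\tG\t0\tB -> A"),
             file.path(dir, "rx2.tsv"))
  writeLines(c("metabolite_id\tname\trole\tmeasurable\tetc_member",
               "A\ta\tinternal\t1\t0",
               "B\tb\tinternal\t1\t0"),
             file.path(dir, "met2.tsv"))
  expect_error(parse_network(file.path(dir, "rx2.tsv"), file.path(dir, "met2.tsv")),
               "duplicate reaction id")
})

test_that("the packaged full network has the documented shape", {
  net <- build_full_network()
  expect_equal(dim(stoich_matrix(net)), c(52L, 38L))
  expect_setequal(unique(net$reactions$pathway),
                  c("G", "PYP", "TCA", "PPP", "ETC", "AP", "LDH", "GDH"))
  # every ETC reaction touches at least one ETC carrier metabolite
  etc_ids <- net$metabolites$metabolite_id[net$metabolites$etc_member]
  etc_rx <- net$reactions[net$reactions$pathway == "ETC", ]
  touches <- purrr::map_lgl(etc_rx$stoichiometry,
                            function(st) any(names(st) %in% etc_ids))
  expect_true(all(touches))
})

test_that("reduction keeps unmeasured internal rows and drops unmeasured external rows", {
  net <- toy_chain_network()
  red <- reduce_to_measured(net, c("A", "P"))
  expect_setequal(red$metabolites$metabolite_id, c("A", "B", "P"))  # S dropped
  expect_true(red$metabolites$constrained_zero[red$metabolites$metabolite_id == "B"])
  expect_equal(ncol(stoich_matrix(red)), 3L)  # all reactions retained

  # measured set = everything: nothing removed, only flags refreshed
  all_ids <- net$metabolites$metabolite_id
  red_all <- reduce_to_measured(net, all_ids)
  expect_equal(dim(stoich_matrix(red_all)), dim(stoich_matrix(net)))

  expect_error(reduce_to_measured(net, character(0)), "empty")
  expect_error(reduce_to_measured(net, "NOPE"), "absent")
})

test_that("reduction is monotone: never adds rows, never removes columns", {
  net <- build_full_network()
  for (ids in list(measured_metabolites(net),
                   head(measured_metabolites(net), 20))) {
    red <- reduce_to_measured(net, ids)
    expect_lte(nrow(stoich_matrix(red)), nrow(stoich_matrix(net)))
    expect_equal(ncol(stoich_matrix(red)), ncol(stoich_matrix(net)))
  }
})

test_that("packaged reduced reduction with one synthesis column is 48 x 39 with full rank", {
  red <- packaged_reduced_network()
  S <- stoich_matrix(red)
  expect_equal(dim(S), c(48L, 39L))
  expect_equal(qr(S)$rank, 39L)
})

test_that("matrix view matches the reaction list entry by entry", {
  for (net in list(toy_chain_network(), build_full_network())) {
    S <- stoich_matrix(net)
    for (j in seq_len(nrow(net$reactions))) {
      st <- net$reactions$stoichiometry[[j]]
      col <- S[, j]
      expect_equal(col[names(st)], st)
      expect_true(all(col[setdiff(names(col), names(st))] == 0))
    }
  }
})

test_that("serialize -> parse round-trips the packaged network exactly", {
  net <- build_full_network()
  dir <- withr::local_tempdir()
  rf <- file.path(dir, "rx.tsv"); mf <- file.path(dir, "met.tsv")
  write_network_definition(net, rf, mf)
  net2 <- parse_network(rf, mf)
  expect_equal(stoich_matrix(net2), stoich_matrix(net))
  expect_equal(net2$reactions$reversible, net$reactions$reversible)
  expect_equal(net2$metabolites$role, net$metabolites$role)
})

test_that("every non-synthesis column consumes and produces something", {
  # no creation from nothing inside pathways, on both packaged networks
  for (net in list(build_full_network(), packaged_reduced_network())) {
    S <- stoich_matrix(net)
    non_syn <- net$reactions$pathway != "SYN"
    expect_true(all(apply(S[, non_syn, drop = FALSE], 2,
                          function(col) any(col < 0) && any(col > 0))))
  }
})

test_that("adding a synthesis column appends exactly one negative-coefficient column", {
  net <- toy_chain_network()
  syn <- structure(list(product_name = "demo",
                        coefficients = c(A = 0.5, B = 0.5),
                        normalization = "fraction", n_skipped = 0L),
                   class = "synthesis_reaction")
  net2 <- add_synthesis_reaction(net, syn)
  expect_equal(ncol(stoich_matrix(net2)), ncol(stoich_matrix(net)) + 1L)
  col <- stoich_matrix(net2)[, "SYN_demo"]
  expect_equal(col[c("A", "B")], c(A = -0.5, B = -0.5))
  expect_true(all(col[setdiff(names(col), c("A", "B"))] == 0))

  red <- reduce_to_measured(net, c("A", "P"))
  bad <- structure(list(product_name = "bad", coefficients = c(S = 1),
                        normalization = "fraction", n_skipped = 0L),
                   class = "synthesis_reaction")
  expect_error(add_synthesis_reaction(red, bad), "measured")
})
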