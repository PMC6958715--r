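test_that("the three consistency rules are checked as stated", {
  g <- make_graph("A_prot", "+", "B_prot")
  expect_true(is_consistent_labeling(g, c(A_prot = "+", B_prot = "+"),
                                     c(A_prot = "+")))
  # no "-" influence justifies B
  expect_false(is_consistent_labeling(g, c(A_prot = "+", B_prot = "-")))
  # observation must keep its labeling
  expect_false(is_consistent_labeling(g, c(A_prot = "-", B_prot = "-"),
                                      c(A_prot = "+")))
  # zero with a couple of + and - received influences
  g2 <- make_graph("A_prot", "+", "C_prot",
                   "B_prot", "-", "C_prot")
  expect_true(is_consistent_labeling(
    g2, c(A_prot = "+", B_prot = "+", C_prot = "0")))
  # zero with a single non-zero influence is not justified
  expect_false(is_consistent_labeling(
    g2, c(A_prot = "+", B_prot = "0", C_prot = "0")))
  # repaired nodes are exempt from justification, not from observation
  expect_true(is_consistent_labeling(g, c(A_prot = "+", B_prot = "-"),
                                     repaired = "B_prot"))
  expect_false(is_consistent_labeling(g, c(A_prot = "+", B_prot = "-"),
                                      c(B_prot = "+"),
                                      repaired = "B_prot"))
  expect_error(is_consistent_labeling(g, c(A_prot = "+")), "total")
})

test_that("exhaustive enumeration matches hand counts on the toy motifs", {
  # two isolated nodes, no observations: all 9 labelings are consistent
  g0 <- signed_graph(nodes = c("A_prot", "B_prot"))
  expect_equal(nrow(enumerate_consistent(g0)), 9)

  # chain with the source observed: a single labeling survives
  g1 <- make_graph("A_prot", "+", "B_prot", "B_prot", "+", "C_prot")
  M <- enumerate_consistent(g1, c(A_prot = "+"))
  expect_equal(nrow(M), 1)
  expect_equal(M[1, ], c(A_prot = "+", B_prot = "+", C_prot = "+"))

  # two-free-node motif: candidate space is 3^2, filtered by the rules
  fx <- fixture_library()$motif_consistent
  free <- setdiff(fx$graph$nodes$id, names(fx$observations))
  expect_length(free, 2)
  expect_equal(3^length(free), 9)
  M2 <- enumerate_consistent(fx$graph, fx$observations)
  expect_equal(nrow(M2), 1)  # C and D forced
  # the inconsistent variant has no consistent labeling
  fxi <- fixture_library()$motif_inconsistent
  expect_equal(nrow(enumerate_consistent(fxi$graph, fxi$observations)), 0)

  expect_error(enumerate_consistent(random_signed_graph(10, seed = 1)),
               "exhaustive bound")
})

test_that("minimal correction sets are found by increasing cardinality", {
  g <- make_graph("A_prot", "+", "B_prot")
  expect_equal(mcos(g, c(A_prot = "+", B_prot = "+")),
               list(k = 0L, repair_sets = list(character(0))))
  rep1 <- mcos(g, c(A_prot = "+", B_prot = "-"))
  expect_equal(rep1$k, 1)
  expect_true(any(vapply(rep1$repair_sets, identical, logical(1), "B_prot")))
  # every reported set of size k restores satisfiability and no subset does
  for (s in rep1$repair_sets) {
    expect_gt(nrow(enumerate_consistent(g, c(A_prot = "+", B_prot = "-"),
                                        repaired = s)), 0)
  }
})

test_that("predictions on the toy motifs match the brute-force oracle", {
  g <- make_graph("A_prot", "+", "B_prot", "B_prot", "+", "C_prot")
  pv <- prediction_vector(predict_signs(g, c(A_prot = "+")))
  expect_equal(pv, c(B_prot = "+", C_prot = "+"))

  g2 <- make_graph("A_prot", "-", "B_prot")
  expect_equal(prediction_vector(predict_signs(g2, c(A_prot = "+"))),
               c(B_prot = "-"))

  # fork with contradictory influences: C undecided across 3 labelings
  g3 <- make_graph("A_prot", "+", "C_prot", "B_prot", "-", "C_prot")
  obs3 <- c(A_prot = "+", B_prot = "+")
  expect_equal(nrow(enumerate_consistent(g3, obs3)), 3)
  pm3 <- predict_signs(g3, obs3)
  expect_equal(pm3$undecided, "C_prot")
  expect_equal(nrow(pm3$predictions), 0)
})

test_that("the hub-contradiction motif needs one repair and flips the hub", {
  fx <- fixture_library()$hub_contradiction
  pm <- predict_signs(fx$graph, fx$observations)
  expect_equal(pm$mcos$k, 1)
  expect_equal(pm$mcos$repair_sets, list("P_gen"))
  pv <- prediction_vector(pm)
  expect_equal(pv[["HUB_prot"]], "-")
  expect_equal(pv[["P_prot"]], "+")
  # without the conflicting "+" observation no repair is needed and the
  # hub flips to the sign of the remaining observations' consensus
  pm2 <- predict_signs(fx$graph, fx$observations["P_gen"])
  expect_equal(pm2$mcos$k, 0)
  expect_equal(prediction_vector(pm2)[["HUB_prot"]], "+")
})

test_that("production predictions equal exhaustive enumeration on random graphs", {
  set.seed(202)
  for (trial in 1:120) {
    inst <- random_instance(trial)
    op <- oracle_predict(inst$graph, inst$obs)
    if (is.null(op)) {
      expect_gt(mcos(inst$graph, inst$obs)$k, 0)
      next
    }
    pm <- predict_signs(inst$graph, inst$obs)
    expect_equal(pm$mcos$k, 0)
    pv <- prediction_vector(pm)
    unobs <- setdiff(inst$graph$nodes$id, names(inst$obs))
    got <- stats::setNames(rep(NA_character_, length(unobs)), unobs)
    got[names(pv)] <- pv
    expect_equal(got, op[unobs], label = paste("trial", trial))
    expect_setequal(pm$undecided, unobs[is.na(op[unobs])])
  }
})

test_that("every consistent labeling restates the observations", {
  set.seed(77)
  for (trial in 1:25) {
    inst <- random_instance(trial, n_obs = 2)
    M <- enumerate_consistent(inst$graph, inst$obs)
    if (nrow(M) == 0) next
    for (nm in names(inst$obs)) {
      expect_true(all(M[, nm] == inst$obs[[nm]]))
    }
  }
})

test_that("removing an observation never shrinks the consistent set", {
  set.seed(88)
  for (trial in 1:25) {
    inst <- random_instance(trial, n_obs = 3)
    if (length(inst$obs) < 2) next
    full <- enumerate_consistent(inst$graph, inst$obs)
    relaxed <- enumerate_consistent(inst$graph, inst$obs[-1])
    expect_gte(nrow(relaxed), nrow(full))
    if (nrow(full) > 0) {
      key <- function(M) apply(M, 1, paste, collapse = "")
      expect_true(all(key(full) %in% key(relaxed)))
    }
  }
})

test_that("predictions are independent of node declaration order", {
  e <- data.frame(from = c("B_prot", "A_prot", "C_prot"),
                  to = c("C_prot", "B_prot", "D_gen"),
                  sign = c("+", "-", "+"))
  g1 <- signed_graph(e)
  g2 <- signed_graph(e[c(3, 1, 2), ])
  obs <- c(D_gen = "+")
  expect_identical(predict_signs(g1, obs)$predictions,
                   predict_signs(g2, obs)$predictions)
})

test_that("prediction output separates kinds and excludes observed nodes", {
  fx <- fixture_library()$complex_toy
  pm <- predict_signs(fx$graph, fx$observations)
  expect_false(any(names(fx$observations) %in% pm$predictions$node))
  bk <- pm$breakdown
  expect_equal(unname(bk["+", "protein"]), 2)
  expect_equal(unname(bk["+", "complex"]), 1)
  tsv <- tempfile(fileext = ".tsv")
  mj <- tempfile(fileext = ".json")
  write_predictions(pm, tsv, mj)
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), 3)
  expect_equal(jsonlite::read_json(mj)$k, 0)
})
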