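test_that("attractor CPS spans its bounds and averages over cycles", {
  net <- regulatory_network(
    nodes = data.frame(name = c("A", "M1", "M2"),
                       role = c("internal", "marker", "marker")),
    basal = list(disease = c(0, 0, 0)))
  cfg <- scoring_config(
    aspects = c("x", "y"),
    rules = data.frame(aspect = c("x", "x", "y"),
                       marker = c("M1", "M2", "M1"),
                       desired = c(1, 0, 1), weight = c(1, 3, 2)),
    aspect_weights = c(1, 1))
  perfect <- matrix(c(0, 1, 0), 1, dimnames = list(NULL, node_names(net)))
  expect_equal(unname(score_attractor(perfect, cfg, net)), c(1, 1))
  worst <- matrix(c(1, 0, 1), 1, dimnames = list(NULL, node_names(net)))
  expect_equal(unname(score_attractor(worst, cfg, net)), c(0, 0))
  # period-2 attractor with M1 alternating and a rule desiring 1:
  # aspect y scores the time-average 0.5; x mixes weights 1 and 3
  cyc <- matrix(c(0, 1, 0, 0, 0, 0), 2, 3, byrow = TRUE,
                dimnames = list(NULL, node_names(net)))
  sc <- score_attractor(cyc, cfg, net)
  expect_equal(unname(sc[["y"]]), 0.5)
  expect_equal(unname(sc[["x"]]), (1 * 0.5 + 3 * 1) / 4)
  # rules must point at marker nodes; empty aspects are rejected
  expect_error(scoring_config("x", data.frame(
    aspect = "x", marker = "M1", desired = 1, weight = 1)[0, ], 1),
    "no rules")
  bad <- scoring_config("x", data.frame(aspect = "x", marker = "A",
                                        desired = 1, weight = 1), 1)
  expect_error(score_attractor(perfect, bad, net), "not a marker")
})

test_that("landscape score is the basin-weighted CPS combination", {
  fx <- curated_fixtures()$scoring
  ls <- build_landscape(fx$net, "disease", mode = "exhaustive")
  sc <- score_landscape(ls, fx$config, fx$net)
  # designed fixture: half the basin scores (1,1,1), half (0,0,0),
  # weights (6,4,1) -> scalar exactly 5.5
  expect_identical(sc$score, 5.5)
  expect_equal(unname(sc$aspect_cps), c(0.5, 0.5, 0.5))
  # single-attractor landscape: landscape CPS equals the attractor row
  one <- ls
  one$attractors <- ls$attractors[1, ]
  one$attractors$basin_fraction <- 1
  sc1 <- score_landscape(one, fx$config, fx$net)
  expect_equal(unname(sc1$aspect_cps),
               unname(score_attractor(one$attractors$states[[1]],
                                      fx$config, fx$net)))
})

test_that("scoring arithmetic is bounded, permutation-invariant and
           monotone over random landscapes", {
  net <- generate_network(8, density = 0.2, n_markers = 4, seed = 21)
  cfg <- scoring_config(
    aspects = c("a", "b", "c"),
    rules = data.frame(
      aspect = c("a", "a", "b", "c"),
      marker = c("n05", "n06", "n07", "n08"),
      desired = c(1, 0, 1, 0), weight = c(2, 1, 1, 1)),
    aspect_weights = c(6, 4, 1))
  wsum <- sum(cfg$aspect_weights)
  withr::with_seed(99, {
    for (i in seq_len(1000)) {
      ls <- random_landscape(net, n_attractors = sample(2:5, 1))
      sc <- score_landscape(ls, cfg, net)
      expect_gte(sc$score, 0)
      expect_lte(sc$score, wsum)
      # permuting attractor order leaves the score unchanged
      perm <- ls
      ord <- sample(nrow(ls$attractors))
      perm$attractors <- ls$attractors[ord, ]
      expect_equal(score_landscape(perm, cfg, net)$score, sc$score)
      # moving one marker state toward its desired value in one
      # attractor never decreases the score
      k <- sample(nrow(ls$attractors), 1)
      rule <- cfg$rules[sample(nrow(cfg$rules), 1), ]
      up <- ls
      up$attractors$states[[k]][, rule$marker] <- rule$desired
      expect_gte(round(score_landscape(up, cfg, net)$score - sc$score,
                       12), 0)
    }
  })
})

test_that("weight fitting recovers designed weights and reports
           anti-correlation honestly", {
  fx <- curated_fixtures()$scoring
  fit <- fit_weights(fx$profiles, fx$target_rank, fx$net, fx$config,
                     mode = "exhaustive")
  expect_equal(unname(fit$weights), c(6, 4, 1))
  expect_equal(fit$tau, 1)
  # a dominated pair (all-zero CPS vs all-one CPS) orders the same way
  # under every candidate weight vector; asking for the opposite ranking
  # must report tau = -1, not fail silently
  markers <- setdiff(node_names(fx$net), "S")
  q_lo <- mutation_profile("q_lo", perturbation("S", "pin0"))
  q_hi <- mutation_profile("q_hi", dplyr::bind_rows(
    perturbation("S", "pin0"),
    lapply(markers, perturbation, mode = "pin1")))
  rev_fit <- fit_weights(list(q_lo, q_hi), c("q_hi", "q_lo"), fx$net,
                         fx$config, mode = "exhaustive", grid = 0:2)
  expect_equal(rev_fit$tau, -1)
  # correctly ordered, every weight fits: the tie-break returns the
  # smallest-sum, lexicographically first vector
  fit2 <- fit_weights(list(q_lo, q_hi), c("q_lo", "q_hi"), fx$net,
                      fx$config, mode = "exhaustive", grid = 0:2)
  expect_equal(fit2$tau, 1)
  expect_equal(unname(fit2$weights), c(0, 0, 1))
  expect_error(fit_weights(fx$profiles[1], "p1", fx$net, fx$config),
               "at least two")
  expect_error(fit_weights(fx$profiles, c("p1", "p2", "p3", "nope"),
                           fx$net, fx$config), "permutation")
})

test_that("score report TSV carries per-attractor rows plus the landscape
           summary", {
  fx <- curated_fixtures()$scoring
  ls <- build_landscape(fx$net, "disease", mode = "exhaustive")
  sc <- score_landscape(ls, fx$config, fx$net)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_score_tsv(sc, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), nrow(ls$attractors) + 1L)
  expect_equal(tab$normal_like_score[nrow(tab)], 5.5)
})
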