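test_that("greedy extraction returns exactly the relay of a linear chain
           and collapses the target delta", {
  fx <- curated_fixtures()$chain
  m <- extract_motif(fx$net, "disease", fx$config, fx$target,
                     epsilon = 0.1, mode = "exhaustive")
  expect_equal(m$delta0, 1)
  expect_equal(m$members$node, "B")
  expect_equal(m$members$fixed_value, 0)
  expect_lte(m$members$residual_delta[nrow(m$members)], 0.1 * m$delta0)
  expect_equal(m$reason, "suppressed below epsilon")
  # identical inputs give identical member order
  m2 <- extract_motif(fx$net, "disease", fx$config, fx$target,
                      epsilon = 0.1, mode = "exhaustive")
  expect_identical(tidy(m), tidy(m2))
  expect_equal(glance(m)$n_members, 1L)
})

test_that("non-improving and unsuppressible targets terminate with their
           reasons", {
  fx <- curated_fixtures()$chain
  # pin0 on the already-off target does not improve the score
  m <- extract_motif(fx$net, "disease", fx$config,
                     perturbation("A", "pin0"), mode = "exhaustive")
  expect_equal(nrow(m$members), 0L)
  expect_equal(m$reason, "non-improving target")
  # pinning the marker itself: the only other node is disconnected, so
  # no candidate can touch the improvement
  net <- regulatory_network(
    nodes = data.frame(name = c("M", "Z"),
                       role = c("marker", "internal")),
    basal = list(disease = c(-1, -1)))
  cfg <- scoring_config("p", data.frame(aspect = "p", marker = "M",
                                        desired = 1, weight = 1), 1)
  m2 <- extract_motif(net, "disease", cfg, perturbation("M", "pin1"),
                      epsilon = 0, mode = "exhaustive")
  expect_equal(nrow(m2$members), 0L)
  expect_equal(m2$reason, "no suppressor")
  expect_equal(m2$delta0, 1)
  # no candidates at all: exhaustion is reported explicitly
  solo <- regulatory_network(
    nodes = data.frame(name = "M", role = "marker"),
    basal = list(disease = -1))
  m3 <- extract_motif(solo, "disease", cfg, perturbation("M", "pin1"),
                      epsilon = 0, mode = "exhaustive")
  expect_equal(m3$reason, "candidate exhaustion")
})

test_that("activity profiles are basin-weighted convex combinations", {
  fx <- curated_fixtures()$toggle
  ls <- build_landscape(fx$net, "disease", mode = "exhaustive")
  ap <- activity_profile(ls, fx$net)
  # two single-state basins at (1,0)/(0,1) plus the period-2 cycle with
  # both nodes averaging 0.5 over the cycle: every node averages 0.5
  expect_equal(ap$activity, c(0.5, 0.5))
  # convex-combination bound on random landscapes
  net <- generate_network(6, density = 0.3, seed = 13)
  ls2 <- build_landscape(net, "disease", mode = "exhaustive")
  ap2 <- activity_profile(ls2, net)
  expect_true(all(ap2$activity >= 0 & ap2$activity <= 1))
  for (k in seq_len(n_nodes(net))) {
    vals <- vapply(ls2$attractors$states, function(s) mean(s[, k]),
                   numeric(1))
    expect_gte(round(ap2$activity[k] - min(vals), 12), 0)
    expect_lte(round(ap2$activity[k] - max(vals), 12), 0)
  }
})

test_that("motif stability reports frozen nodes turning responsive after
           the reversion perturbation", {
  fx <- curated_fixtures()$frozen
  st <- motif_stability(fx$net, "disease", fx$motif_nodes,
                        fx$perturbation, mode = "exhaustive")
  # the saturated feedback pair is frozen at 1 in disease
  expect_equal(st$activity_baseline, c(1, 1))
  expect_equal(st$class_baseline, c("stable", "stable"))
  # restoring the driver releases the loop: activities move to 0.5
  expect_equal(st$activity_perturbed, c(0.5, 0.5))
  expect_equal(st$class_perturbed, c("responsive", "responsive"))
  # a pinned node always classifies stable at its pin value
  st2 <- motif_stability(pin_node(fx$net, "Q", 1), "disease", "Q",
                         fx$perturbation, mode = "exhaustive")
  expect_equal(st2$activity_baseline, 1)
  expect_equal(st2$activity_perturbed, 1)
  expect_equal(unique(c(st2$class_baseline, st2$class_perturbed)),
               "stable")
})

test_that("motif reports serialize to JSON and TSV", {
  fx <- curated_fixtures()$chain
  m <- extract_motif(fx$net, "disease", fx$config, fx$target,
                     mode = "exhaustive")
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_motif(m, jf, tf)
  back <- jsonlite::fromJSON(jf, simplifyVector = FALSE)
  expect_equal(back$target$node, "A")
  expect_equal(length(back$members), 1L)
  expect_equal(utils::read.delim(tf)$node, "B")
})
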