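test_that("single scan ranks score changes against a shared baseline", {
  # A drives marker M (desired 1); decoy Z has no path to any marker
  net <- regulatory_network(
    nodes = data.frame(name = c("A", "M", "Z"),
                       role = c("internal", "marker", "internal")),
    edges = data.frame(source = "A", target = "M", weight = 2),
    basal = list(normal = c(-1, -1, -1), disease = c(-1, -1, -1)))
  cfg <- scoring_config("p", data.frame(aspect = "p", marker = "M",
                                        desired = 1, weight = 1), 1)
  scan <- single_scan(net, "disease", cfg, modes = c("pin0", "pin1"),
                      mode = "exhaustive")
  expect_s3_class(scan, "bn_scan")
  expect_equal(nrow(scan), 6L)
  # marker-irrelevant node: delta exactly 0 in both modes
  expect_equal(scan$delta[scan$node == "Z"], c(0, 0))
  # pin1 on the direct activator raises the score
  d_a1 <- scan$delta[scan$node == "A" & scan$mode == "pin1"]
  expect_gt(d_a1, 0)
  # deltas recompute from the stored scores and the shared baseline
  expect_equal(scan$delta, scan$score - scan$baseline)
  expect_equal(unique(scan$baseline), attr(scan, "baseline"))
  # results invariant to node enumeration order
  scan_rev <- single_scan(net, "disease", cfg, modes = c("pin0", "pin1"),
                          nodes = c("Z", "M", "A"), mode = "exhaustive")
  expect_equal(as.data.frame(scan), as.data.frame(scan_rev))
  # reversion-target filter keeps strict improvers only (pin1 on the
  # activator or on the marker itself both raise the score)
  expect_equal(reversion_targets(scan)$node, c("A", "M"))
  expect_true(all(reversion_targets(scan)$delta > 0))
})

test_that("restore rows appear only where disease and normal basal differ", {
  fx <- curated_fixtures()$frozen
  scan <- single_scan(fx$net, "disease", fx$config, mode = "exhaustive")
  restored <- scan[scan$mode == "restore", ]
  expect_equal(restored$node, "P")  # only P's basal is disease-shifted
  expect_equal(restored$delta, 0.5)  # exhaustive hand-enumerated value
  # without a normal context restore is skipped with a warning
  no_norm <- regulatory_network(
    nodes = data.frame(name = c("A", "M"),
                       role = c("internal", "marker")),
    edges = data.frame(source = "A", target = "M", weight = 2),
    basal = list(disease = c(1, -1)))
  cfg <- scoring_config("p", data.frame(aspect = "p", marker = "M",
                                        desired = 0, weight = 1), 1)
  expect_warning(
    sc <- single_scan(no_norm, "disease", cfg, mode = "exhaustive"),
    "normal")
  expect_false("restore" %in% sc$mode)
})

test_that("redundant branches are synergistic at tau = 0 in exhaustive
           mode", {
  fx <- curated_fixtures()$redundant
  syn <- double_scan(fx$net, "disease", fx$config,
                     candidates = data.frame(node = c("A", "B"),
                                             mode = "pin0"),
                     tau = 0, mode = "exhaustive")
  expect_equal(syn$classification, "synergistic")
  # either branch alone is buffered by the other; both together release
  # the marker completely
  expect_equal(syn$delta_a, 0)
  expect_equal(syn$delta_b, 0)
  expect_equal(syn$delta_ab, 1)
  expect_gt(syn$delta_ab, (syn$delta_a + syn$delta_b) * (1 + 0))
})

test_that("independent pathways are exactly additive at tau = 0", {
  fx <- curated_fixtures()$independent
  add <- double_scan(fx$net, "disease", fx$config,
                     candidates = data.frame(node = c("A", "B"),
                                             mode = "pin0"),
                     tau = 0, mode = "exhaustive")
  expect_equal(add$classification, "additive")
  expect_identical(add$delta_ab, add$delta_a + add$delta_b)
})

test_that("pair scan picks each candidate's better single mode and
           classifies with the relative band", {
  fx <- curated_fixtures()$redundant
  # character candidates: best mode per node resolved by a single scan
  syn <- double_scan(fx$net, "disease", fx$config,
                     candidates = c("A", "B"), tau = 0,
                     mode = "exhaustive")
  expect_equal(nrow(syn), 1L)
  expect_equal(sort(c(syn$node_a, syn$node_b)), c("A", "B"))
  # antagonistic classification: joint effect below the band
  expect_equal(boolscape:::classify_synergy(0.5, 1, 0.2, "relative"), "antagonistic")
  expect_equal(boolscape:::classify_synergy(1.1, 1, 0.2, "relative"), "additive")
  expect_equal(boolscape:::classify_synergy(1.3, 1, 0.2, "relative"), "synergistic")
  expect_equal(boolscape:::classify_synergy(1.05, 1, 0.1, "absolute"), "additive")
  expect_error(double_scan(fx$net, "disease", fx$config,
                           candidates = "A"), "at least two")
})
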