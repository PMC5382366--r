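test_that("update rule: positive fires, negative silences, zero holds", {
  # zero matrix, zero basal: every state holds
  hold <- regulatory_network(
    nodes = data.frame(name = c("A", "B"), role = "internal"),
    basal = list(disease = c(0, 0)))
  for (s in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))) {
    expect_equal(unname(step_state(hold, s)), s)
  }
  # single node, negative basal, no inputs: 1 -> 0
  neg <- regulatory_network(
    nodes = data.frame(name = "A", role = "internal"),
    basal = list(disease = -1))
  expect_equal(unname(step_state(neg, 1)), 0)
  # 3-node chain: (1,0,0) -> (1,1,0) -> (1,1,1), hand-executed
  ch <- chain3_net()
  s1 <- step_state(ch, c(1, 0, 0))
  expect_equal(unname(s1), c(1, 1, 0))
  expect_equal(unname(step_state(ch, s1)), c(1, 1, 1))
})

test_that("step matches the scalar per-node oracle on every fixture state", {
  fx <- curated_fixtures()
  for (name in names(fx)) {
    net <- fx[[name]]$net
    for (ctx in names(net$basal)) {
      states <- all_states(n_nodes(net))
      for (k in seq_len(nrow(states))) {
        expect_equal(unname(step_state(net, states[k, ], ctx)),
                     oracle_step(net, states[k, ], ctx),
                     info = paste(name, ctx, k))
      }
    }
  }
})

test_that("find_attractor detects points and cycles with transients", {
  fx <- curated_fixtures()
  tog <- fx$toggle$net
  # (1,0) is a fixed point of the mutual-inhibition toggle
  r <- find_attractor(tog, c(1, 0))
  expect_equal(r$attractor$period, 1L)
  expect_equal(r$transient, 0L)
  expect_equal(unname(r$attractor$states[1, ]), c(1, 0))
  # (0,0) <-> (1,1) is the period-2 cycle
  r2 <- find_attractor(tog, c(0, 0))
  expect_equal(r2$attractor$period, 2L)
  # one step maps states[k] to states[(k+1) mod period]
  nxt <- step_state(tog, r2$attractor$states[1, ])
  expect_equal(unname(nxt), unname(r2$attractor$states[2, ]))
  # entering the cycle from either phase yields the same canonical id
  r3 <- find_attractor(tog, c(1, 1))
  expect_identical(r2$attractor$id, r3$attractor$id)
  # transient cap is honoured
  expect_error(find_attractor(chain3_net(), c(1, 0, 0),
                              max_transient = 1L),
               "transient cap")
})

test_that("exhaustive landscapes normalize and respect the state-space cap", {
  net <- two_node_net()
  ls <- build_landscape(net, "disease", mode = "exhaustive")
  expect_equal(sum(ls$attractors$basin_count), ls$total_samples)
  expect_equal(sum(ls$attractors$basin_fraction), 1)
  big <- generate_network(12, density = 0.2, seed = 5)
  expect_error(build_landscape(big, "disease", mode = "exhaustive",
                               exhaustive_cap = 2^10),
               "sampled")
  expect_error(build_landscape(big, "disease", mode = "sampled",
                               n_samples = 10, seed = NULL),
               "seed")
})

test_that("sampled landscapes are deterministic per seed and match the
           exhaustive oracle on a random 10-node network", {
  net <- generate_network(10, density = 0.3, seed = 11)
  ex <- build_landscape(net, "disease", mode = "exhaustive")
  s1 <- build_landscape(net, "disease", mode = "sampled",
                        n_samples = 10000, seed = 7)
  s2 <- build_landscape(net, "disease", mode = "sampled",
                        n_samples = 10000, seed = 7)
  expect_identical(tidy(s1), tidy(s2))
  s3 <- build_landscape(net, "disease", mode = "sampled",
                        n_samples = 10000, seed = 8)
  for (sm in list(s1, s3)) {
    major <- ex$attractors[ex$attractors$basin_fraction >= 0.02, ]
    expect_true(all(major$id %in% sm$attractors$id))
    m <- match(major$id, sm$attractors$id)
    expect_true(all(abs(sm$attractors$basin_fraction[m] -
                          major$basin_fraction) <= 0.03))
  }
})

test_that("pinned nodes stay at their pinned value in every attractor", {
  net <- generate_network(8, density = 0.3, seed = 3)
  pnet <- pin_node(pin_node(net, "n02", 1), "n05", 0)
  ls <- build_landscape(pnet, "disease", mode = "exhaustive")
  for (s in ls$attractors$states) {
    expect_true(all(s[, "n02"] == 1))
    expect_true(all(s[, "n05"] == 0))
  }
  ap <- activity_profile(ls, pnet)
  expect_equal(ap$activity[ap$node == "n02"], 1)
  expect_equal(ap$activity[ap$node == "n05"], 0)
})

test_that("synchronous point attractors are asynchronous fixed points", {
  fx <- curated_fixtures()
  for (name in c("toggle", "frozen", "tumorigenesis")) {
    net <- fx[[name]]$net
    ls <- build_landscape(net, "disease", mode = "exhaustive")
    rep <- check_async(net, ls, "disease", n_traj = 50, seed = 2)
    expect_length(rep$flags, 0)
  }
  # 2-node mutual activation: both all-0 and all-1 fixed points absorb
  # asynchronous trajectories too
  mut <- regulatory_network(
    nodes = data.frame(name = c("A", "B"), role = "internal"),
    edges = data.frame(source = c("A", "B"), target = c("B", "A"),
                       weight = c(2, 2)),
    basal = list(disease = c(-1, -1)))
  ls <- build_landscape(mut, "disease", mode = "exhaustive")
  rep <- check_async(mut, ls, "disease", n_traj = 100, seed = 5)
  expect_equal(rep$n_point_attractors, 2L)
  expect_length(rep$flags, 0)
  expect_equal(rep$async_convergence, 1)
})

test_that("response curves hit their boundary equivalences and are
           monotone on a single activating path", {
  # I -> M, weight +2, basal M = -1: M copies the input with one step lag
  net <- regulatory_network(
    nodes = data.frame(name = c("I", "M"), role = c("input", "marker")),
    edges = data.frame(source = "I", target = "M", weight = 2),
    basal = list(disease = c(0, -1)))
  rc <- response_curves(net, "disease", "I",
                        activity_levels = c(0, 0.25, 0.5, 0.75, 1),
                        n_steps = 300, n_reps = 20, seed = 9)
  ratios <- rc$activation_ratio[rc$marker == "M"]
  # level 0: input silent, marker falls to its autonomous value 0
  expect_equal(ratios[1], 0)
  # level 1: equals the deterministic pin1 landscape marker activity
  pinned <- activity_profile(
    build_landscape(pin_node(net, "I", 1), "disease",
                    mode = "exhaustive"), net)
  expect_equal(ratios[5], pinned$activity[pinned$node == "M"])
  expect_true(all(diff(ratios) >= 0))
  expect_error(response_curves(net, "disease", "M", 0.5), "role input")
})

test_that("landscape export writes JSON and TSV", {
  ls <- build_landscape(two_node_net(), "disease", mode = "exhaustive")
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_landscape(ls, jf, tf)
  back <- jsonlite::fromJSON(jf, simplifyVector = FALSE)
  expect_equal(back$total_samples, ls$total_samples)
  expect_equal(length(back$attractors), nrow(ls$attractors))
  expect_equal(nrow(utils::read.delim(tf)), nrow(ls$attractors))
})
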