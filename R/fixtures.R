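#' Generate a random weighted-sum network
#'
#' Draws a random signed weighted digraph with role annotations and two
#' basal contexts (`"normal"` and `"disease"`) that differ in a random
#' subset of entries.  Same seed, same network.
#'
#' @param n_nodes Number of nodes.
#' @param density Probability of each ordered node pair carrying an edge.
#' @param weights Pool of signed nonzero edge weights (default integer
#'   weights in \[-2, 2\] excluding 0, matching weighted-sum logics
#'   translated from Boolean operators).
#' @param n_inputs,n_markers Number of input / marker role nodes
#'   (`n_inputs + n_markers <= n_nodes`).
#' @param basal_values Pool of basal level values.
#' @param shift_prob Per-entry probability that the disease basal differs
#'   from the normal one.
#' @param self_loops Allow self-edges?
#' @param seed Integer seed (required).
#' @return A validated `bn_network`.
#' @export
generate_network <- function(n_nodes, density = 0.2,
                             weights = c(-2, -1, 1, 2),
                             n_inputs = 1L, n_markers = 2L,
                             basal_values = c(-1, 0, 1),
                             shift_prob = 0.3, self_loops = FALSE,
                             seed) {
  assert_count(n_nodes, "n_nodes")
  assert_count(seed, "seed", min = 0L)
  if (n_inputs + n_markers > n_nodes) {
    abort("n_inputs + n_markers must not exceed n_nodes")
  }
  if (any(weights == 0)) abort("edge weight pool must exclude 0")
  withr::with_seed(seed, {
    nm <- sprintf("n%02d", seq_len(n_nodes))
    roles <- c(rep("input", n_inputs),
               rep("internal", n_nodes - n_inputs - n_markers),
               rep("marker", n_markers))
    pairs <- expand.grid(source = nm, target = nm,
                         stringsAsFactors = FALSE)
    if (!self_loops) pairs <- pairs[pairs$source != pairs$target, ]
    # input nodes receive no edges: their state is set by the environment
    pairs <- pairs[!pairs$target %in% nm[roles == "input"], ]
    keep <- stats::runif(nrow(pairs)) < density
    edges <- NULL
    if (any(keep)) {
      edges <- tibble(
        source = pairs$source[keep], target = pairs$target[keep],
        weight = sample(weights, sum(keep), replace = TRUE)
      )
    }
    normal <- sample(basal_values, n_nodes, replace = TRUE)
    shift <- stats::runif(n_nodes) < shift_prob
    disease <- normal
    disease[shift] <- sample(basal_values, sum(shift), replace = TRUE)
    regulatory_network(
      nodes = tibble(name = nm, role = roles),
      edges = edges,
      basal = list(normal = normal, disease = disease)
    )
  })
}

#' Curated fixture networks
#'
#' Small hand-designed networks, each isolating one mechanism of the
#' analysis pipeline, with exhaustively enumerable state spaces:
#'
#' * `toggle` -- 2-node mutual inhibition (weights -2, basal +1): two
#'   point attractors plus one period-2 cycle; the bistability /
#'   activity-0.5 demonstration.
#' * `redundant` -- two redundant oncogenic branches `A`, `B` jointly
#'   driving marker `M`; either pin alone is buffered, pinning both
#'   releases the marker: the synergy demonstration.
#' * `independent` -- two disjoint pathways to disjoint markers: exactly
#'   additive double perturbation.
#' * `chain` -- target `A` -> relay `B` -> marker `M` plus decoy `Z`:
#'   the greedy motif procedure must return exactly the relay.
#' * `frozen` -- a mutual-activation feedback pair driven to saturation by
#'   a disease basal shift; restoring the driver releases the loop and
#'   moves activities from 1 toward 0.5: the motif-stability
#'   demonstration.
#' * `scoring` -- 12-node three-aspect scoring network: one free switch
#'   node drives eleven markers so the two basin halves carry designed CPS
#'   rows (1,1,1) and (0,0,0); scalar normal-like score under weights
#'   (6,4,1) is exactly 5.5.  Also carries the 4-profile set whose CPS
#'   rows are designed so the minimal integer weights reproducing the
#'   target ranking are exactly (6,4,1).
#' * `tumorigenesis` -- four free switch nodes plus a driven marker; the
#'   shipped sequence pins the switches one by one, halving the attractor
#'   count at every step (16, 8, 4, 2, 1).
#'
#' Each entry is a list with `net` and, where relevant, `config`,
#' `profiles`, `target_rank`, `sequence`, `target`, `motif_nodes`,
#' `perturbation`.
#'
#' @return A named list of fixtures.
#' @export
curated_fixtures <- function() {
  list(
    toggle = fixture_toggle(),
    redundant = fixture_redundant(),
    independent = fixture_independent(),
    chain = fixture_chain(),
    frozen = fixture_frozen(),
    scoring = fixture_scoring(),
    tumorigenesis = fixture_tumorigenesis()
  )
}

one_aspect_config <- function(rules, aspect = "proliferation", weight = 1) {
  scoring_config(aspect, mutate(rules, aspect = aspect), weight)
}

#' @rdname curated_fixtures
#' @export
fixture_toggle <- function() {
  net <- regulatory_network(
    nodes = tibble(name = c("A", "B"), role = c("internal", "marker")),
    edges = tibble(source = c("B", "A"), target = c("A", "B"),
                   weight = c(-2, -2)),
    basal = list(normal = c(1, 1), disease = c(1, 1))
  )
  config <- one_aspect_config(tibble(marker = "B", desired = 0, weight = 1))
  list(net = net, config = config)
}

#' @rdname curated_fixtures
#' @export
fixture_redundant <- function() {
  net <- regulatory_network(
    nodes = tibble(name = c("A", "B", "M"),
                   role = c("internal", "internal", "marker")),
    edges = tibble(source = c("A", "B"), target = c("M", "M"),
                   weight = c(2, 2)),
    basal = list(normal = c(-1, -1, -1), disease = c(1, 1, -1))
  )
  config <- one_aspect_config(tibble(marker = "M", desired = 0, weight = 1))
  list(net = net, config = config)
}

#' @rdname curated_fixtures
#' @export
fixture_independent <- function() {
  net <- regulatory_network(
    nodes = tibble(name = c("A", "B", "M1", "M2"),
                   role = c("internal", "internal", "marker", "marker")),
    edges = tibble(source = c("A", "B"), target = c("M1", "M2"),
                   weight = c(2, 2)),
    basal = list(normal = c(-1, -1, -1, -1), disease = c(1, 1, -1, -1))
  )
  config <- scoring_config(
    aspects = c("proliferation", "EMT"),
    rules = tibble(aspect = c("proliferation", "EMT"),
                   marker = c("M1", "M2"), desired = c(0, 0),
                   weight = c(1, 1)),
    aspect_weights = c(1, 1)
  )
  list(net = net, config = config)
}

#' @rdname curated_fixtures
#' @export
fixture_chain <- function() {
  net <- regulatory_network(
    nodes = tibble(name = c("A", "B", "M", "Z"),
                   role = c("internal", "internal", "marker", "internal")),
    edges = tibble(source = c("A", "B"), target = c("B", "M"),
                   weight = c(2, 2)),
    basal = list(normal = c(-1, -1, -1, -1), disease = c(-1, -1, -1, -1))
  )
  config <- one_aspect_config(tibble(marker = "M", desired = 1, weight = 1))
  list(net = net, config = config, target = perturbation("A", "pin1"))
}

#' @rdname curated_fixtures
#' @export
fixture_frozen <- function() {
  net <- regulatory_network(
    nodes = tibble(name = c("P", "Q", "M"),
                   role = c("internal", "internal", "marker")),
    edges = tibble(source = c("P", "Q", "Q"), target = c("Q", "P", "M"),
                   weight = c(2, 2, 2)),
    basal = list(normal = c(-1, -1, -1), disease = c(3, -1, -1))
  )
  config <- one_aspect_config(tibble(marker = "M", desired = 0, weight = 1))
  list(net = net, config = config, motif_nodes = c("P", "Q"),
       perturbation = perturbation("P", "restore"))
}

#' @rdname curated_fixtures
#' @export
fixture_scoring <- function() {
  markers <- c(paste0("P", 1:4), paste0("E", 1:4), paste0("St", 1:3))
  nm <- c("S", markers)
  net <- regulatory_network(
    nodes = tibble(name = nm,
                   role = c("internal", rep("marker", length(markers)))),
    edges = tibble(source = "S", target = markers, weight = 2),
    basal = list(normal = c(0, rep(-1, length(markers))),
                 disease = c(0, rep(-1, length(markers))))
  )
  config <- scoring_config(
    aspects = c("proliferation", "EMT", "stemness"),
    rules = bind_rows(
      tibble(aspect = "proliferation", marker = paste0("P", 1:4),
             desired = 1, weight = c(5, 1, 4, 10)),
      tibble(aspect = "EMT", marker = paste0("E", 1:4),
             desired = 1, weight = c(6, 4, 3, 7)),
      tibble(aspect = "stemness", marker = paste0("St", 1:3),
             desired = 1, weight = c(1, 2, 2))
    ),
    aspect_weights = c(6, 4, 1)
  )
  # four mutation profiles whose single-attractor CPS rows are
  # (0.30, 0.50, 0.40), (0.50, 0.30, 0.20), (0.30, 0.70, 0.00),
  # (0.25, 0.65, 0.60): the minimal integer weights ordering them as
  # p1 < p2 < p3 < p4 are exactly (6, 4, 1)
  pin1 <- function(nodes) {
    bind_rows(lapply(nodes, perturbation, mode = "pin1"))
  }
  profiles <- list(
    mutation_profile("p1", bind_rows(perturbation("S", "pin0"),
                                     pin1(c("P1", "P2", "E1", "E2",
                                            "St2")))),
    mutation_profile("p2", bind_rows(perturbation("S", "pin0"),
                                     pin1(c("P4", "E1", "St1")))),
    mutation_profile("p3", bind_rows(perturbation("S", "pin0"),
                                     pin1(c("P1", "P2", "E2", "E3",
                                            "E4")))),
    mutation_profile("p4", bind_rows(perturbation("S", "pin0"),
                                     pin1(c("P1", "E1", "E4", "St1",
                                            "St2"))))
  )
  list(net = net, config = config, profiles = profiles,
       target_rank = c("p1", "p2", "p3", "p4"),
       expected_weights = c(6, 4, 1), expected_score = 5.5)
}

#' @rdname curated_fixtures
#' @export
fixture_tumorigenesis <- function() {
  nm <- c(paste0("F", 1:4), "D", "M")
  net <- regulatory_network(
    nodes = tibble(name = nm,
                   role = c(rep("internal", 5), "marker")),
    edges = tibble(source = "D", target = "M", weight = 2),
    basal = list(normal = c(0, 0, 0, 0, -1, -1),
                 disease = c(0, 0, 0, 0, 1, -1))
  )
  config <- one_aspect_config(tibble(marker = "M", desired = 0, weight = 1))
  sequence <- mutation_sequence(
    tibble(node = paste0("F", 4:1), mode = "pin0",
           shift_value = NA_real_),
    label = "tumorigenesis"
  )
  list(net = net, config = config, sequence = sequence)
}
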