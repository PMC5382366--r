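# shared helpers: tiny networks built in code and an update-rule oracle
# that is independent of the package's matrix stepping path

two_node_net <- function() {
  regulatory_network(
    nodes = data.frame(name = c("A", "B"),
                       role = c("internal", "marker")),
    edges = data.frame(source = "A", target = "B", weight = 1),
    basal = list(normal = c(0, 0), disease = c(0, 0))
  )
}

chain3_net <- function() {
  # A -> B -> C, weights +1, basal 0 everywhere
  regulatory_network(
    nodes = data.frame(name = c("A", "B", "C"),
                       role = c("input", "internal", "marker")),
    edges = data.frame(source = c("A", "B"), target = c("B", "C"),
                       weight = c(1, 1)),
    basal = list(normal = c(0, 0, 0), disease = c(0, 0, 0))
  )
}

# scalar, per-node reimplementation of the update rule straight from its
# definition: sign of (sum_j w_ij * v_j + basal_i), zero holds
oracle_step <- function(net, v, context) {
  m <- net$connectivity
  b <- net$basal[[context]]
  out <- numeric(length(v))
  for (i in seq_along(v)) {
    w <- 0
    for (j in seq_along(v)) w <- w + m[i, j] * v[j]
    w <- round(w + b[i], 12)
    out[i] <- if (w > 0) 1 else if (w < 0) 0 else v[i]
  }
  pins <- net$pins
  if (length(pins)) out[match(names(pins), node_names(net))] <- pins
  out
}

all_states <- function(n) {
  m <- matrix(0, 2^n, n)
  for (k in seq_len(n)) m[, k] <- floor((seq_len(2^n) - 1) / 2^(k - 1)) %% 2
  m
}

# synthetic landscape with random attractor states and basins, for
# scoring-arithmetic property tests
random_landscape <- function(net, n_attractors, max_period = 3L) {
  n <- n_nodes(net)
  att <- tibble::tibble(
    id = as.character(seq_len(n_attractors)),
    period = sample(seq_len(max_period), n_attractors, replace = TRUE)
  )
  att$states <- lapply(att$period, function(p) {
    s <- matrix(sample(c(0, 1), p * n, replace = TRUE), p, n)
    colnames(s) <- node_names(net)
    s
  })
  att$basin_count <- as.numeric(sample.int(50, n_attractors,
                                           replace = TRUE))
  att$basin_fraction <- att$basin_count / sum(att$basin_count)
  structure(list(attractors = att, total_samples = sum(att$basin_count),
                 mode = "sampled", seed = NULL, context = "disease",
                 pins = numeric(0)),
            class = "bn_landscape")
}
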