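#' Synchronous weighted-sum Boolean dynamics
#'
#' Each node holds a binary state.  One synchronous step computes the
#' weighted-sum input vector `W = M %*% V + basal` (connectivity times the
#' current state plus the context's basal levels) and sets every node to 1
#' where its weighted sum is positive, to 0 where it is negative, and holds
#' the current state where it is exactly zero.  Weighted sums are rounded to
#' 12 decimals before the sign test so integer-weight networks behave like
#' integer arithmetic.  Pinned nodes are overwritten with their pinned value
#' after the update.
#'
#' @name dynamics
NULL

# powers of two used to encode a binary state vector as one double;
# exact for N <= 53
state_powers <- function(n) 2^(seq_len(n) - 1)

encode_states <- function(states, pow) as.vector(states %*% pow)

decode_state <- function(code, n) {
  v <- numeric(n)
  for (i in seq_len(n)) {
    v[i] <- code %% 2
    code <- (code - v[i]) / 2
  }
  v
}

# advance a whole batch of states (rows) by one synchronous step
step_matrix <- function(states, tconn, basal, pin_idx, pin_vals) {
  w <- states %*% tconn
  w <- w + rep(basal, each = nrow(states))
  w <- round(w, WS_DIGITS)
  nxt <- (w > 0) + (w == 0) * states
  if (length(pin_idx)) {
    nxt[, pin_idx] <- rep(pin_vals, each = nrow(nxt))
  }
  nxt
}

sim_pieces <- function(net, context) {
  check_context(net, context)
  nm <- node_names(net)
  pin_idx <- match(names(net$pins), nm)
  list(
    tconn = t(net$connectivity),
    basal = unname(net$basal[[context]]),
    pin_idx = pin_idx,
    pin_vals = unname(net$pins),
    n = length(nm),
    pow = state_powers(length(nm))
  )
}

as_state <- function(net, state) {
  v <- as.numeric(state)
  if (length(v) != n_nodes(net) || !all(v %in% c(0, 1))) {
    abort("state must be a binary vector with one entry per node")
  }
  names(v) <- node_names(net)
  v
}

#' Advance a network state by one synchronous step
#'
#' @param net A `bn_network` (possibly with pinned nodes).
#' @param state Binary state vector, one entry per node.
#' @param context Basal context to use.
#' @return The next state as a named binary vector.
#' @export
step_state <- function(net, state, context = "disease") {
  p <- sim_pieces(net, context)
  v <- as_state(net, state)
  nxt <- step_matrix(matrix(v, 1L), p$tconn, p$basal, p$pin_idx, p$pin_vals)
  stats::setNames(as.numeric(nxt[1L, ]), node_names(net))
}

canonical_attractor <- function(states_mat, pow, node_nm) {
  codes <- encode_states(states_mat, pow)
  k <- which.min(codes)
  ord <- c(seq(k, length(codes)), if (k > 1L) seq_len(k - 1L))
  states_mat <- states_mat[ord, , drop = FALSE]
  codes <- codes[ord]
  colnames(states_mat) <- node_nm
  list(
    id = paste(format(codes, scientific = FALSE, trim = TRUE),
               collapse = "|"),
    period = length(codes),
    states = states_mat,
    codes = codes
  )
}

# walk a single trajectory from `state` (a plain numeric vector) until a
# state repeats; returns the canonical attractor and the transient length
trace_attractor <- function(state, p, node_nm, max_transient) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path_codes <- numeric(0)
  path_states <- list()
  v <- matrix(state, 1L)
  for (t in seq_len(max_transient + 1L)) {
    code <- encode_states(v, p$pow)
    key <- format(code, scientific = FALSE, trim = TRUE)
    hit <- seen[[key]]
    if (!is.null(hit)) {
      cyc <- seq(hit, length(path_codes))
      mat <- do.call(rbind, path_states[cyc])
      return(list(attractor = canonical_attractor(mat, p$pow, node_nm),
                  transient = hit - 1L))
    }
    seen[[key]] <- length(path_codes) + 1L
    path_codes <- c(path_codes, code)
    path_states[[length(path_codes)]] <- as.numeric(v[1L, ])
    v <- step_matrix(v, p$tconn, p$basal, p$pin_idx, p$pin_vals)
  }
  abort(paste0("transient cap exceeded (", max_transient,
               " steps) without a state revisit"))
}

#' Find the attractor reached from an initial state
#'
#' Iterates the synchronous update recording visited states; on the first
#' revisit the cycle is extracted and canonicalized (rotation starting at
#' the lexicographically smallest state, so identical attractors always
#' receive equal ids).
#'
#' @param net A `bn_network`.
#' @param initial Binary initial state vector.
#' @param context Basal context.
#' @param max_transient Maximum steps before a revisit must occur; exceeding
#'   it raises an error.
#' @return A list with `attractor` (fields `id`, `period`, `states`: a
#'   period x N binary matrix) and `transient` (steps before cycle entry).
#' @export
find_attractor <- function(net, initial, context = "disease",
                           max_transient = 10000L) {
  assert_count(max_transient, "max_transient")
  p <- sim_pieces(net, context)
  v <- as_state(net, initial)
  if (length(p$pin_idx)) v[p$pin_idx] <- p$pin_vals
  trace_attractor(as.numeric(v), p, node_names(net), max_transient)
}

initial_state_matrix <- function(p, mode, n_samples, seed) {
  free <- setdiff(seq_len(p$n), p$pin_idx)
  if (mode == "exhaustive") {
    s <- 2^length(free)
    states <- matrix(0, s, p$n)
    if (length(free)) {
      idx <- seq_len(s) - 1
      for (k in seq_along(free)) {
        states[, free[k]] <- floor(idx / 2^(k - 1)) %% 2
      }
    }
  } else {
    if (is.null(seed)) abort("sampled mode requires a seed")
    states <- withr::with_seed(seed, {
      m <- matrix(0, n_samples, p$n)
      if (length(free)) {
        m[, free] <- sample(c(0, 1), n_samples * length(free),
                            replace = TRUE)
      }
      m
    })
  }
  if (length(p$pin_idx)) {
    states[, p$pin_idx] <- rep(p$pin_vals, each = nrow(states))
  }
  states
}

#' Build an attractor landscape
#'
#' Estimates (or enumerates) the attractor landscape of a network in a
#' context: the set of attractors together with basin-of-attraction counts.
#' In `sampled` mode, `n_samples` initial states are drawn uniformly and
#' independently over the free (unpinned) nodes, a plain Monte-Carlo
#' estimate of basin measure; in `exhaustive` mode all `2^f` free-node
#' states are enumerated (requires `2^f <= exhaustive_cap`).
#'
#' Trajectories are advanced in a single batch; identical states are merged
#' (the dynamics are deterministic) and states already known to lie on an
#' attractor absorb their trajectory's count immediately.  Residual states
#' are resolved by exact single-trajectory cycle detection.
#'
#' @param net A `bn_network`.
#' @param context Basal context.
#' @param mode `"sampled"` or `"exhaustive"`.
#' @param n_samples Number of initial states in sampled mode.
#' @param seed Integer seed; mandatory in sampled mode.
#' @param exhaustive_cap Largest free-state-space size accepted in
#'   exhaustive mode (default 2^20).
#' @param max_transient Transient cap per trajectory.
#' @return A `bn_landscape`: list with `attractors` (tibble: `id`, `period`,
#'   `states` list-column, `basin_count`, `basin_fraction`),
#'   `total_samples`, `mode`, `seed`, `context`, and the pin mask used.
#' @export
build_landscape <- function(net, context = "disease",
                            mode = c("sampled", "exhaustive"),
                            n_samples = 20000L, seed = NULL,
                            exhaustive_cap = 2^20,
                            max_transient = 10000L) {
  mode <- match.arg(mode)
  p <- sim_pieces(net, context)
  n_free <- p$n - length(p$pin_idx)
  if (mode == "exhaustive" && 2^n_free > exhaustive_cap) {
    abort(paste0("exhaustive enumeration needs 2^", n_free,
                 " states, above the cap; use sampled mode"))
  }
  if (mode == "sampled") assert_count(n_samples, "n_samples")
  states <- initial_state_matrix(p, mode, n_samples, seed)
  total <- nrow(states)

  # aggregate duplicate states: counts per unique current state
  codes <- encode_states(states, p$pow)
  first <- !duplicated(codes)
  counts <- as.numeric(table(factor(codes, levels = codes[first])))
  states <- states[first, , drop = FALSE]
  codes <- codes[first]

  known_codes <- numeric(0)   # codes of states known to lie on an attractor
  known_id <- character(0)    # attractor id per known code
  attractors <- list()        # id -> canonical attractor
  basin <- numeric(0)         # id -> absorbed count
  node_nm <- node_names(net)

  absorb <- function(ids, cnt) {
    agg <- rowsum(cnt, ids)
    for (id in rownames(agg)) {
      basin[id] <<- (if (id %in% names(basin)) basin[[id]] else 0) +
        agg[id, 1L]
    }
  }
  register <- function(att) {
    if (!att$id %in% names(attractors)) {
      attractors[[att$id]] <<- att
      known_codes <<- c(known_codes, att$codes)
      known_id <<- c(known_id, rep(att$id, att$period))
    }
  }

  batch_rounds <- 0L
  stall <- 0L
  while (nrow(states) > 0L) {
    hit <- match(codes, known_codes)
    got <- !is.na(hit)
    if (any(got)) {
      absorb(known_id[hit[got]], counts[got])
      states <- states[!got, , drop = FALSE]
      codes <- codes[!got]
      counts <- counts[!got]
      stall <- 0L
      if (nrow(states) == 0L) break
    }
    if (batch_rounds >= max_transient || stall >= 4L) {
      # active set stopped shrinking: remaining distinct states are (or
      # feed) unregistered cycles -- resolve each exactly
      for (k in seq_len(nrow(states))) {
        res <- trace_attractor(as.numeric(states[k, ]), p, node_nm,
                               max_transient)
        register(res$attractor)
        absorb(res$attractor$id, counts[k])
      }
      states <- states[0, , drop = FALSE]
      break
    }
    prev_n <- nrow(states)
    states <- step_matrix(states, p$tconn, p$basal, p$pin_idx, p$pin_vals)
    codes <- encode_states(states, p$pow)
    keep <- !duplicated(codes)
    if (!all(keep)) {
      counts <- as.numeric(rowsum(
        counts, factor(codes, levels = codes[keep])))
      states <- states[keep, , drop = FALSE]
      codes <- codes[keep]
    }
    stall <- if (nrow(states) < prev_n) 0L else stall + 1L
    batch_rounds <- batch_rounds + 1L
  }

  ids <- names(attractors)
  att_tbl <- tibble(
    id = ids,
    period = vapply(attractors, function(a) a$period, integer(1)),
    states = lapply(attractors, function(a) a$states),
    basin_count = unname(vapply(ids, function(id) basin[[id]],
                                numeric(1)))
  ) |>
    mutate(basin_fraction = .data$basin_count / total) |>
    arrange(desc(.data$basin_count), .data$id)

  structure(
    list(attractors = att_tbl, total_samples = total, mode = mode,
         seed = seed, context = context, pins = net$pins),
    class = "bn_landscape"
  )
}

#' @export
print.bn_landscape <- function(x, ...) {
  cat("<bn_landscape> ", nrow(x$attractors), " attractor(s) from ",
      x$total_samples, " ", x$mode, " initial states (context: ",
      x$context, ")\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Check point attractors under asynchronous update
#'
#' Every synchronous point attractor is a fixed point of the node-wise
#' update map and therefore invariant under any update order; this check
#' verifies that directly (a flag would indicate an internal inconsistency)
#' and, in addition, runs random-order asynchronous trajectories (one
#' uniformly chosen node updated per micro-step) from sampled initial
#' states, reporting the fraction that settle into the synchronous
#' point-attractor set.
#'
#' @param net A `bn_network`.
#' @param landscape A `bn_landscape` built for the same network/context.
#' @param context Basal context.
#' @param n_traj Number of asynchronous trajectories.
#' @param n_steps Micro-steps per trajectory (default `50 * N`).
#' @param seed Integer seed.
#' @return A list: `n_point_attractors`, `flags` (synchronous period-1
#'   attractors that are not fixed points; must be empty),
#'   `async_convergence` (fraction of trajectories ending on a synchronous
#'   point attractor), `n_traj`.
#' @export
check_async <- function(net, landscape, context = "disease",
                        n_traj = 200L, n_steps = NULL, seed = 1L) {
  p <- sim_pieces(net, context)
  n_steps <- n_steps %||% (50L * p$n)
  pts <- landscape$attractors |> filter(.data$period == 1L)
  flags <- character(0)
  point_codes <- numeric(0)
  for (k in seq_len(nrow(pts))) {
    s <- pts$states[[k]][1L, ]
    nxt <- step_matrix(matrix(s, 1L), p$tconn, p$basal, p$pin_idx,
                       p$pin_vals)
    if (!all(nxt[1L, ] == s)) flags <- c(flags, pts$id[k])
    point_codes <- c(point_codes, encode_states(matrix(s, 1L), p$pow))
  }
  converged <- 0L
  if (n_traj > 0L) {
    withr::with_seed(seed, {
      for (r in seq_len(n_traj)) {
        v <- initial_state_matrix(p, "sampled", 1L,
                                  seed = sample.int(2^30, 1L))[1L, ]
        order_nodes <- sample(p$n, n_steps, replace = TRUE)
        for (i in order_nodes) {
          if (i %in% p$pin_idx) next
          w <- round(sum(p$tconn[, i] * v) + p$basal[i], WS_DIGITS)
          v[i] <- if (w > 0) 1 else if (w < 0) 0 else v[i]
        }
        code <- encode_states(matrix(v, 1L), p$pow)
        if (code %in% point_codes) converged <- converged + 1L
      }
    })
  }
  list(
    n_point_attractors = nrow(pts),
    flags = flags,
    async_convergence = if (n_traj > 0L) converged / n_traj else NA_real_,
    n_traj = n_traj
  )
}

#' Input-output response curves under stochastic input activity
#'
#' Sweeps the stochastic activity level of one input node: at every step of
#' every trajectory the input's state is drawn independently as 1 with the
#' given probability, all other nodes follow the synchronous weighted-sum
#' rule, and each marker's activation ratio is its time-average over the
#' post-transient window (second half of the trajectory), averaged over
#' `n_reps` trajectories.
#'
#' @param net A `bn_network`.
#' @param context Basal context.
#' @param input_node An input-role node.
#' @param activity_levels Probabilities in \[0, 1\].
#' @param n_steps Steps per trajectory.
#' @param n_reps Trajectories per level.
#' @param seed Integer seed.
#' @return A tibble with columns `input`, `activity_level`, `marker`,
#'   `activation_ratio`.
#' @export
response_curves <- function(net, context = "disease", input_node,
                            activity_levels = seq(0, 1, by = 0.25),
                            n_steps = 200L, n_reps = 20L, seed = 1L) {
  check_node(net, input_node)
  if (!input_node %in% nodes_with_role(net, "input")) {
    abort(paste0(input_node, " does not have role input"))
  }
  if (any(activity_levels < 0 | activity_levels > 1)) {
    abort("activity levels must lie in [0, 1]")
  }
  p <- sim_pieces(net, context)
  i_in <- match(input_node, node_names(net))
  markers <- nodes_with_role(net, "marker")
  i_mk <- match(markers, node_names(net))
  window <- seq(floor(n_steps / 2) + 1L, n_steps)

  res <- withr::with_seed(seed, {
    purrr::map(activity_levels, function(lvl) {
      acc <- numeric(length(markers))
      for (r in seq_len(n_reps)) {
        v <- initial_state_matrix(p, "sampled", 1L,
                                  seed = sample.int(2^30, 1L))[1L, ]
        v[i_in] <- as.numeric(stats::runif(1) < lvl)
        tot <- numeric(length(markers))
        draws <- as.numeric(stats::runif(n_steps) < lvl)
        for (t in seq_len(n_steps)) {
          v <- step_matrix(matrix(v, 1L), p$tconn, p$basal, p$pin_idx,
                           p$pin_vals)[1L, ]
          v[i_in] <- draws[t]
          if (t >= window[1L]) tot <- tot + v[i_mk]
        }
        acc <- acc + tot / length(window)
      }
      tibble(input = input_node, activity_level = lvl, marker = markers,
             activation_ratio = unname(acc) / n_reps)
    })
  })
  bind_rows(res)
}

#' Export a landscape to JSON and TSV
#'
#' JSON carries the full attractor set (states as bitstrings in node
#' order), the TSV one summary row per attractor.
#'
#' @param landscape A `bn_landscape`.
#' @param json_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the landscape.
#' @export
write_landscape <- function(landscape, json_path = NULL, tsv_path = NULL) {
  att <- landscape$attractors
  if (!is.null(json_path)) {
    obj <- list(
      attractors = lapply(seq_len(nrow(att)), function(k) {
        list(
          states = apply(att$states[[k]], 1L,
                         function(s) paste(s, collapse = "")),
          period = att$period[k],
          basin_count = att$basin_count[k]
        )
      }),
      total_samples = landscape$total_samples,
      mode = landscape$mode,
      context = landscape$context,
      seed = landscape$seed
    )
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(tidy(landscape), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(landscape)
}
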