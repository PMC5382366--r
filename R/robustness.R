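#' Define a sequence of accumulating mutations
#'
#' An ordered list of node-state fixations (or basal shifts); prefix `k`
#' of the sequence defines the cumulative mutation profile after the
#' k-th accumulation step.
#'
#' @param perturbations Data frame of perturbation rows (modes `pin0`,
#'   `pin1` or `basal_shift`); no node may appear twice.
#' @param label Sequence label (e.g. `"tumorigenesis"`, `"reversed"`,
#'   `"random"`).
#' @param seed Optional seed recorded for randomly generated sequences.
#' @return A `bn_sequence`.
#' @export
mutation_sequence <- function(perturbations, label = "sequence",
                              seed = NULL) {
  pert <- as_tibble(perturbations)
  if (nrow(pert)) {
    if (!all(pert$mode %in% c("pin0", "pin1", "basal_shift"))) {
      abort("sequence modes are limited to pin0, pin1 and basal_shift")
    }
    if (anyDuplicated(pert$node)) {
      abort(paste0("node mutated twice in sequence: ",
                   pert$node[duplicated(pert$node)][1]))
    }
  }
  if (!"shift_value" %in% names(pert)) pert$shift_value <- NA_real_
  structure(list(perturbations = pert, label = label, seed = seed),
            class = "bn_sequence")
}

#' @export
print.bn_sequence <- function(x, ...) {
  cat("<bn_sequence> ", x$label, ": ", nrow(x$perturbations),
      " step(s)\n", sep = "")
  invisible(x)
}

#' Reverse a mutation sequence
#' @param sequence A `bn_sequence`.
#' @return The same sequence with steps in reverse order, label suffixed
#'   `"-reversed"`.
#' @export
reverse_sequence <- function(sequence) {
  mutation_sequence(sequence$perturbations[rev(seq_len(
    nrow(sequence$perturbations))), ],
    label = paste0(sequence$label, "-reversed"), seed = sequence$seed)
}

top5_mean_basin <- function(landscape) {
  b <- sort(landscape$attractors$basin_fraction, decreasing = TRUE)
  mean(utils::head(b, 5L))
}

#' Landscape robustness along an accumulating mutation sequence
#'
#' For every prefix of the sequence (including the empty prefix, step 0)
#' the landscape is rebuilt and three robustness metrics are recorded: the
#' number of attractors, the mean basin fraction of the five largest
#' attractors (fewer if the landscape has fewer, flagged in
#' `fewer_than_five`), and the normal-like score.  Few attractors with
#' large major basins mark a landscape that is robust to external signals.
#'
#' @param net A `bn_network`.
#' @param context Basal context.
#' @param sequence A `bn_sequence`.
#' @param config A `bn_scoring_config`.
#' @param mode,n_samples,seed Landscape simulation parameters.
#' @return A `bn_trajectory` tibble: columns `step`, `mutation` (node or
#'   `NA` at step 0), `pin_mode`, `n_attractors`, `top5_mean_basin`,
#'   `fewer_than_five`, `score`, plus the sequence label.
#' @export
robustness_trajectory <- function(net, context = "disease", sequence,
                                  config,
                                  mode = c("sampled", "exhaustive"),
                                  n_samples = 20000L, seed = NULL) {
  mode <- match.arg(mode)
  pert <- sequence$perturbations
  cur <- net
  rows <- vector("list", nrow(pert) + 1L)
  for (k in 0:nrow(pert)) {
    if (k > 0L) {
      cur <- apply_one_perturbation(cur, pert$node[k], pert$mode[k],
                                    pert$shift_value[k], context)
    }
    ls <- tryCatch(
      build_landscape(cur, context, mode = mode, n_samples = n_samples,
                      seed = seed),
      error = function(e) {
        abort(paste0("landscape failed at accumulation step ", k, ": ",
                     conditionMessage(e)))
      }
    )
    sc <- score_landscape(ls, config, net)$score
    rows[[k + 1L]] <- tibble(
      label = sequence$label,
      step = k,
      mutation = if (k > 0L) pert$node[k] else NA_character_,
      pin_mode = if (k > 0L) pert$mode[k] else NA_character_,
      n_attractors = nrow(ls$attractors),
      top5_mean_basin = top5_mean_basin(ls),
      fewer_than_five = nrow(ls$attractors) < 5L,
      score = sc
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("bn_trajectory", class(out))
  out
}

#' Ensemble of random mutation-sequence trajectories
#'
#' Draws `n_sequences` random node orders (uniform, without replacement)
#' and tracks a robustness trajectory for each.  Under the `"random"` rule
#' each mutation's pin value is a fair coin; under `"score-decreasing"`
#' each node's pin value (0 vs 1) is chosen greedily as the one that
#' lowers the normal-like score of the cumulative landscape more (ties
#' pin to 0).
#'
#' @param net A `bn_network`.
#' @param context Basal context.
#' @param config A `bn_scoring_config`.
#' @param n_sequences Number of random sequences.
#' @param length Mutations per sequence (at most the number of nodes).
#' @param seed Master seed; each sequence derives its own.
#' @param rule `"random"` or `"score-decreasing"`.
#' @param mode,n_samples,sim_seed Landscape simulation parameters.
#' @return A `bn_trajectory` tibble of all trajectories, distinguished by
#'   `sequence_id`; the generated sequences are in `attr(, "sequences")`.
#' @export
sequence_ensemble <- function(net, context = "disease", config,
                              n_sequences = 30L, length = 5L, seed = 1L,
                              rule = c("random", "score-decreasing"),
                              mode = c("sampled", "exhaustive"),
                              n_samples = 20000L, sim_seed = NULL) {
  rule <- match.arg(rule)
  mode <- match.arg(mode)
  assert_count(n_sequences, "n_sequences")
  assert_count(length, "length", min = 0L)
  if (length > n_nodes(net)) {
    abort("sequence length cannot exceed the number of nodes")
  }

  sequences <- vector("list", n_sequences)
  trajectories <- vector("list", n_sequences)
  for (q in seq_len(n_sequences)) {
    sseed <- derive_seed(seed, q)
    order_nodes <- withr::with_seed(
      sseed, sample(node_names(net), length))
    if (rule == "random") {
      vals <- withr::with_seed(derive_seed(sseed, 1L),
                               sample(c(0, 1), length, replace = TRUE))
      modes <- ifelse(vals == 1, "pin1", "pin0")
    } else {
      # greedy: per step pick the pin value lowering the score more
      modes <- character(length)
      cur <- net
      for (k in seq_len(length)) {
        sc <- vapply(c("pin0", "pin1"), function(m) {
          pnet <- apply_one_perturbation(cur, order_nodes[k], m, NA_real_,
                                         context)
          ls <- build_landscape(pnet, context, mode = mode,
                                n_samples = n_samples, seed = sim_seed)
          score_landscape(ls, config, net)$score
        }, numeric(1))
        modes[k] <- if (sc[["pin0"]] <= sc[["pin1"]]) "pin0" else "pin1"
        cur <- apply_one_perturbation(cur, order_nodes[k], modes[k],
                                      NA_real_, context)
      }
    }
    seq_k <- mutation_sequence(
      tibble(node = order_nodes, mode = modes, shift_value = NA_real_),
      label = paste0(rule, "-", q), seed = sseed)
    sequences[[q]] <- seq_k
    trajectories[[q]] <- robustness_trajectory(
      net, context, seq_k, config, mode = mode, n_samples = n_samples,
      seed = sim_seed) |>
      mutate(sequence_id = q, .before = 1L)
  }
  out <- bind_rows(trajectories)
  attr(out, "sequences") <- sequences
  class(out) <- c("bn_trajectory", class(out))
  out
}

#' Write a robustness trajectory as TSV
#'
#' One row per accumulation step: step, attractor count, mean basin of the
#' five major attractors, normal-like score.
#'
#' @param trajectory A `bn_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  utils::write.table(as.data.frame(trajectory), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
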