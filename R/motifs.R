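#' Greedy extraction of a functional network motif
#'
#' A functional motif is the minimal node set whose state fixation
#' suppresses a reversion target's score improvement -- a functional unit
#' of reversion, not a topological subgraph.  Starting from a reversion
#' target `A` with a positive score increase, the procedure repeatedly
#' fixes each remaining candidate node to 0 and to 1, recomputes the
#' target's score increase with the accumulated fixed set in place (both
#' the baseline and the perturbed landscape carry the fixed set), and
#' appends the (node, value) that most decreases the increase.  It stops
#' when the residual increase falls to `epsilon` times the original, or no
#' candidate reduces it further.  Ties break deterministically: smaller
#' residual, then node name, then fixed value 0 before 1.
#'
#' @param net A `bn_network`.
#' @param context Basal context.
#' @param config A `bn_scoring_config`.
#' @param target A perturbation row (see [perturbation()]) naming the
#'   reversion target and its mode.
#' @param epsilon Stop threshold as a fraction of the original increase
#'   (default 0.1).
#' @param mode,n_samples,seed Landscape simulation parameters.
#' @return A `bn_motif`: list with `target`, `delta0` (original increase),
#'   `members` (tibble `node`, `fixed_value`, `residual_delta`), and
#'   `reason` (termination reason).
#' @export
extract_motif <- function(net, context = "disease", config, target,
                          epsilon = 0.1,
                          mode = c("sampled", "exhaustive"),
                          n_samples = 20000L, seed = NULL) {
  mode <- match.arg(mode)
  target <- as_tibble(target)
  check_node(net, target$node[1])

  target_delta <- function(fixed_net) {
    base_ls <- build_landscape(fixed_net, context, mode = mode,
                               n_samples = n_samples, seed = seed)
    base <- score_landscape(base_ls, config, net)$score
    pnet <- apply_one_perturbation(fixed_net, target$node[1],
                                   target$mode[1], target$shift_value[1],
                                   context)
    ls <- build_landscape(pnet, context, mode = mode,
                          n_samples = n_samples, seed = seed)
    score_landscape(ls, config, net)$score - base
  }

  delta0 <- target_delta(net)
  members <- tibble(node = character(), fixed_value = numeric(),
                    residual_delta = numeric())
  if (delta0 <= 0) {
    return(structure(list(target = target, delta0 = delta0,
                          members = members,
                          reason = "non-improving target"),
                     class = "bn_motif"))
  }

  fixed_net <- net
  current <- delta0
  reason <- NULL
  repeat {
    if (current <= epsilon * delta0) {
      reason <- "suppressed below epsilon"
      break
    }
    cands <- setdiff(free_nodes(fixed_net), target$node[1])
    if (!length(cands)) {
      reason <- "candidate exhaustion"
      break
    }
    trial <- tidyr::expand_grid(node = sort(cands), value = c(0, 1))
    trial$delta <- purrr::map2_dbl(trial$node, trial$value, function(n, v) {
      target_delta(pin_node(fixed_net, n, v))
    })
    trial <- trial |> arrange(.data$delta, .data$node, .data$value)
    best <- trial[1L, ]
    if (best$delta >= current) {
      reason <- "no suppressor"
      break
    }
    fixed_net <- pin_node(fixed_net, best$node, best$value)
    current <- best$delta
    members <- bind_rows(members,
                         tibble(node = best$node, fixed_value = best$value,
                                residual_delta = best$delta))
  }
  structure(list(target = target, delta0 = delta0, members = members,
                 reason = reason),
            class = "bn_motif")
}

#' @export
print.bn_motif <- function(x, ...) {
  cat("<bn_motif> target ", x$target$node[1], " (", x$target$mode[1],
      "), original delta ", format(x$delta0, digits = 4), "\n", sep = "")
  if (nrow(x$members)) {
    cat("  members:",
        paste0(x$members$node, "=", x$members$fixed_value,
               collapse = " -> "), "\n")
  }
  cat("  stopped:", x$reason, "\n")
  invisible(x)
}

#' Basin-weighted node activity profile of a landscape
#'
#' For every node, the activity is the basin-fraction-weighted mean of its
#' state over each attractor's cycle states.  Activities near 0 or 1 mark
#' nodes robustly frozen across the landscape; activities near 0.5 mark
#' nodes that respond to the choice of initial state.  A pinned node's
#' activity is exactly its pinned value.
#'
#' @param landscape A `bn_landscape`.
#' @param net The corresponding `bn_network`.
#' @param condition Label attached to the profile (e.g. `"disease"`).
#' @return A tibble with columns `node`, `activity`, `condition`.
#' @export
activity_profile <- function(landscape, net, condition = "disease") {
  att <- landscape$attractors
  act <- Reduce(`+`, lapply(seq_len(nrow(att)), function(k) {
    att$basin_fraction[k] * colMeans(att$states[[k]])
  }))
  tibble(node = node_names(net), activity = as.numeric(act),
         condition = condition)
}

classify_stability <- function(activity, stable_band = 0.1,
                               responsive_band = c(0.4, 0.6)) {
  dplyr::case_when(
    activity <= stable_band | activity >= 1 - stable_band ~ "stable",
    activity >= responsive_band[1] & activity <= responsive_band[2] ~
      "responsive",
    TRUE ~ "intermediate"
  )
}

#' Motif stability under a reversion perturbation
#'
#' Compares the basin-weighted activity of each motif node between the
#' unperturbed landscape and the landscape after applying a reversion
#' perturbation.  Nodes frozen to 0/1 in the unperturbed condition that
#' move toward 0.5 after the perturbation mark a motif whose robustness the
#' target releases.
#'
#' @param net A `bn_network`.
#' @param context Basal context.
#' @param motifs A character vector of motif node names, a `bn_motif`, or
#'   a named list of either (multiple motifs).
#' @param perturbation A perturbation row to apply (see [perturbation()]).
#' @param mode,n_samples,seed Landscape simulation parameters.
#' @param stable_band Activities within this distance of 0 or 1 are
#'   `stable`.
#' @param responsive_band Activities inside this interval are `responsive`;
#'   everything else is `intermediate`.
#' @return A tibble with columns `motif`, `node`, `activity_baseline`,
#'   `activity_perturbed`, `class_baseline`, `class_perturbed`.
#' @export
motif_stability <- function(net, context = "disease", motifs, perturbation,
                            mode = c("sampled", "exhaustive"),
                            n_samples = 20000L, seed = NULL,
                            stable_band = 0.1,
                            responsive_band = c(0.4, 0.6)) {
  mode <- match.arg(mode)
  as_members <- function(m) {
    if (inherits(m, "bn_motif")) unique(c(m$target$node, m$members$node))
    else as.character(m)
  }
  if (inherits(motifs, "bn_motif") || is.character(motifs)) {
    motifs <- list(motif_1 = motifs)
  }
  if (is.null(names(motifs))) {
    names(motifs) <- paste0("motif_", seq_along(motifs))
  }

  pert <- as_tibble(perturbation)
  base_ls <- build_landscape(net, context, mode = mode,
                             n_samples = n_samples, seed = seed)
  pnet <- apply_one_perturbation(net, pert$node[1], pert$mode[1],
                                 pert$shift_value[1], context)
  pert_ls <- build_landscape(pnet, context, mode = mode,
                             n_samples = n_samples, seed = seed)
  act_base <- activity_profile(base_ls, net, "baseline")
  act_pert <- activity_profile(pert_ls, net, "perturbed")

  bind_rows(imap(motifs, function(m, label) {
    nodes <- as_members(m)
    for (nd in nodes) check_node(net, nd)
    tibble(
      motif = label,
      node = nodes,
      activity_baseline = act_base$activity[match(nodes, act_base$node)],
      activity_perturbed = act_pert$activity[match(nodes, act_pert$node)]
    )
  })) |>
    mutate(
      class_baseline = classify_stability(.data$activity_baseline,
                                          stable_band, responsive_band),
      class_perturbed = classify_stability(.data$activity_perturbed,
                                           stable_band, responsive_band)
    )
}

#' Write a motif result as JSON and its members as TSV
#' @param motif A `bn_motif`.
#' @param json_path,tsv_path Output paths (either may be `NULL`).
#' @return Invisibly, the motif.
#' @export
write_motif <- function(motif, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(
      target = as.list(motif$target[1, c("node", "mode")]),
      delta0 = motif$delta0,
      members = lapply(seq_len(nrow(motif$members)), function(k) {
        as.list(motif$members[k, ])
      }),
      reason = motif$reason
    )
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(motif$members, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(motif)
}
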