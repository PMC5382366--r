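#' Systematic single-node perturbation scan
#'
#' Perturbs every node (or a chosen subset) under each requested mode,
#' rebuilds and rescores the attractor landscape, and reports the change in
#' normal-like score against a baseline landscape computed once per scan
#' (same mode, samples and seed).  Nodes whose perturbation raises the
#' score are candidate reversion targets; use [reversion_targets()] to
#' filter them.
#'
#' `restore` rows are only generated where the node's basal level in the
#' active context differs from its `"normal"` value (restoring an
#' unchanged node is the identity); if the network lacks a `"normal"`
#' context, restore is skipped with a warning.
#'
#' @param net A `bn_network`.
#' @param context Basal context.
#' @param config A `bn_scoring_config`.
#' @param modes Subset of `c("pin0", "pin1", "restore")`.
#' @param nodes Nodes to scan (default: all).
#' @param mode,n_samples,seed Landscape simulation parameters.
#' @return A `bn_scan` tibble, one row per (node, mode), sorted by
#'   decreasing `delta`, with columns `node`, `mode`, `baseline`, `score`,
#'   `delta`, `n_attractors`.  The baseline score is stored in
#'   `attr(, "baseline")`.
#' @export
single_scan <- function(net, context = "disease", config,
                        modes = c("pin0", "pin1", "restore"),
                        nodes = NULL,
                        mode = c("sampled", "exhaustive"),
                        n_samples = 20000L, seed = NULL) {
  mode <- match.arg(mode)
  modes <- match.arg(modes, c("pin0", "pin1", "restore"),
                     several.ok = TRUE)
  nodes <- nodes %||% node_names(net)
  for (nd in nodes) check_node(net, nd)
  check_context(net, context)

  if ("restore" %in% modes && !"normal" %in% names(net$basal)) {
    warn("restore mode requested but no \"normal\" context; skipping")
    modes <- setdiff(modes, "restore")
  }

  ls_mode <- mode
  base_ls <- build_landscape(net, context, mode = ls_mode,
                             n_samples = n_samples, seed = seed)
  baseline <- score_landscape(base_ls, config, net)$score

  grid <- tidyr::expand_grid(node = nodes, mode = modes)
  if ("restore" %in% modes) {
    unchanged <- grid$mode == "restore" &
      net$basal[[context]][grid$node] == net$basal[["normal"]][grid$node]
    grid <- grid[!unchanged, ]
  }

  rows <- purrr::pmap(grid, function(node, mode) {
    pnet <- apply_one_perturbation(net, node, mode, NA_real_, context)
    ls <- build_landscape(pnet, context, mode = ls_mode,
                          n_samples = n_samples, seed = seed)
    sc <- score_landscape(ls, config, net)$score
    tibble(node = node, mode = mode, baseline = baseline, score = sc,
           delta = sc - baseline, n_attractors = nrow(ls$attractors))
  })
  out <- bind_rows(rows) |> arrange(desc(.data$delta), .data$node)
  attr(out, "baseline") <- baseline
  class(out) <- c("bn_scan", class(out))
  out
}

#' Filter a scan down to reversion targets
#'
#' @param scan A `bn_scan` from [single_scan()].
#' @param threshold Minimum score increase (default 0, strict).
#' @return The filtered scan tibble.
#' @export
reversion_targets <- function(scan, threshold = 0) {
  scan |> filter(.data$delta > threshold)
}

classify_synergy <- function(delta_ab, delta_sum, tau, band) {
  bounds <- if (band == "relative") {
    c(lo = delta_sum * (1 - tau), hi = delta_sum * (1 + tau))
  } else {
    c(lo = delta_sum - tau, hi = delta_sum + tau)
  }
  if (delta_ab > bounds[["hi"]]) "synergistic"
  else if (delta_ab < bounds[["lo"]]) "antagonistic"
  else "additive"
}

#' Double-node perturbation scan with synergy classification
#'
#' For every unordered pair of candidate nodes, measures the normal-like
#' score increase of the pair perturbation against the increases of the two
#' single perturbations under a shared baseline.  A pair is synergistic
#' when the joint increase exceeds the sum of the single increases beyond
#' the tolerance band, antagonistic when it falls short of it, and additive
#' within the band.  With the relative band, the boundaries are
#' `(delta_A + delta_B) * (1 +/- tau)`.
#'
#' @param net A `bn_network`.
#' @param context Basal context.
#' @param config A `bn_scoring_config`.
#' @param candidates Either a character vector of node names (the scan mode
#'   per node is then chosen as the better of `pin0`/`pin1` by its single
#'   delta) or a data frame with columns `node` and `mode` (each mode one
#'   of `pin0`, `pin1`).
#' @param tau Additive tolerance (default 0.2 relative).
#' @param band `"relative"` or `"absolute"`.
#' @param mode,n_samples,seed Landscape simulation parameters.
#' @return A `bn_synergy` tibble: one row per pair with columns `node_a`,
#'   `mode_a`, `node_b`, `mode_b`, `delta_a`, `delta_b`, `delta_ab`,
#'   `classification`, `tau`, `band`.
#' @export
double_scan <- function(net, context = "disease", config, candidates,
                        tau = 0.2, band = c("relative", "absolute"),
                        mode = c("sampled", "exhaustive"),
                        n_samples = 20000L, seed = NULL) {
  band <- match.arg(band)
  mode <- match.arg(mode)
  if (NROW(candidates) < 2L && length(candidates) < 2L) {
    abort("need at least two candidate nodes")
  }

  if (is.character(candidates)) {
    sc <- single_scan(net, context, config, modes = c("pin0", "pin1"),
                      nodes = candidates, mode = mode,
                      n_samples = n_samples, seed = seed)
    cand <- sc |>
      group_by(.data$node) |>
      slice_max(.data$delta, n = 1L, with_ties = FALSE) |>
      ungroup() |>
      select("node", "mode")
  } else {
    cand <- as_tibble(candidates)
    if (!all(c("node", "mode") %in% names(cand))) {
      abort("`candidates` needs columns `node` and `mode`")
    }
    if (!all(cand$mode %in% c("pin0", "pin1"))) {
      abort("pair-scan modes are limited to pin0 and pin1")
    }
  }
  if (nrow(cand) < 2L) abort("need at least two candidate nodes")
  if (anyDuplicated(cand$node)) {
    dup <- cand$node[duplicated(cand$node)][1]
    inform(paste0("dropping duplicate candidate node: ", dup))
    cand <- cand[!duplicated(cand$node), ]
  }

  base_ls <- build_landscape(net, context, mode = mode,
                             n_samples = n_samples, seed = seed)
  baseline <- score_landscape(base_ls, config, net)$score

  single_delta <- vapply(seq_len(nrow(cand)), function(k) {
    pnet <- apply_one_perturbation(net, cand$node[k], cand$mode[k],
                                   NA_real_, context)
    ls <- build_landscape(pnet, context, mode = mode,
                          n_samples = n_samples, seed = seed)
    score_landscape(ls, config, net)$score - baseline
  }, numeric(1))
  neg <- which(single_delta < 0)
  if (length(neg)) {
    inform(paste0("candidate(s) with negative single delta kept in pair ",
                  "scan: ", paste(cand$node[neg], collapse = ", ")))
  }

  pairs <- utils::combn(nrow(cand), 2L)
  rows <- purrr::map(seq_len(ncol(pairs)), function(q) {
    i <- pairs[1L, q]; j <- pairs[2L, q]
    pnet <- apply_one_perturbation(net, cand$node[i], cand$mode[i],
                                   NA_real_, context)
    pnet <- apply_one_perturbation(pnet, cand$node[j], cand$mode[j],
                                   NA_real_, context)
    ls <- build_landscape(pnet, context, mode = mode,
                          n_samples = n_samples, seed = seed)
    d_ab <- score_landscape(ls, config, net)$score - baseline
    tibble(
      node_a = cand$node[i], mode_a = cand$mode[i],
      node_b = cand$node[j], mode_b = cand$mode[j],
      delta_a = single_delta[i], delta_b = single_delta[j],
      delta_ab = d_ab,
      classification = classify_synergy(d_ab,
                                        single_delta[i] + single_delta[j],
                                        tau, band),
      tau = tau, band = band
    )
  })
  out <- bind_rows(rows) |> arrange(desc(.data$delta_ab))
  attr(out, "baseline") <- baseline
  class(out) <- c("bn_synergy", class(out))
  out
}
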