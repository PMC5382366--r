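#' Build a phenotype scoring configuration
#'
#' The scoring system maps marker-node activities of an attractor to one
#' cancer-proximity score (CPS) per phenotype aspect (conventionally
#' proliferation, EMT and stemness).  Each aspect is defined by weighted
#' rules `(marker, desired activity, rule weight)`; an attractor's aspect
#' CPS is the weighted satisfaction fraction of its rules, in \[0, 1\].
#' High CPS is normal-like, low CPS is proximate to cancerous.  Aspect
#' weights combine the per-aspect landscape CPS values into one scalar
#' normal-like score; the conventional integer weights are 6 (proliferation),
#' 4 (EMT) and 1 (stemness).
#'
#' @param aspects Ordered character vector of aspect names.
#' @param rules Data frame with columns `aspect`, `marker`, `desired`
#'   (0 or 1), `weight` (positive).  Every aspect must have at least one
#'   rule.
#' @param aspect_weights Nonnegative numeric vector, one weight per aspect.
#' @return An object of class `bn_scoring_config`.
#' @export
scoring_config <- function(aspects, rules, aspect_weights) {
  aspects <- as.character(aspects)
  if (anyDuplicated(aspects)) abort("aspect names must be unique")
  rules <- as_tibble(rules)
  if (!all(c("aspect", "marker", "desired", "weight") %in% names(rules))) {
    abort("`rules` needs columns aspect, marker, desired, weight")
  }
  unknown <- setdiff(unique(rules$aspect), aspects)
  if (length(unknown)) {
    abort(paste0("rule references unknown aspect: ", unknown[1]))
  }
  empty <- setdiff(aspects, unique(rules$aspect))
  if (length(empty)) {
    abort(paste0("aspect has no rules: ", empty[1]))
  }
  if (!all(rules$desired %in% c(0, 1))) {
    abort("rule `desired` must be 0 or 1")
  }
  if (any(rules$weight <= 0)) abort("rule weights must be positive")
  aspect_weights <- as.numeric(aspect_weights)
  if (length(aspect_weights) != length(aspects)) {
    abort("`aspect_weights` must have one entry per aspect")
  }
  if (any(aspect_weights < 0)) abort("aspect weights must be nonnegative")
  names(aspect_weights) <- aspects
  structure(list(aspects = aspects, rules = rules,
                 aspect_weights = aspect_weights),
            class = "bn_scoring_config")
}

#' @export
print.bn_scoring_config <- function(x, ...) {
  cat("<bn_scoring_config> aspects:",
      paste0(x$aspects, " (w=", x$aspect_weights, ")", collapse = ", "),
      "\n", nrow(x$rules), "marker rules\n")
  invisible(x)
}

#' Read a scoring configuration from JSON
#'
#' Format: `{"aspects":[...], "rules":{aspect:[{"marker","desired",
#' "weight"}]}, "aspect_weights":[...]}`.
#'
#' @param path Path to a scoring-config JSON file.
#' @return A `bn_scoring_config`.
#' @export
read_scoring_config <- function(path) {
  obj <- read_json_strict(path)
  check_fields(obj, c("aspects", "rules", "aspect_weights"),
               c("aspects", "rules", "aspect_weights"), "scoring config")
  aspects <- as.character(unlist(obj$aspects))
  rules <- bind_rows(imap(obj$rules, function(rr, aspect) {
    bind_rows(lapply(rr, function(r) {
      check_fields(r, c("marker", "desired", "weight"),
                   c("marker", "desired", "weight"), "scoring rule")
      tibble(aspect = aspect, marker = as.character(r$marker),
             desired = as.numeric(r$desired),
             weight = as.numeric(r$weight))
    }))
  }))
  scoring_config(aspects, rules, as.numeric(unlist(obj$aspect_weights)))
}

#' Write a scoring configuration to JSON
#' @param config A `bn_scoring_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scoring_config <- function(config, path) {
  rules <- lapply(config$aspects, function(a) {
    rr <- config$rules |> filter(.data$aspect == a)
    lapply(seq_len(nrow(rr)), function(k) {
      list(marker = rr$marker[k], desired = rr$desired[k],
           weight = rr$weight[k])
    })
  })
  names(rules) <- config$aspects
  obj <- list(aspects = as.list(config$aspects), rules = rules,
              aspect_weights = unname(config$aspect_weights))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load the default marker-rule reconstruction shipped with the package
#'
#' A reconstruction of a colorectal marker rubric over the eight
#' conventional markers (Snail, SLUG, MMP, E-cadherin, CyclinE, CyclinD,
#' p21, Caspase-3): proliferation favours cyclins off and p21 on, EMT
#' favours Snail/SLUG/MMP off and E-cadherin on, stemness penalizes Snail.
#' Caspase-3 carries no rule so the normal-like optimum does not require
#' inducing apoptosis.  The exact marker-to-score table is configurable;
#' this file is a documented default, not ground truth.
#'
#' @return A `bn_scoring_config`.
#' @export
default_scoring_config <- function() {
  read_scoring_config(system.file("extdata", "configs",
                                  "default_scoring.json",
                                  package = "boolscape", mustWork = TRUE))
}

check_config_net <- function(config, net) {
  mk <- nodes_with_role(net, "marker")
  bad <- setdiff(unique(config$rules$marker), mk)
  if (length(bad)) {
    abort(paste0("scoring rule marker is not a marker node: ", bad[1]))
  }
  invisible(config)
}

marker_activity <- function(states_mat, markers) {
  colMeans(states_mat[, markers, drop = FALSE])
}

#' Score one attractor against the phenotype rubric
#'
#' For cyclic attractors each marker's activity is its mean over the cycle
#' states.  The CPS of an aspect is
#' `sum(w * (1 - |activity - desired|)) / sum(w)` over its rules.
#'
#' @param attractor An attractor as returned inside [build_landscape()] /
#'   [find_attractor()] (a list with a `states` matrix), or a bare
#'   period x N binary state matrix with node-name columns.
#' @param config A `bn_scoring_config`.
#' @param net The `bn_network` the attractor belongs to.
#' @return Named numeric vector of per-aspect CPS values in \[0, 1\].
#' @export
score_attractor <- function(attractor, config, net) {
  check_config_net(config, net)
  states <- if (is.matrix(attractor)) attractor else attractor$states
  act <- marker_activity(states, unique(config$rules$marker))
  vapply(config$aspects, function(a) {
    rr <- config$rules[config$rules$aspect == a, ]
    sum(rr$weight * (1 - abs(act[rr$marker] - rr$desired))) /
      sum(rr$weight)
  }, numeric(1))
}

#' Score an attractor landscape: the normal-like score
#'
#' Computes the per-attractor CPS matrix, basin-weights it into the
#' landscape CPS vector (`S = s . b / b_total`), and collapses it with the
#' aspect weights into the scalar normal-like score.  High scores are
#' normal-like; the maximum is the sum of the aspect weights.
#'
#' @param landscape A `bn_landscape`.
#' @param config A `bn_scoring_config`.
#' @param net The scored `bn_network`.
#' @return A `bn_score`: list with `aspect_cps` (named landscape CPS
#'   vector), `score` (scalar), `per_attractor` (tibble of CPS rows with
#'   basin fractions), and `aspect_weights`.
#' @export
score_landscape <- function(landscape, config, net) {
  if (nrow(landscape$attractors) == 0L) abort("landscape has no attractors")
  check_config_net(config, net)
  cps <- vapply(landscape$attractors$states,
                function(s) score_attractor(s, config, net),
                numeric(length(config$aspects)))
  cps <- if (is.null(dim(cps))) matrix(cps, ncol = 1L) else t(cps)
  colnames(cps) <- config$aspects
  b <- landscape$attractors$basin_fraction
  aspect_cps <- as.numeric(b %*% cps)
  names(aspect_cps) <- config$aspects
  structure(
    list(
      aspect_cps = aspect_cps,
      score = sum(config$aspect_weights * aspect_cps),
      per_attractor = bind_cols(
        landscape$attractors |> select("id", "period", "basin_fraction"),
        as_tibble(cps)
      ),
      aspect_weights = config$aspect_weights
    ),
    class = "bn_score"
  )
}

#' @export
print.bn_score <- function(x, ...) {
  cat("<bn_score> normal-like score:", format(x$score), "\n  aspect CPS:",
      paste0(names(x$aspect_cps), "=", format(x$aspect_cps, digits = 4),
             collapse = ", "), "\n")
  invisible(x)
}

#' Write a per-attractor score report as TSV
#'
#' One row per attractor (CPS per aspect, basin fraction) plus a trailing
#' landscape row carrying the basin-weighted CPS vector and the scalar
#' normal-like score.
#'
#' @param score A `bn_score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_tsv <- function(score, path) {
  per <- score$per_attractor
  landscape_row <- tibble(id = "LANDSCAPE", period = NA_integer_,
                          basin_fraction = 1)
  for (a in names(score$aspect_cps)) {
    landscape_row[[a]] <- score$aspect_cps[[a]]
  }
  out <- bind_rows(per, landscape_row)
  out$normal_like_score <- c(rep(NA_real_, nrow(per)), score$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fit aspect weights to an external malignancy ranking
#'
#' Scores each mutation profile's landscape under every candidate integer
#' weight vector on a grid and returns the weights that maximize the
#' Kendall tau between the induced normal-like score ordering and a target
#' ranking (profile names ordered from most malignant, i.e. lowest
#' expected score, to most normal-like).  Ties are broken by the smaller
#' weight sum, then lexicographically, so the result is deterministic.
#'
#' @param profiles List of `bn_profile` objects.
#' @param target_rank Character vector: a permutation of the profile names,
#'   most malignant first.
#' @param net A `bn_network`.
#' @param config A `bn_scoring_config` (its aspect weights are ignored; the
#'   grid replaces them).
#' @param context Basal context the profiles act on.
#' @param grid Integer candidate values per aspect (default `0:10`).
#' @param mode,n_samples,seed Landscape simulation parameters.
#' @return A `bn_weight_fit`: list with `weights` (best vector), `tau`,
#'   `profile_scores` (tibble of aspect CPS per profile and the best-fit
#'   score), and `n_candidates`.
#' @export
fit_weights <- function(profiles, target_rank, net, config,
                        context = "disease", grid = 0:10,
                        mode = "exhaustive", n_samples = 20000L,
                        seed = NULL) {
  if (length(profiles) < 2L) abort("need at least two profiles")
  names(profiles) <- vapply(profiles, function(p) p$name, character(1))
  if (!setequal(target_rank, names(profiles)) ||
      length(target_rank) != length(profiles)) {
    abort("`target_rank` must be a permutation of the profile names")
  }
  if (!length(grid)) abort("empty weight search space")
  cps <- vapply(profiles, function(pr) {
    pnet <- apply_profile(net, pr, context)
    ls <- build_landscape(pnet, context, mode = mode,
                          n_samples = n_samples, seed = seed)
    score_landscape(ls, config, net)$aspect_cps
  }, numeric(length(config$aspects)))
  cps <- if (is.null(dim(cps))) matrix(cps, ncol = 1L,
                                       dimnames = list(names(profiles)))
         else t(cps)

  target_pos <- match(rownames(cps), target_rank)
  cand <- as.matrix(expand.grid(rep(list(sort(grid)), ncol(cps))))
  cand <- cand[rowSums(cand) > 0, , drop = FALSE]
  if (!nrow(cand)) abort("empty weight search space")
  # round candidate scores so CPS rows that tie exactly are seen as tied
  # (a last-bit float difference must not masquerade as concordance)
  taus <- apply(cand, 1L, function(w) {
    stats::cor(round(as.numeric(cps %*% w), WS_DIGITS), target_pos,
               method = "kendall")
  })
  taus[is.na(taus)] <- -Inf
  best_tau <- max(taus)
  top <- cand[taus == best_tau, , drop = FALSE]
  ord <- do.call(order, c(list(rowSums(top)),
                          lapply(seq_len(ncol(top)), function(j) top[, j])))
  weights <- as.numeric(top[ord[1L], ])
  names(weights) <- config$aspects
  structure(
    list(
      weights = weights,
      tau = best_tau,
      profile_scores = as_tibble(cps) |>
        mutate(profile = rownames(cps),
               score = as.numeric(cps %*% weights),
               target_position = target_pos, .before = 1L),
      n_candidates = nrow(cand)
    ),
    class = "bn_weight_fit"
  )
}

#' @export
print.bn_weight_fit <- function(x, ...) {
  cat("<bn_weight_fit> best weights:",
      paste0(names(x$weights), "=", x$weights, collapse = ", "),
      " (Kendall tau:", format(x$tau, digits = 4), ")\n")
  invisible(x)
}
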