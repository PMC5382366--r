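#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_tile labs scale_fill_gradient2 facet_wrap theme_minimal coord_flip
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an attractor landscape
#'
#' @param x A `bn_landscape`.
#' @param ... Unused.
#' @return One row per attractor: `id`, `period`, `basin_count`,
#'   `basin_fraction`, and the first cycle state as a bitstring.
#' @export
tidy.bn_landscape <- function(x, ...) {
  x$attractors |>
    mutate(state = map_chr(.data$states,
                           function(s) paste(s[1L, ], collapse = ""))) |>
    select("id", "period", "basin_count", "basin_fraction", "state")
}

#' One-row landscape summary
#' @param x A `bn_landscape`.
#' @param ... Unused.
#' @return Tibble: attractor count, point-attractor basin coverage, top-5
#'   mean basin, sampling metadata.
#' @export
glance.bn_landscape <- function(x, ...) {
  att <- x$attractors
  tibble(
    n_attractors = nrow(att),
    n_point = sum(att$period == 1L),
    point_basin_coverage = sum(att$basin_fraction[att$period == 1L]),
    top5_mean_basin = top5_mean_basin(x),
    total_samples = x$total_samples,
    mode = x$mode,
    context = x$context
  )
}

#' @export
autoplot.bn_landscape <- function(object, ...) {
  d <- tidy(object) |>
    mutate(label = paste0(substr(.data$id, 1, 12),
                          ifelse(.data$period > 1L,
                                 paste0(" (p", .data$period, ")"), "")))
  ggplot(d, aes(x = stats::reorder(.data$label, .data$basin_fraction),
                y = .data$basin_fraction)) +
    geom_col() +
    coord_flip() +
    labs(x = "attractor", y = "basin fraction",
         title = "Attractor landscape") +
    theme_minimal()
}

#' Tidy a landscape score
#' @param x A `bn_score`.
#' @param ... Unused.
#' @return One row per (attractor, aspect) with CPS and basin fraction.
#' @export
tidy.bn_score <- function(x, ...) {
  x$per_attractor |>
    pivot_longer(cols = names(x$aspect_cps), names_to = "aspect",
                 values_to = "cps")
}

#' One-row score summary
#' @param x A `bn_score`.
#' @param ... Unused.
#' @return Tibble with the scalar normal-like score and the per-aspect
#'   landscape CPS values.
#' @export
glance.bn_score <- function(x, ...) {
  bind_cols(tibble(normal_like_score = x$score),
            as_tibble(as.list(x$aspect_cps)))
}

#' @export
autoplot.bn_score <- function(object, ...) {
  d <- tibble(aspect = factor(names(object$aspect_cps),
                              levels = names(object$aspect_cps)),
              cps = object$aspect_cps)
  ggplot(d, aes(x = .data$aspect, y = .data$cps)) +
    geom_col() +
    labs(y = "landscape CPS",
         title = sprintf("Normal-like score: %.3f", object$score)) +
    theme_minimal()
}

#' Tidy a perturbation scan
#' @param x A `bn_scan`.
#' @param ... Unused.
#' @return The scan as a plain tibble.
#' @export
tidy.bn_scan <- function(x, ...) as_tibble(x)

#' @export
autoplot.bn_scan <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(label = paste0(.data$node, " (", .data$mode, ")"))
  ggplot(d, aes(x = stats::reorder(.data$label, .data$delta),
                y = .data$delta)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "normal-like score change",
         title = "Single-node perturbation scan") +
    theme_minimal()
}

#' Tidy a synergy table
#' @param x A `bn_synergy`.
#' @param ... Unused.
#' @return The pair table as a plain tibble.
#' @export
tidy.bn_synergy <- function(x, ...) as_tibble(x)

#' @export
autoplot.bn_synergy <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(pair = paste(.data$node_a, .data$node_b, sep = "-"),
           expected = .data$delta_a + .data$delta_b)
  ggplot(d, aes(x = .data$expected, y = .data$delta_ab,
                colour = .data$classification)) +
    geom_point(size = 2) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    labs(x = "sum of single deltas", y = "pair delta",
         title = "Double-node perturbation synergy") +
    theme_minimal()
}

#' Tidy a motif result
#' @param x A `bn_motif`.
#' @param ... Unused.
#' @return One row per member with its residual target delta.
#' @export
tidy.bn_motif <- function(x, ...) {
  x$members |> mutate(target = x$target$node[1], .before = 1L)
}

#' One-row motif summary
#' @param x A `bn_motif`.
#' @param ... Unused.
#' @return Tibble: target, original delta, member count, final residual,
#'   termination reason.
#' @export
glance.bn_motif <- function(x, ...) {
  tibble(
    target = x$target$node[1],
    target_mode = x$target$mode[1],
    delta0 = x$delta0,
    n_members = nrow(x$members),
    residual_delta = if (nrow(x$members)) {
      x$members$residual_delta[nrow(x$members)]
    } else x$delta0,
    reason = x$reason
  )
}

#' Tidy a robustness trajectory
#' @param x A `bn_trajectory`.
#' @param ... Unused.
#' @return The trajectory as a plain tibble.
#' @export
tidy.bn_trajectory <- function(x, ...) as_tibble(x)

#' @export
autoplot.bn_trajectory <- function(object, ...) {
  d <- as_tibble(object)
  if (!"sequence_id" %in% names(d)) d$sequence_id <- 1L
  d <- d |>
    pivot_longer(cols = c("n_attractors", "top5_mean_basin", "score"),
                 names_to = "metric", values_to = "value")
  ggplot(d, aes(x = .data$step, y = .data$value,
                group = .data$sequence_id)) +
    geom_line(alpha = 0.6) +
    geom_point(size = 1) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "accumulated mutations", y = NULL,
         title = "Robustness along mutation accumulation") +
    theme_minimal()
}

#' Heat-map of node activities across conditions
#'
#' @param profiles A tibble of activity profiles (rows from
#'   [activity_profile()], possibly several conditions bound together).
#' @return A ggplot heat-map, blue (frozen at 0) through purple (0.5,
#'   responsive) to red (frozen at 1).
#' @export
plot_activity <- function(profiles) {
  ggplot(profiles, aes(x = .data$condition, y = .data$node,
                       fill = .data$activity)) +
    geom_tile(colour = "grey80") +
    scale_fill_gradient2(low = "#2166ac", mid = "#9970ab",
                         high = "#b2182b", midpoint = 0.5,
                         limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "activity",
         title = "Basin-weighted node activities") +
    theme_minimal()
}
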