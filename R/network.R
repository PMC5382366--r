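#' Construct a weighted-sum regulatory network
#'
#' A regulatory network couples an ordered node set with a signed, weighted
#' connectivity matrix and one basal-level vector per biological context
#' (e.g. `"normal"` and `"disease"`).  Entry `(i, j)` of the connectivity
#' matrix is the influence of node `j` on node `i`; the basal level is the
#' drift a node feels in the absence of incoming signal.  Nodes carry a role
#' annotation: `input` nodes represent external stimuli, `marker` nodes are
#' the phenotype readouts used by the scoring system, everything else is
#' `internal`.
#'
#' @param nodes Data frame with columns `name` (unique identifiers) and
#'   `role` (one of `"input"`, `"marker"`, `"internal"`).
#' @param edges Data frame with columns `source`, `target`, `weight`
#'   (nonzero signed reals); direction is source regulates target.  May be
#'   `NULL` or empty for an edgeless network.
#' @param basal Named list of numeric basal vectors, one per context.  Each
#'   vector must have one entry per node, in node order (or named by node).
#'   Contexts `"normal"` and `"disease"` are conventional but not enforced.
#' @return An object of class `bn_network`.
#' @examples
#' net <- regulatory_network(
#'   nodes = data.frame(name = c("A", "B"), role = c("internal", "marker")),
#'   edges = data.frame(source = "A", target = "B", weight = 1),
#'   basal = list(normal = c(0, 0), disease = c(1, 0))
#' )
#' @export
regulatory_network <- function(nodes, edges = NULL, basal) {
  nodes <- as_tibble(nodes)
  if (!all(c("name", "role") %in% names(nodes))) {
    abort("`nodes` must have columns `name` and `role`")
  }
  nodes$name <- as.character(nodes$name)
  nodes$role <- as.character(nodes$role)
  nm <- nodes$name
  n <- length(nm)
  if (n < 1L) abort("a network needs at least one node")
  if (anyDuplicated(nm)) {
    abort(paste0("duplicate node name: ", nm[duplicated(nm)][1]))
  }
  bad_role <- setdiff(unique(nodes$role), c("input", "marker", "internal"))
  if (length(bad_role)) {
    abort(paste0("unknown role: ", bad_role[1],
                 " (must be input, marker or internal)"))
  }

  conn <- matrix(0, n, n, dimnames = list(target = nm, source = nm))
  if (!is.null(edges) && nrow(as.data.frame(edges)) > 0L) {
    edges <- as_tibble(edges)
    if (!all(c("source", "target", "weight") %in% names(edges))) {
      abort("`edges` must have columns `source`, `target`, `weight`")
    }
    for (col in c("source", "target")) {
      unknown <- setdiff(unique(as.character(edges[[col]])), nm)
      if (length(unknown)) {
        abort(paste0("edge references unknown node: ", unknown[1]))
      }
    }
    if (any(!is.finite(edges$weight)) || any(edges$weight == 0)) {
      abort("edge weights must be finite and nonzero")
    }
    key <- paste(edges$source, edges$target)
    if (anyDuplicated(key)) {
      abort(paste0("duplicate edge: ", key[duplicated(key)][1]))
    }
    conn[cbind(as.character(edges$target), as.character(edges$source))] <-
      edges$weight
  }

  if (!is.list(basal) || is.null(names(basal)) || any(names(basal) == "")) {
    abort("`basal` must be a named list of context vectors")
  }
  basal <- lapply(basal, function(v) {
    v <- as.numeric(v)
    if (length(v) != n) {
      abort(paste0("each basal vector must have length ", n))
    }
    names(v) <- nm
    v
  })

  structure(
    list(nodes = nodes, connectivity = conn, basal = basal,
         pins = stats::setNames(numeric(0), character(0))),
    class = "bn_network"
  )
}

#' @export
print.bn_network <- function(x, ...) {
  cat("<bn_network> ", n_nodes(x), " nodes, ",
      sum(x$connectivity != 0), " links, contexts: ",
      paste(names(x$basal), collapse = ", "), "\n", sep = "")
  if (length(x$pins)) {
    cat("  pinned:", paste0(names(x$pins), "=", x$pins, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Number of nodes in a network
#' @param net A `bn_network`.
#' @return Integer node count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' Node names of a network
#' @param net A `bn_network`.
#' @return Character vector in network order.
#' @export
node_names <- function(net) net$nodes$name

#' Nodes with a given role
#' @param net A `bn_network`.
#' @param role One of `"input"`, `"marker"`, `"internal"`.
#' @return Character vector of node names.
#' @export
nodes_with_role <- function(net, role) {
  net$nodes$name[net$nodes$role == role]
}

#' Free (unpinned) nodes of a network
#' @param net A `bn_network`.
#' @return Character vector of node names not held fixed by a pin.
#' @export
free_nodes <- function(net) setdiff(node_names(net), names(net$pins))

check_node <- function(net, node) {
  if (!node %in% node_names(net)) {
    abort(paste0("unknown node: ", node))
  }
  invisible(node)
}

check_context <- function(net, context) {
  if (!context %in% names(net$basal)) {
    abort(paste0("unknown context: ", context, " (available: ",
                 paste(names(net$basal), collapse = ", "), ")"))
  }
  invisible(context)
}

#' Pin a node to a fixed Boolean value
#'
#' A pinned node is overwritten with its pinned value after every update
#' step and in every sampled initial state, so it is constant along every
#' trajectory.  Pinning is idempotent; re-pinning a node replaces its value.
#'
#' @param net A `bn_network`.
#' @param node Node name.
#' @param value 0 or 1.
#' @return A derived `bn_network` with the pin recorded; the input network
#'   is not modified.
#' @export
pin_node <- function(net, node, value) {
  check_node(net, node)
  if (!value %in% c(0, 1)) abort("pin value must be 0 or 1")
  net$pins[node] <- as.numeric(value)
  net
}

#' Describe a single node-level intervention
#'
#' Four intervention modes are supported: `pin0` (inhibition: clamp state to
#' 0), `pin1` (activation: clamp to 1), `restore` (reset the node's basal
#' level in the active context back to its `"normal"` value), and
#' `basal_shift` (add `shift_value` to the node's basal level).
#'
#' @param node Node name.
#' @param mode One of `"pin0"`, `"pin1"`, `"restore"`, `"basal_shift"`.
#' @param shift_value Shift amount; required for `basal_shift`, ignored
#'   otherwise.
#' @return A one-row tibble with columns `node`, `mode`, `shift_value`.
#' @export
perturbation <- function(node, mode, shift_value = NA_real_) {
  assert_string(node, "node")
  if (!mode %in% c("pin0", "pin1", "restore", "basal_shift")) {
    abort(paste0("unknown perturbation mode: ", mode))
  }
  if (mode == "basal_shift" && !is.finite(shift_value)) {
    abort("`shift_value` is required for basal_shift")
  }
  tibble(node = node, mode = mode, shift_value = as.numeric(shift_value))
}

#' Bundle perturbations into a named mutation profile
#'
#' @param name Profile identifier.
#' @param perturbations A data frame of perturbations (rows as produced by
#'   [perturbation()]), or a list of such rows.  No node may appear twice.
#' @return An object of class `bn_profile`.
#' @export
mutation_profile <- function(name, perturbations) {
  assert_string(name, "name")
  if (is.list(perturbations) && !is.data.frame(perturbations)) {
    perturbations <- bind_rows(perturbations)
  }
  perturbations <- as_tibble(perturbations)
  if (nrow(perturbations) && !all(c("node", "mode") %in% names(perturbations))) {
    abort("perturbations need columns `node` and `mode`")
  }
  if (!"shift_value" %in% names(perturbations)) {
    perturbations$shift_value <- NA_real_
  }
  if (anyDuplicated(perturbations$node)) {
    abort(paste0("node appears twice in profile: ",
                 perturbations$node[duplicated(perturbations$node)][1]))
  }
  structure(list(name = name, perturbations = perturbations),
            class = "bn_profile")
}

#' @export
print.bn_profile <- function(x, ...) {
  cat("<bn_profile> ", x$name, ": ", nrow(x$perturbations),
      " perturbation(s)\n", sep = "")
  invisible(x)
}

apply_one_perturbation <- function(net, node, mode, shift_value, context) {
  check_node(net, node)
  if (mode == "pin0") {
    net <- pin_node(net, node, 0)
  } else if (mode == "pin1") {
    net <- pin_node(net, node, 1)
  } else if (mode == "restore") {
    if (!"normal" %in% names(net$basal)) {
      abort("restore requires a \"normal\" basal context")
    }
    net$basal[[context]][node] <- net$basal[["normal"]][node]
  } else if (mode == "basal_shift") {
    net$basal[[context]][node] <- net$basal[[context]][node] + shift_value
  } else {
    abort(paste0("unknown perturbation mode: ", mode))
  }
  net
}

#' Apply a mutation profile to a network
#'
#' Produces a derived network: pin modes add the node to the pin mask with
#' the clamped value, `restore` replaces the node's basal entry in the
#' active context with its `"normal"` value, and `basal_shift` adds the
#' shift to the basal entry.  The input network is never modified, so
#' re-using the original object exactly undoes a profile.
#'
#' @param net A `bn_network`.
#' @param profile A `bn_profile` (or a perturbation data frame).
#' @param context Context whose basal vector the profile acts on.
#' @return The perturbed `bn_network`.
#' @export
apply_profile <- function(net, profile, context = "disease") {
  check_context(net, context)
  pert <- if (inherits(profile, "bn_profile")) profile$perturbations
          else as_tibble(profile)
  if (nrow(pert) == 0L) return(net)
  for (k in seq_len(nrow(pert))) {
    net <- apply_one_perturbation(net, pert$node[k], pert$mode[k],
                                  pert$shift_value[k], context)
  }
  net
}

# ---- file formats ---------------------------------------------------------

read_json_strict <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

check_fields <- function(obj, allowed, required, where) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra)) {
    abort(paste0("unknown field in ", where, ": ", extra[1]))
  }
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    abort(paste0("missing field in ", where, ": ", missing[1]))
  }
  invisible(obj)
}

#' Read a network from its JSON representation
#'
#' The format is
#' `{"nodes":[{"name","role"}...], "edges":[{"source","target","weight"}...],
#' "basal":{"<context>":[...]}}`; edge direction `source -> target`
#' corresponds to connectivity entry (target, source).  Unknown fields are
#' rejected, and a file written by [write_network()] reads back bit-exactly.
#'
#' @param path Path to a network JSON file.
#' @return A validated `bn_network`.
#' @export
read_network <- function(path) {
  obj <- read_json_strict(path)
  check_fields(obj, c("nodes", "edges", "basal"), c("nodes", "basal"),
               "network file")
  nodes <- bind_rows(lapply(obj$nodes, function(nd) {
    check_fields(nd, c("name", "role"), c("name", "role"), "node entry")
    tibble(name = as.character(nd$name), role = as.character(nd$role))
  }))
  edges <- NULL
  if (!is.null(obj$edges) && length(obj$edges)) {
    edges <- bind_rows(lapply(obj$edges, function(ed) {
      check_fields(ed, c("source", "target", "weight"),
                   c("source", "target", "weight"), "edge entry")
      tibble(source = as.character(ed$source),
             target = as.character(ed$target),
             weight = as.numeric(ed$weight))
    }))
  }
  basal <- lapply(obj$basal, function(v) as.numeric(unlist(v)))
  regulatory_network(nodes, edges, basal)
}

network_edge_table <- function(net) {
  idx <- which(net$connectivity != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble(source = character(), target = character(),
                  weight = numeric()))
  }
  nm <- node_names(net)
  tibble(source = nm[idx[, "source"]], target = nm[idx[, "target"]],
         weight = net$connectivity[idx]) |>
    arrange(.data$target, .data$source)
}

#' Write a network to canonical JSON
#'
#' Nodes keep network order; edges are written sorted by (target, source)
#' so the representation is canonical and round-trips through
#' [read_network()] bit-exactly.  Pins are transient simulation state and
#' are not serialized.
#'
#' @param net A `bn_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  edges <- network_edge_table(net)
  obj <- list(
    nodes = lapply(seq_len(n_nodes(net)), function(i) {
      list(name = net$nodes$name[i], role = net$nodes$role[i])
    }),
    edges = lapply(seq_len(nrow(edges)), function(k) {
      list(source = edges$source[k], target = edges$target[k],
           weight = edges$weight[k])
    }),
    basal = lapply(net$basal, unname)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a mutation profile from JSON
#'
#' Format: `{"name", "perturbations":[{"node","mode","shift_value"?}]}`.
#'
#' @param path Path to a profile JSON file.
#' @return A `bn_profile`.
#' @export
read_profile <- function(path) {
  obj <- read_json_strict(path)
  check_fields(obj, c("name", "perturbations"), c("name", "perturbations"),
               "profile file")
  pert <- bind_rows(lapply(obj$perturbations, function(p) {
    check_fields(p, c("node", "mode", "shift_value"), c("node", "mode"),
                 "perturbation entry")
    perturbation(as.character(p$node), as.character(p$mode),
                 if (is.null(p$shift_value)) NA_real_
                 else as.numeric(p$shift_value))
  }))
  mutation_profile(as.character(obj$name), pert)
}

#' Write a mutation profile to JSON
#' @param profile A `bn_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  pert <- profile$perturbations
  obj <- list(
    name = profile$name,
    perturbations = lapply(seq_len(nrow(pert)), function(k) {
      p <- list(node = pert$node[k], mode = pert$mode[k])
      if (is.finite(pert$shift_value[k])) {
        p$shift_value <- pert$shift_value[k]
      }
      p
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export the connectivity matrix as TSV for human inspection
#'
#' Rows are targets, columns are sources; entry (i, j) is the weight of the
#' link j -> i.
#'
#' @param net A `bn_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity_tsv <- function(net, path) {
  m <- net$connectivity
  df <- data.frame(node = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
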