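#' Feature specification for excitatory arrow typing
#'
#' Features are properties of node pairs that decide which excitatory arrows
#' in the learned patterns are equivalent (i.e. carry the same coupling
#' strength, on Hebbian grounds). Two are built in: the *level feature*
#' (do the two nodes sit at the same level of attribute-equivalent columns?)
#' and the *distance feature* (the geometric distance between the two
#' columns' positions, e.g. dot locations).
#'
#' @param coordinates Optional data frame with columns `column`, `x`, `y`
#'   giving a 2-D position per attribute column (used by the distance
#'   feature). Coordinates must be finite.
#' @param level_feature Logical; if `TRUE`, pairs of nodes in
#'   attribute-equivalent columns are distinguished by whether they carry the
#'   same level label.
#' @param extra Optional function `f(node_a, node_b, network_nodes)` returning
#'   a scalar comparable value appended to the feature tuple; rarely needed.
#'
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(coordinates = NULL, level_feature = TRUE, extra = NULL) {
  if (!is.null(coordinates)) {
    coordinates <- as_tibble(coordinates)
    stopifnot(all(c("column", "x", "y") %in% names(coordinates)))
    if (!all(is.finite(coordinates$x)) || !all(is.finite(coordinates$y))) {
      abort("feature coordinates must be finite")
    }
  }
  structure(
    list(coordinates = coordinates, level_feature = isTRUE(level_feature),
         extra = extra),
    class = "feature_spec"
  )
}

# distance feature comparisons must be robust to float noise on ideal
# coordinates: round to 9 significant digits (relative tolerance 1e-9)
.round_distance <- function(d) signif(d, 9)

#' Build a rivalry network
#'
#' Constructs a rivalry network from attribute columns, learned patterns, and
#' a feature specification. Nodes within a column are all-to-all connected by
#' inhibitory arrows (typed by the column's attribute type); nodes within a
#' learned pattern are all-to-all connected by excitatory arrows, typed by the
#' feature tuple of the pair. A pair of nodes lying in `p` learned patterns
#' receives a single arrow of multiplicity `p`.
#'
#' @param columns Data frame with columns `column` (column identifier),
#'   `type` (attribute type; attribute-equivalent columns share a type), and
#'   `level` (level label), one row per level. Level order within a column is
#'   the row order and fixes the node numbering.
#' @param patterns Data frame with columns `pattern` (pattern identifier),
#'   `column`, and `level`: exactly one level per column per pattern.
#' @param features A [feature_spec()].
#' @param node_order Optional data frame with columns `node`, `column`,
#'   `level` pinning explicit node ids (useful to match published numbering);
#'   by default nodes are numbered column-by-column in row order.
#'
#' @return An object of class `rivalry_network` with components `columns`,
#'   `nodes`, `patterns`, `inhibitory`, `excitatory`, `features`, `n_nodes`.
#' @examples
#' cols <- tibble::tibble(column = "image", type = "image",
#'                        level = c("monkey", "text"))
#' pats <- tibble::tibble(pattern = c(1, 2), column = "image",
#'                        level = c("monkey", "text"))
#' rivalry_network(cols, pats)
#' @export
rivalry_network <- function(columns, patterns, features = feature_spec(),
                            node_order = NULL) {
  columns <- as_tibble(columns)
  patterns <- as_tibble(patterns)
  stopifnot(all(c("column", "type", "level") %in% names(columns)))
  stopifnot(all(c("pattern", "column", "level") %in% names(patterns)))
  if (nrow(columns) == 0L) abort("at least one attribute column is required")
  if (nrow(patterns) == 0L) abort("at least one learned pattern is required")

  col_tab <- columns |>
    group_by(.data$column) |>
    summarise(type = .data$type[1], n_levels = dplyr::n(), .groups = "drop")
  if (any(duplicated(columns[c("column", "level")]))) {
    abort("level labels must be unique within a column")
  }
  # attribute-equivalent columns must have equal level counts
  bad <- col_tab |>
    group_by(.data$type) |>
    summarise(ok = length(unique(.data$n_levels)) == 1L, .groups = "drop")
  if (any(!bad$ok)) {
    abort(paste0("attribute-equivalent columns have unequal level counts: type(s) ",
                 paste(bad$type[!bad$ok], collapse = ", ")))
  }

  # node table (1-based ids, column-by-column unless pinned)
  nodes <- columns |>
    mutate(node = seq_len(nrow(columns))) |>
    left_join(col_tab |> select("column", cell_class = "type"), by = "column") |>
    select("node", "column", "level", "cell_class")
  if (!is.null(node_order)) {
    node_order <- as_tibble(node_order)
    stopifnot(all(c("node", "column", "level") %in% names(node_order)))
    nodes <- nodes |>
      select(-"node") |>
      left_join(node_order |> select("node", "column", "level"),
                by = c("column", "level")) |>
      select("node", "column", "level", "cell_class") |>
      arrange(.data$node)
    if (any(is.na(nodes$node)) || anyDuplicated(nodes$node) ||
        !setequal(nodes$node, seq_len(nrow(nodes)))) {
      abort("node_order must assign ids 1..n bijectively to (column, level)")
    }
  }

  # validate and resolve patterns to node ids
  pat_nodes <- patterns |>
    left_join(nodes, by = c("column", "level"))
  if (any(is.na(pat_nodes$node))) {
    bad <- pat_nodes |> filter(is.na(.data$node))
    abort(paste0("pattern references unknown column/level: ",
                 paste(paste0(bad$column, "=", bad$level), collapse = ", ")))
  }
  pat_check <- pat_nodes |>
    group_by(.data$pattern, .data$column) |>
    summarise(k = dplyr::n(), .groups = "drop")
  if (any(pat_check$k != 1L)) abort("a pattern must choose exactly one level per column")
  per_pat <- pat_nodes |> group_by(.data$pattern) |>
    summarise(k = dplyr::n_distinct(.data$column), .groups = "drop")
  if (any(per_pat$k != nrow(col_tab))) {
    abort("a pattern must choose one level in every column")
  }
  key <- split(pat_nodes$node, pat_nodes$pattern) |> map_chr(\(x) paste(sort(x), collapse = ","))
  if (anyDuplicated(key)) abort("learned patterns must be distinct")

  inhibitory <- .inhibitory_arrows(nodes)
  excitatory <- .excitatory_arrows(nodes, pat_nodes, features)

  structure(
    list(columns = col_tab, nodes = nodes, patterns = pat_nodes,
         inhibitory = inhibitory, excitatory = excitatory,
         features = features, n_nodes = nrow(nodes)),
    class = "rivalry_network"
  )
}

.inhibitory_arrows <- function(nodes) {
  by_col <- split(nodes, nodes$column)
  rows <- map(by_col, function(nd) {
    if (nrow(nd) < 2L) return(NULL)
    pr <- t(combn(sort(nd$node), 2L))
    tibble(from = pr[, 1], to = pr[, 2],
           class = paste0("inh:", nd$cell_class[1]))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(from = integer(), to = integer(), class = character())
  }
  arrange(out, .data$from, .data$to)
}

# feature tuple label for an excitatory pair; directed = TRUE when the two
# cell classes differ (ordered attribute-type pair, as in networks mixing
# e.g. grating and color nodes)
.exc_class <- function(a, b, nodes, features) {
  na <- nodes[nodes$node == a, ]
  nb <- nodes[nodes$node == b, ]
  coords <- features$coordinates
  dist_part <- NULL
  if (!is.null(coords) &&
      all(c(na$column, nb$column) %in% coords$column)) {
    pa <- coords[coords$column == na$column, c("x", "y")]
    pb <- coords[coords$column == nb$column, c("x", "y")]
    d <- .round_distance(sqrt((pa$x - pb$x)^2 + (pa$y - pb$y)^2))
    dist_part <- paste0("d=", format(d, digits = 12))
  }
  extra_part <- NULL
  if (!is.null(features$extra)) {
    extra_part <- paste0("f=", format(features$extra(a, b, nodes)))
  }
  if (na$cell_class == nb$cell_class) {
    level_part <- NULL
    if (features$level_feature) {
      level_part <- if (na$level == nb$level) "same" else "diff"
    }
    lab <- paste(c(paste0("exc:", na$cell_class), level_part, dist_part,
                   extra_part), collapse = "|")
    tibble(from = min(a, b), to = max(a, b), class = lab, directed = FALSE)
  } else {
    # unequal attribute types: two directed arrows in distinct classes
    base <- c(dist_part, extra_part)
    tibble(
      from = c(a, b), to = c(b, a),
      class = c(
        paste(c(paste0("exc:", na$cell_class, "->", nb$cell_class), base), collapse = "|"),
        paste(c(paste0("exc:", nb$cell_class, "->", na$cell_class), base), collapse = "|")
      ),
      directed = TRUE
    )
  }
}

.excitatory_arrows <- function(nodes, pat_nodes, features) {
  pats <- split(pat_nodes$node, pat_nodes$pattern)
  pair_rows <- map(pats, function(pn) {
    if (length(pn) < 2L) return(NULL)
    pr <- t(combn(sort(pn), 2L))
    tibble(a = pr[, 1], b = pr[, 2])
  }) |> bind_rows()
  if (is.null(pair_rows) || nrow(pair_rows) == 0L) {
    return(tibble(from = integer(), to = integer(), class = character(),
                  multiplicity = integer(), directed = logical()))
  }
  # multiplicity = number of learned patterns containing the pair
  mult <- pair_rows |> count(.data$a, .data$b, name = "multiplicity")
  arrows <- pmap(mult, function(a, b, multiplicity) {
    .exc_class(a, b, nodes, features) |> mutate(multiplicity = multiplicity)
  }) |> bind_rows()
  arrows |>
    select("from", "to", "class", "multiplicity", "directed") |>
    arrange(.data$from, .data$to)
}

#' Partition the excitatory arrows of a network into classes
#'
#' @param network A [rivalry_network()].
#' @return A tibble with one row per excitatory arrow (`from`, `to`,
#'   `multiplicity`, `directed`) and a deterministic, order-independent
#'   `class` label (`class_id` is the label's rank).
#' @export
excitatory_arrow_classes <- function(network) {
  stopifnot(inherits(network, "rivalry_network"))
  exc <- network$excitatory
  labs <- sort(unique(exc$class))
  exc |>
    mutate(class_id = match(.data$class, labs)) |>
    arrange(.data$class_id, .data$from, .data$to)
}

#' Number of distinct excitatory arrow classes
#' @param network A [rivalry_network()].
#' @return Integer count of distinct feature tuples realized.
#' @export
n_excitatory_classes <- function(network) {
  length(unique(network$excitatory$class))
}

#' @export
print.rivalry_network <- function(x, ...) {
  cat("<rivalry_network> ", x$n_nodes, " nodes, ",
      nrow(x$columns), " attribute columns, ",
      dplyr::n_distinct(x$patterns$pattern), " learned patterns\n", sep = "")
  cat("  inhibitory arrows: ", nrow(x$inhibitory), " in ",
      dplyr::n_distinct(x$inhibitory$class), " class(es)\n", sep = "")
  ndir <- sum(x$excitatory$directed) / 2
  cat("  excitatory arrows: ", nrow(x$excitatory) - ndir, " in ",
      n_excitatory_classes(x), " class(es)\n", sep = "")
  invisible(x)
}

#' @export
tidy.rivalry_network <- function(x, ...) x$nodes

#' @export
glance.rivalry_network <- function(x, ...) {
  tibble(
    n_nodes = x$n_nodes,
    n_columns = nrow(x$columns),
    n_patterns = dplyr::n_distinct(x$patterns$pattern),
    n_inhibitory = nrow(x$inhibitory),
    n_inhibitory_classes = dplyr::n_distinct(x$inhibitory$class),
    n_excitatory = nrow(x$excitatory),
    n_excitatory_classes = n_excitatory_classes(x)
  )
}

#' All arrows of a network as one tibble
#' @param network A [rivalry_network()].
#' @return Tibble with `from`, `to`, `kind`, `class`, `multiplicity`,
#'   `directed`.
#' @export
network_arrows <- function(network) {
  bind_rows(
    network$inhibitory |>
      mutate(kind = "inhibitory", multiplicity = 1L, directed = FALSE),
    network$excitatory |> mutate(kind = "excitatory")
  ) |>
    select("from", "to", "kind", "class", "multiplicity", "directed")
}
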