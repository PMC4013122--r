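# End-to-end analysis pipeline, config round-trip (YAML), GraphML export,
# and report writers.

#' Write / read a network configuration file
#'
#' Plain-YAML description of a rivalry network: attribute columns with level
#' lists, learned patterns as column-to-level maps, the feature
#' specification, and the explicit node numbering. `read_network_config()`
#' reconstructs an identical network.
#'
#' @param network A [rivalry_network()].
#' @param path Output (input) file path.
#' @return `write_network_config()` returns `path` invisibly;
#'   `read_network_config()` returns a [rivalry_network()].
#' @export
write_network_config <- function(network, path) {
  nodes <- network$nodes |> arrange(.data$node)
  col_order <- unique(nodes$column)
  cols <- map(col_order, function(cl) {
    nd <- nodes |> filter(.data$column == cl)
    list(column = cl, type = nd$cell_class[1], levels = as.list(nd$level))
  })
  pats <- network$patterns |> arrange(.data$pattern, .data$node)
  pat_list <- map(unique(pats$pattern), function(pp) {
    sub <- pats |> filter(.data$pattern == pp)
    list(pattern = pp, levels = as.list(setNames(sub$level, sub$column)))
  })
  feats <- list(level_feature = network$features$level_feature)
  if (!is.null(network$features$coordinates)) {
    co <- network$features$coordinates
    feats$coordinates <- map(seq_len(nrow(co)), \(i)
      list(column = co$column[i], x = co$x[i], y = co$y[i]))
  }
  node_order <- map(seq_len(nrow(nodes)), \(i)
    list(node = nodes$node[i], column = nodes$column[i],
         level = nodes$level[i]))
  yaml::write_yaml(list(columns = cols, patterns = pat_list,
                        features = feats, node_order = node_order), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$columns) || is.null(cfg$patterns)) {
    abort("config must contain 'columns' and 'patterns'")
  }
  columns <- bind_rows(map(cfg$columns, \(cl) tibble(
    column = cl$column, type = cl$type, level = as.character(unlist(cl$levels))
  )))
  patterns <- bind_rows(map(cfg$patterns, \(pp) tibble(
    pattern = pp$pattern, column = names(pp$levels),
    level = as.character(unlist(pp$levels))
  )))
  coords <- NULL
  if (!is.null(cfg$features$coordinates)) {
    coords <- bind_rows(map(cfg$features$coordinates, \(co)
      tibble(column = co$column, x = co$x, y = co$y)))
  }
  features <- feature_spec(
    coordinates = coords,
    level_feature = !isFALSE(cfg$features$level_feature)
  )
  node_order <- NULL
  if (!is.null(cfg$node_order)) {
    node_order <- bind_rows(map(cfg$node_order, \(nd)
      tibble(node = as.integer(nd$node), column = nd$column,
             level = nd$level)))
  }
  rivalry_network(columns, patterns, features, node_order = node_order)
}

#' Export a network as GraphML
#'
#' Nodes carry `column`, `level`, `cell_class`; edges carry `kind`
#' (inhibitory/excitatory), `class`, `multiplicity` and `bidirectional`
#' (undirected arrows are stored once with `bidirectional = TRUE`).
#'
#' @param network A [rivalry_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(network, path) {
  arr <- network_arrows(network)
  g <- igraph::graph_from_data_frame(
    arr |>
      mutate(bidirectional = !.data$directed) |>
      select("from", "to", "kind", "class", "multiplicity", "bidirectional"),
    directed = TRUE,
    vertices = network$nodes |>
      arrange(.data$node) |>
      mutate(name = as.character(.data$node)) |>
      select("name", "column", "level", "cell_class")
  )
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Full symmetry analysis of a rivalry network
#'
#' Runs the whole pipeline: symmetry group, maximal fusion state, isotypic
#' decomposition, fusion-breaking classification, and the predicted periodic
#' solution branches with their percept alternation cases.
#'
#' @param network A [rivalry_network()], or the name of a built-in network
#'   (see [paper_networks()]).
#' @param seed Seed for the decomposition's random equivariant draw.
#' @return Object of class `rivalry_analysis`.
#' @examples
#' analyze(paper_network("conventional-monkey-text"))
#' @export
analyze <- function(network, seed = 0L) {
  if (is.character(network)) network <- paper_network(network)
  stopifnot(inherits(network, "rivalry_network"))
  group <- automorphism_group(network)
  decomposition <- isotypic_decomposition(group, seed = seed)
  level_swaps <- level_swap_elements(group, network)
  rho <- attr(level_swaps, "canonical_rho")
  branches <- NULL
  cases <- NULL
  if (!is.null(rho)) {
    decomposition <- fusion_breaking_components(decomposition, level_swaps)
    branches <- branch_catalog(decomposition, group, network)
    cases <- map(branches, function(bl) {
      if (!is.list(bl)) return(NULL)
      map(bl, \(b) enumerate_alternation_cases(b, network))
    })
  }
  structure(
    list(network = network, group = group,
         group_name = group_name(group, network),
         fusion = fixed_point_subspace(group$elements, network$n_nodes),
         level_swaps = level_swaps, rho = rho,
         decomposition = decomposition, branches = branches,
         alternation_cases = cases, seed = seed),
    class = "rivalry_analysis"
  )
}

#' @export
print.rivalry_analysis <- function(x, ...) {
  cat("== rivalry network analysis ==\n")
  print(x$network)
  cat("\nsymmetry group: order ", x$group$order, " (", x$group_name, ")\n",
      sep = "")
  cat("maximal fusion state: ", length(x$fusion$classes),
      " synchrony class(es)\n", sep = "")
  if (is.null(x$rho)) {
    cat("no canonical eye swap: fusion-breaking classification unavailable\n")
    print(tidy(x$decomposition))
    return(invisible(x))
  }
  cat("canonical eye swap: ", perm_cycles(x$rho), "\n\n", sep = "")
  cat("isotypic components (per node dimension k):\n")
  print(tidy(x$decomposition))
  cat("\npredicted periodic solution branches:\n")
  for (nm in names(x$branches)) {
    bl <- x$branches[[nm]]
    if (!is.list(bl)) {
      cat("  ", nm, ": ", bl, "\n", sep = "")
      next
    }
    for (i in seq_along(bl)) {
      ncase <- length(x$alternation_cases[[nm]][[i]])
      cat("  [", nm, "] ", bl[[i]]$name,
          if (ncase > 1L) paste0(" (", ncase, " percept cases)"),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
tidy.rivalry_analysis <- function(x, ...) tidy(x$decomposition)

#' @export
glance.rivalry_analysis <- function(x, ...) {
  n_branch <- if (is.null(x$branches)) NA_integer_ else
    sum(map_int(x$branches, \(bl) if (is.list(bl)) length(bl) else 0L))
  tb <- tidy(x$decomposition)
  tibble(
    n_nodes = x$network$n_nodes,
    group_order = x$group$order,
    group_name = x$group_name,
    n_fusion_classes = length(x$fusion$classes),
    n_components = length(x$decomposition$components),
    n_fusion_breaking = if (is.null(x$rho)) NA_integer_ else
      sum(tb$fusion_breaking),
    n_branches = n_branch
  )
}

#' Simulate a rivalry network and classify the realized oscillation
#'
#' Builds the rate model, locates the fusion equilibrium, computes the
#' isotypic Jacobian spectrum, perturbs the equilibrium along a
#' fusion-breaking component (by default the one with the largest leading
#' real part), integrates, and classifies the spatiotemporal symmetry and
#' percept alternation of the realized attractor.
#'
#' @param analysis A [analyze()] result (or a network/name, analyzed on the
#'   fly).
#' @param params [rate_params()] for the model.
#' @param duration Integration time (default 400).
#' @param perturbation Size of the initial symmetry-breaking perturbation.
#' @param component Component id to perturb along; default automatic.
#' @param transient Fraction of the trajectory discarded as transient.
#' @return Object of class `rivalry_simulation`: model, equilibrium,
#'   spectrum, trajectory, spatiotemporal classification, dominance trace.
#' @export
simulate_rivalry <- function(analysis, params = rate_params(),
                             duration = 400, perturbation = 1e-3,
                             component = NULL, transient = 0.6) {
  if (!inherits(analysis, "rivalry_analysis")) analysis <- analyze(analysis)
  network <- analysis$network
  group <- analysis$group
  decomposition <- analysis$decomposition
  model <- rate_model(network, params)
  eq <- find_fusion_equilibrium(model, group)
  spectrum <- isotypic_jacobian_spectrum(model, eq, decomposition)
  lead_re <- map_dbl(spectrum$blocks, \(ev) max(Re(ev)))
  comps <- decomposition$components
  if (is.null(component)) {
    flagged <- which(map_lgl(comps, \(cp) isTRUE(cp$fusion_breaking)))
    if (length(flagged) == 0L) flagged <- seq_along(comps)
    component <- flagged[which.max(lead_re[flagged])]
  }
  B <- comps[[component]]$basis
  dir <- c(B[, 1], numeric(model$n))
  state0 <- as.numeric(eq) + perturbation * dir / sqrt(sum(dir^2))
  traj <- integrate_model(model, state0, duration)
  st <- classify_spatiotemporal(traj, group, transient = transient)
  dom <- if (st$periodic) {
    dominance_trace(traj, network, transient = transient, period = st$period)
  } else NULL
  structure(
    list(analysis = analysis, model = model, equilibrium = eq,
         spectrum = spectrum, component = component, trajectory = traj,
         spatiotemporal = st, dominance = dom),
    class = "rivalry_simulation"
  )
}

#' @export
print.rivalry_simulation <- function(x, ...) {
  cat("== rivalry simulation ==\n")
  print(x$model)
  cat("fusion equilibrium residual: ",
      format(attr(x$equilibrium, "residual")), "\n", sep = "")
  lead <- map_dbl(x$spectrum$blocks, \(ev) max(Re(ev)))
  cat("leading Jacobian real parts by component: ",
      paste(sprintf("%s=%.4f", names(x$spectrum$blocks), lead),
            collapse = ", "), "\n", sep = "")
  cat("perturbed along component ", x$component, "\n", sep = "")
  print(x$spatiotemporal)
  if (!is.null(x$dominance)) print(x$dominance)
  invisible(x)
}

#' @export
glance.rivalry_simulation <- function(x, ...) {
  tibble(
    equilibrium_residual = as.numeric(attr(x$equilibrium, "residual")),
    off_block = x$spectrum$off_block,
    perturbed_component = x$component,
    periodic = x$spatiotemporal$periodic,
    period = x$spatiotemporal$period,
    n_percepts = if (is.null(x$dominance)) NA_integer_ else
      nrow(x$dominance$sequence)
  )
}

#' Write a Markdown analysis report
#'
#' @param analysis A [analyze()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_markdown_report <- function(analysis, path) {
  x <- analysis
  tb_to_md <- function(tb) {
    cells <- map(tb, \(col) format(col))
    hdr <- paste0("| ", paste(names(tb), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(tb)), collapse = "|"), "|")
    body <- map_chr(seq_len(nrow(tb)), \(i)
      paste0("| ", paste(map_chr(cells, i), collapse = " | "), " |"))
    c(hdr, sep, body)
  }
  g <- glance(x$network)
  lines <- c(
    "# Rivalry network analysis", "",
    sprintf("- nodes: %d; attribute columns: %d; learned patterns: %d",
            g$n_nodes, g$n_columns, g$n_patterns),
    sprintf("- excitatory arrow classes: %d", g$n_excitatory_classes),
    sprintf("- symmetry group: order %d (%s)", x$group$order, x$group_name),
    sprintf("- maximal fusion state: %d synchrony class(es)",
            length(x$fusion$classes)),
    if (!is.null(x$rho)) {
      sprintf("- canonical eye swap: %s", perm_cycles(x$rho))
    } else "- no canonical eye swap found",
    "", "## Isotypic decomposition", "",
    tb_to_md(tidy(x$decomposition) |>
               select("component", "dim_per_k", "irrep_dim", "multiplicity",
                      "basis", "kernel",
                      dplyr::any_of(c("fusion_breaking", "leads_to_fusion"))))
  )
  if (!is.null(x$branches)) {
    lines <- c(lines, "", "## Predicted periodic solution branches", "")
    for (nm in names(x$branches)) {
      bl <- x$branches[[nm]]
      if (!is.list(bl)) {
        lines <- c(lines, sprintf("- %s: %s", nm, bl))
        next
      }
      for (i in seq_along(bl)) {
        b <- bl[[i]]
        cases <- x$alternation_cases[[nm]][[i]]
        lines <- c(lines, sprintf("- **%s** (%s): %d percept case(s)",
                                  b$name, nm, length(cases)))
        for (ps in cases) {
          seqcols <- setdiff(names(ps$sequence), c("step", "t_start"))
          states <- map_chr(seq_len(nrow(ps$sequence)), \(k)
            paste(unlist(ps$sequence[k, seqcols]), collapse = "/"))
          lines <- c(lines, sprintf("    - %s%s",
                                    if (!is.null(ps$case))
                                      paste0("[", ps$case, "] ") else "",
                                    paste(states, collapse = " -> ")))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}
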