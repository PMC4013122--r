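# From phase patterns to percept alternation sequences. A percept is the
# choice, in each attribute column, of the level whose activity is the unique
# maximum; equal maxima within the tie tolerance give a fused (indeterminate)
# column.

.percept_keys <- function(X, network, tie_tol = 1e-9) {
  nodes <- network$nodes |> arrange(.data$node)
  cols <- unique(nodes$column)
  nsamp <- ncol(X)
  per_col <- map(cols, function(cl) {
    idx <- nodes$node[nodes$column == cl]
    sub <- X[idx, , drop = FALSE]
    top <- apply(sub, 2, max)
    lab <- character(nsamp)
    for (s in seq_len(nsamp)) {
      winners <- which(sub[, s] > top[s] - tie_tol)
      lab[s] <- if (length(winners) == 1L) {
        nodes$level[nodes$node == idx[winners]]
      } else "(fused)"
    }
    lab
  })
  names(per_col) <- cols
  per_col
}

# compress per-sample percepts into the cyclic sequence of distinct percepts
.compress_percepts <- function(per_col, t) {
  key <- do.call(paste, c(per_col, sep = "|"))
  nsamp <- length(key)
  chg <- c(TRUE, key[-1] != key[-nsamp])
  steps <- cumsum(chg)
  starts <- which(chg)
  seq_tb <- tibble(t_start = t[starts], key = key[starts])
  # cyclic merge: last run equal to first run
  if (nrow(seq_tb) > 1L && seq_tb$key[nrow(seq_tb)] == seq_tb$key[1]) {
    seq_tb <- seq_tb[-nrow(seq_tb), ]
  }
  # rotate to start at the lexicographically smallest percept
  if (nrow(seq_tb) > 1L) {
    k <- which.min(rank(seq_tb$key, ties.method = "first"))
    seq_tb <- bind_rows(seq_tb[k:nrow(seq_tb), ], seq_tb[seq_len(k - 1L), ])
  }
  seq_tb$step <- seq_len(nrow(seq_tb))
  parts <- strsplit(seq_tb$key, "|", fixed = TRUE)
  wide <- as_tibble(setNames(
    map(seq_along(per_col), \(j) map_chr(parts, j)),
    names(per_col)
  ))
  bind_cols(seq_tb["step"], seq_tb["t_start"], wide)
}

new_percept_sequence <- function(tb, case = NULL) {
  structure(list(sequence = tb, case = case), class = "percept_sequence")
}

#' @export
print.percept_sequence <- function(x, ...) {
  cat("<percept_sequence> ", nrow(x$sequence), " percept(s) per cycle",
      if (!is.null(x$case)) paste0(" [case: ", x$case, "]"), "\n", sep = "")
  print(x$sequence)
  invisible(x)
}

#' @export
tidy.percept_sequence <- function(x, ...) x$sequence

#' Percept alternation sequence of a predicted branch
#'
#' Renders the branch on the waveform templates over one period, takes the
#' per-column dominance (unique activity maximum; ties are fused), and
#' compresses to the cyclic sequence of distinct percepts with switching
#' epochs. With a nonzero wave offset `delta`, independent waves switch at
#' different moments, producing interleaved derived percepts.
#'
#' @param branch A `solution_branch`.
#' @param network The [rivalry_network()].
#' @param waveforms A [waveform_template()].
#' @param samples Samples per period (>= 8; default 256).
#' @param const_values Named numeric values for constant (fused) wave labels;
#'   default 0.
#' @param tie_tol Dominance tie tolerance.
#' @return A `percept_sequence`.
#' @export
percept_sequence <- function(branch, network, waveforms = waveform_template(),
                             samples = 256L, const_values = NULL,
                             tie_tol = 1e-9) {
  stopifnot(samples >= 8L)
  # midpoint sampling avoids landing exactly on waveform crossings, which
  # would register spurious one-sample fused percepts
  t <- (seq_len(samples) - 0.5) / samples
  X <- branch_signals(branch, t, waveforms, const_values)
  new_percept_sequence(.compress_percepts(.percept_keys(X, network, tie_tol), t))
}

#' Enumerate percept alternation cases of a branch with fused nodes
#'
#' For a branch containing constant (fused) nodes competing with oscillating
#' nodes in the same column, the percepts depend on whether the constant
#' level sits above or below the oscillation amplitude; each independent
#' constant label gives one binary choice. All sign cases are enumerated
#' (a branch with no such competition gives exactly one case).
#'
#' @inheritParams percept_sequence
#' @param high,low Constant levels representing "above" / "below" the unit
#'   oscillation amplitude (defaults 1.5, -1.5).
#' @return List of `percept_sequence` objects, one per case, labeled by the
#'   sign choices.
#' @export
enumerate_alternation_cases <- function(branch, network,
                                        waveforms = waveform_template(),
                                        samples = 256L, tie_tol = 1e-9,
                                        high = 1.5, low = -1.5) {
  pat <- branch$pattern
  nodes <- network$nodes
  const_waves <- unique(pat$wave[pat$const])
  competing <- keep(const_waves, function(w) {
    cls <- nodes$column[match(pat$node[pat$wave == w], nodes$node)]
    osc_cols <- nodes$column[match(pat$node[!pat$const], nodes$node)]
    any(cls %in% osc_cols)
  })
  if (length(competing) == 0L) {
    return(list(percept_sequence(branch, network, waveforms, samples,
                                 tie_tol = tie_tol)))
  }
  choices <- expand.grid(rep(list(c(TRUE, FALSE)), length(competing)))
  names(choices) <- competing
  map(seq_len(nrow(choices)), function(i) {
    vals <- setNames(ifelse(unlist(choices[i, ]), high, low), competing)
    lab <- paste(paste0(competing, ifelse(unlist(choices[i, ]), ">osc", "<osc")),
                 collapse = ", ")
    ps <- percept_sequence(branch, network, waveforms, samples,
                           const_values = as.list(vals), tie_tol = tie_tol)
    ps$case <- lab
    ps
  })
}

#' @export
autoplot.solution_branch <- function(object, network = NULL,
                                     template = waveform_template(), ...) {
  t <- 0:255 / 256
  X <- branch_signals(object, t, template)
  df <- tibble(
    t = rep(t, each = nrow(X)),
    node = factor(rep(seq_len(nrow(X)), times = length(t))),
    activity = as.vector(X)
  )
  if (!is.null(network)) {
    nd <- network$nodes
    df$column <- nd$column[match(as.integer(as.character(df$node)), nd$node)]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$activity,
                                        colour = .data$node)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = object$name, x = "time (periods)", y = "activity")
  if (!is.null(network)) p <- p + ggplot2::facet_wrap(~column)
  p
}
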