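# Built-in example networks for the classic binocular-rivalry experiments.
# Node numbering follows the published permutation cycles (e.g. the eye swap
# rho = (12)(34)(56)(78) for the four-dot networks), which the fixtures pin
# via explicit level ordering: the first level listed in each column is the
# "row 1" node, taken from the first learned pattern.

.cols_tbl <- function(...) {
  # .cols_tbl("UL" = c("red","green"), ... , .type = "dot-color")
  args <- list(...)
  type <- args$.type %||% "attr"
  args$.type <- NULL
  bind_rows(imap(args, \(lv, nm) tibble(column = nm, type = type, level = lv)))
}

.pats_tbl <- function(...) {
  # .pats_tbl(list(UL = "red", ...), list(...))
  pats <- list(...)
  bind_rows(imap(pats, \(p, i) tibble(pattern = i, column = names(p),
                                      level = unlist(p, use.names = FALSE))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.square_coords <- function(cols = c("UL", "LL", "LR", "UR")) {
  tibble(column = cols, x = c(0, 0, 1, 1), y = c(1, 0, 0, 1))
}

.triangle_coords <- function(cols = c("UL", "LL", "R")) {
  tibble(column = cols, x = c(0, 0, sqrt(3) / 2), y = c(1, 0, 0.5))
}

.fixture_builders <- list(

  `conventional-monkey-text` = function() {
    rivalry_network(
      .cols_tbl(image = c("monkey", "text"), .type = "image"),
      .pats_tbl(list(image = "monkey"), list(image = "text"))
    )
  },

  `scrambled-monkey-text` = function() {
    # nodes: 1=(blue,monkey) 2=(blue,text) 3=(white,text) 4=(white,monkey)
    # learned patterns {1,3} and {2,4}; rho=(12)(34), kappa=(13)(24)
    rivalry_network(
      .cols_tbl(blue = c("monkey", "text"), white = c("text", "monkey"),
                .type = "region-image"),
      .pats_tbl(list(blue = "monkey", white = "text"),
                list(blue = "text", white = "monkey"))
    )
  },

  `six-area-monkey-text` = function() {
    # refined 12-node model: one column per image area, alternating content
    lv1 <- rep(c("monkey", "text"), 3)
    cols <- bind_rows(map(1:6, \(j) tibble(
      column = paste0("area", j), type = "region-image",
      level = c(lv1[j], setdiff(c("monkey", "text"), lv1[j]))
    )))
    pats <- bind_rows(
      tibble(pattern = 1L, column = paste0("area", 1:6), level = lv1),
      tibble(pattern = 2L, column = paste0("area", 1:6),
             level = rev(lv1))
    )
    rivalry_network(cols, pats)
  },

  `shevell-two-gratings` = function() {
    # nodes: 1=horizontal 2=vertical; top color 3=green 4=pink 5=gray;
    # bottom color 6=gray 7=green 8=pink.
    # learned: (horizontal, pink, gray) = {1,4,6}; (vertical, gray, green) = {2,5,7}
    cols <- bind_rows(
      tibble(column = "grating", type = "grating",
             level = c("horizontal", "vertical")),
      tibble(column = "color-top", type = "color",
             level = c("green", "pink", "gray")),
      tibble(column = "color-bottom", type = "color",
             level = c("gray", "green", "pink"))
    )
    pats <- .pats_tbl(
      list(grating = "horizontal", `color-top` = "pink", `color-bottom` = "gray"),
      list(grating = "vertical", `color-top` = "gray", `color-bottom` = "green")
    )
    rivalry_network(cols, pats)
  },

  `hong-shevell` = function() {
    # nodes: left 1=orange 2=gray 3=blue; right 4=orange 5=gray 6=blue
    # learned: (orange, gray) = {1,5}; (blue, gray) = {3,5}
    cols <- bind_rows(
      tibble(column = "color-left", type = "half-color",
             level = c("orange", "gray", "blue")),
      tibble(column = "color-right", type = "half-color",
             level = c("orange", "gray", "blue"))
    )
    pats <- .pats_tbl(
      list(`color-left` = "orange", `color-right` = "gray"),
      list(`color-left` = "blue", `color-right` = "gray")
    )
    rivalry_network(cols, pats)
  },

  `four-dot-conventional` = function() {
    rivalry_network(
      .cols_tbl(UL = c("red", "green"), LL = c("red", "green"),
                LR = c("red", "green"), UR = c("red", "green"),
                .type = "dot-color"),
      .pats_tbl(list(UL = "red", LL = "red", LR = "red", UR = "red"),
                list(UL = "green", LL = "green", LR = "green", UR = "green")),
      feature_spec(coordinates = .square_coords())
    )
  },

  `four-dot-scrambled-diagonal` = function() {
    rivalry_network(
      .cols_tbl(UL = c("red", "green"), LL = c("green", "red"),
                LR = c("red", "green"), UR = c("green", "red"),
                .type = "dot-color"),
      .pats_tbl(list(UL = "red", LL = "green", LR = "red", UR = "green"),
                list(UL = "green", LL = "red", LR = "green", UR = "red")),
      feature_spec(coordinates = .square_coords())
    )
  },

  `four-dot-scrambled-adjacent` = function() {
    rivalry_network(
      .cols_tbl(UL = c("red", "green"), LL = c("red", "green"),
                LR = c("green", "red"), UR = c("green", "red"),
                .type = "dot-color"),
      .pats_tbl(list(UL = "red", LL = "red", LR = "green", UR = "green"),
                list(UL = "green", LL = "green", LR = "red", UR = "red")),
      feature_spec(coordinates = .square_coords())
    )
  },

  `four-dot-scrambled-unbalanced` = function() {
    # single red dot in the UR position of the first learned image
    rivalry_network(
      .cols_tbl(UL = c("green", "red"), LL = c("green", "red"),
                LR = c("green", "red"), UR = c("red", "green"),
                .type = "dot-color"),
      .pats_tbl(list(UL = "green", LL = "green", LR = "green", UR = "red"),
                list(UL = "red", LL = "red", LR = "red", UR = "green")),
      feature_spec(coordinates = .square_coords())
    )
  },

  `three-dot-conventional` = function() {
    rivalry_network(
      .cols_tbl(UL = c("red", "green"), LL = c("red", "green"),
                R = c("red", "green"), .type = "dot-color"),
      .pats_tbl(list(UL = "red", LL = "red", R = "red"),
                list(UL = "green", LL = "green", R = "green")),
      feature_spec(coordinates = .triangle_coords())
    )
  },

  `three-dot-scrambled` = function() {
    rivalry_network(
      .cols_tbl(UL = c("red", "green"), LL = c("red", "green"),
                R = c("green", "red"), .type = "dot-color"),
      .pats_tbl(list(UL = "red", LL = "red", R = "green"),
                list(UL = "green", LL = "green", R = "red")),
      feature_spec(coordinates = .triangle_coords())
    )
  }
)

#' Built-in rivalry networks for published experiments
#'
#' Returns one of the built-in networks, with node numbering matching the
#' published permutation cycles for the corresponding experiment.
#'
#' @param name Fixture identifier; see [paper_networks()] for the registry.
#' @return A [rivalry_network()].
#' @examples
#' paper_network("scrambled-monkey-text")
#' @export
paper_network <- function(name) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% names(.fixture_builders)) {
    abort(paste0(
      "unknown network name ", if (is.character(name)) paste0("'", name, "'") else "",
      "; available: ", paste(names(.fixture_builders), collapse = ", ")))
  }
  .fixture_builders[[name]]()
}

#' List the built-in network fixtures
#' @return Character vector of fixture names accepted by [paper_network()].
#' @export
paper_networks <- function() names(.fixture_builders)
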