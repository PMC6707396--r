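#' Deterministic force-directed layout
#'
#' Runs a Fruchterman-Reingold force simulation (via igraph) under a fixed
#' seed and writes the resulting coordinates into `x` and `y` node
#' attributes (floats, arbitrary units, y increasing downward in viewers).
#' Coordinates are translated into the positive quadrant and, when the
#' bounding box exceeds 1000 units, uniformly scaled down to fit
#' \[0, 1000\]^2; small graphs are never scaled up, so relative distances
#' on sparse graphs stay meaningful. A single node is placed at the origin.
#' The same network, seed and iteration count always give identical
#' coordinates.
#'
#' @param net A [network()].
#' @param seed Integer seed for the simulation.
#' @param iterations Number of simulation iterations (>= 1).
#' @return The network with `x`/`y` columns; layout parameters are kept in
#'   the `$layout` field.
#' @export
apply_layout <- function(net, seed = 42, iterations = 100) {
  stopifnot(iterations >= 1)
  nn <- nrow(net$nodes)
  if (nn == 0) {
    net$nodes$x <- numeric()
    net$nodes$y <- numeric()
  } else if (nn == 1) {
    net$nodes$x <- 0
    net$nodes$y <- 0
  } else {
    g <- as_igraph(net)
    coords <- withr::with_seed(as.integer(seed), {
      igraph::layout_with_fr(g, niter = as.integer(iterations))
    })
    coords[, 1] <- coords[, 1] - min(coords[, 1])
    coords[, 2] <- coords[, 2] - min(coords[, 2])
    extent <- max(coords, 1e-12)
    if (extent > 1000) coords <- coords * (1000 / extent)
    net$nodes$x <- round(coords[, 1], 6)
    net$nodes$y <- round(coords[, 2], 6)
  }
  net$layout <- list(seed = as.integer(seed),
                     iterations = as.integer(iterations))
  net
}
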