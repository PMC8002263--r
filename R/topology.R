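#' The UNet++ node lattice
#'
#' A UNet++ of depth `L` arranges convolution blocks on a triangular grid of
#' nodes `X(i, j)`, `0 <= i <= L`, `0 <= j <= L - i`: `i` indexes the
#' down-sampling level, `j` the position along the nested skip pathway.
#' `X(i, 0)` is the plain encoder; each `X(i, j)` with `j > 0` fuses all
#' same-level predecessors `X(i, 0..j-1)` with the up-sampled output of
#' `X(i+1, j-1)`, so its fan-in is `j + 1`. `X(0, L)` is the final decoder
#' node feeding the classification head.
#'
#' @param depth Encoder depth `L >= 1`.
#' @return An object of class `unetpp_grid`: list with `depth`, a data.frame
#'   `nodes` (columns `i`, `j`, `indegree`) in forward execution order, and
#'   an `edges` data.frame (`from_i`, `from_j`, `to_i`, `to_j`,
#'   `kind` in `down`/`up`/`skip`).
#' @examples
#' g <- build_topology(4)
#' nrow(g$nodes)  # 15 nodes
#' @export
build_topology <- function(depth) {
  if (length(depth) != 1 || !is.finite(depth) || depth < 1 ||
      depth != round(depth))
    stop_invalid("depth must be an integer >= 1")
  L <- as.integer(depth)

  nodes <- do.call(rbind, lapply(0:L, function(j) {
    if (L - j >= 0) data.frame(i = 0:(L - j), j = j)
  }))
  # forward order: encoder top-down first (j = 0), then each skip column
  nodes <- nodes[order(nodes$j, nodes$i), ]
  rownames(nodes) <- NULL

  edges <- list()
  for (r in seq_len(nrow(nodes))) {
    i <- nodes$i[r]; j <- nodes$j[r]
    if (j == 0 && i > 0) {
      edges[[length(edges) + 1L]] <-
        data.frame(from_i = i - 1L, from_j = 0L, to_i = i, to_j = 0L,
                   kind = "down")
    } else if (j > 0) {
      for (k in 0:(j - 1)) {
        edges[[length(edges) + 1L]] <-
          data.frame(from_i = i, from_j = k, to_i = i, to_j = j,
                     kind = "skip")
      }
      edges[[length(edges) + 1L]] <-
        data.frame(from_i = i + 1L, from_j = j - 1L, to_i = i, to_j = j,
                   kind = "up")
    }
  }
  edges <- do.call(rbind, edges)
  indeg <- integer(nrow(nodes))
  for (r in seq_len(nrow(nodes))) {
    indeg[r] <- sum(edges$to_i == nodes$i[r] & edges$to_j == nodes$j[r])
  }
  nodes$indegree <- indeg
  structure(list(depth = L, nodes = nodes, edges = edges),
            class = "unetpp_grid")
}

#' @export
print.unetpp_grid <- function(x, ...) {
  cat(sprintf("UNet++ grid, depth %d: %d nodes, %d edges\n",
              x$depth, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Input sources of one grid node
#'
#' Lists, in concatenation order, where node `X(i, j)` takes its input from:
#' the same-level skip sources `X(i, 0) .. X(i, j-1)` followed by the
#' up-sampled `X(i+1, j-1)` for decoder nodes; the down-sampled `X(i-1, 0)`
#' for encoder nodes; the network input for `X(0, 0)`.
#'
#' @param i,j Node coordinates.
#' @param grid A [build_topology()] result.
#' @return A data.frame with columns `from_i`, `from_j`, `via`
#'   (`"identity"`, `"downsample"` or `"upsample"`); for `X(0, 0)` a
#'   zero-row frame with attribute `input = TRUE`.
#' @export
node_inputs <- function(i, j, grid) {
  if (!inherits(grid, "unetpp_grid")) stop_invalid("grid required")
  i <- as.integer(i); j <- as.integer(j)
  L <- grid$depth
  if (i < 0 || j < 0 || i + j > L)
    stop_invalid(sprintf("node X(%d,%d) not in depth-%d grid", i, j, L))
  if (i == 0 && j == 0) {
    out <- data.frame(from_i = integer(0), from_j = integer(0),
                      via = character(0))
    attr(out, "input") <- TRUE
    return(out)
  }
  if (j == 0) {
    return(data.frame(from_i = i - 1L, from_j = 0L, via = "downsample"))
  }
  rbind(
    data.frame(from_i = i, from_j = 0:(j - 1), via = "identity"),
    data.frame(from_i = i + 1L, from_j = j - 1L, via = "upsample"))
}
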