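#' Weighted Fruchterman-Reingold force-directed layout
#'
#' Places network nodes in the plane by the classic force model: every node
#' pair repels with force `k^2 / d`, every edge attracts with force
#' `w * d^2 / k` (absolute edge weight `w`, distance `d`, ideal spring
#' length `k = sqrt(area / n)`), displacements capped by a linearly cooling
#' temperature. Strongly connected nodes therefore end up closer than weakly
#' connected ones. Edge sign is ignored for the layout (attraction is only
#' defined for nonnegative weights); sign is conveyed by arrow style in the
#' plots instead. Coordinates are centred on the origin and deterministic
#' given the seed.
#'
#' @param network an `sdm_network`, or a square (possibly weighted)
#'   adjacency matrix; only retained edges attract for a purged network.
#' @param iterations number of cooling steps (default 100).
#' @param seed integer seed for the random initial placement.
#' @return object of class `sdm_layout`: `coords` (n x 2 matrix),
#'   `iterations`, `seed`.
#' @export
#' @examples
#' fruchterman_reingold_layout(matrix(c(0, 1, 1, 0), 2), seed = 1)$coords
fruchterman_reingold_layout <- function(network, iterations = 100, seed = 1) {
  W <- if (inherits(network, "sdm_network")) {
    abs(network$weights * network$retained)
  } else abs(as.matrix(network))
  n <- nrow(W)
  stopifnot(n >= 1, ncol(W) == n)
  A <- W + t(W) # symmetric attraction strengths
  if (n == 1) {
    return(structure(list(coords = matrix(0, 1, 2), iterations = 0L,
                          seed = as.integer(seed)), class = "sdm_layout"))
  }
  set.seed(derive_seed(seed, "fr_layout"))
  area <- n
  k <- sqrt(area / n)
  pos <- matrix(runif(2 * n, -sqrt(area) / 2, sqrt(area) / 2), n, 2)
  temp0 <- 0.1 * sqrt(area)
  for (it in seq_len(iterations)) {
    temp <- temp0 * (1 - (it - 1) / iterations)
    disp <- matrix(0, n, 2)
    for (v in seq_len(n)) {
      delta <- sweep(pos, 2, pos[v, ], "-") # vectors v -> u
      d <- sqrt(rowSums(delta^2))
      d[v] <- Inf
      d <- pmax(d, 1e-9)
      unit <- delta / d
      # repulsion pushes v away from every u; attraction pulls along edges
      f <- -k^2 / d + A[v, ] * d^2 / k
      f[v] <- 0 # no self force
      disp[v, ] <- colSums(unit * f)
    }
    len <- pmax(sqrt(rowSums(disp^2)), 1e-9)
    pos <- pos + disp / len * pmin(len, temp)
  }
  pos <- sweep(pos, 2, colMeans(pos))
  structure(list(coords = pos, iterations = as.integer(iterations),
                 seed = as.integer(seed)), class = "sdm_layout")
}
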