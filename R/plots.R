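#' Render summary figures of a fitted analysis
#'
#' Draws, on the current graphics device: (1) bar panels of the average
#' activation, outstrength and instrength of each skill across physicians;
#' (2) the average skills network with nodes placed by the weighted
#' Fruchterman-Reingold layout and arrow width proportional to the absolute
#' average retained edge weight (dashed arrows mark negative weights);
#' (3) per-physician small-multiple networks; and (4) observed-versus-
#' predicted competence scatters when predictions are supplied. Missing
#' inputs are skipped with a warning.
#'
#' @param node_params long node-parameter table.
#' @param network_fit an `sdm_network_fit` (or `NULL` to skip network
#'   panels).
#' @param predictions output of [predict_competence()] (or `NULL`).
#' @param seed layout seed.
#' @param max_physicians cap on small-multiple panels.
#' @return invisibly, the average weight matrix used for the network plot.
#' @export
render_reports <- function(node_params, network_fit = NULL,
                           predictions = NULL, seed = 1,
                           max_physicians = 12) {
  if (is.null(node_params)) {
    warning("render_reports: no node parameters; nothing to draw")
    return(invisible(NULL))
  }
  skills <- sort(unique(node_params$skill))
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (type in c("activation", "outstrength", "instrength")) {
    avg <- tapply(node_params[[type]], node_params$skill, mean)
    graphics::barplot(avg, names.arg = skills, xlab = "skill", ylab = type,
                      main = paste("average", type), col = "grey70")
  }
  avg_W <- NULL
  if (!is.null(network_fit)) {
    n <- network_fit$n_skills
    Ws <- lapply(network_fit$networks, function(net) {
      net$weights * net$retained
    })
    avg_W <- Reduce(`+`, Ws) / length(Ws)
    graphics::par(mfrow = c(1, 1), mar = c(1, 1, 3, 1))
    plot_one_network(avg_W, seed = seed, main = "average skills network")
    ids <- utils::head(names(network_fit$networks), max_physicians)
    graphics::par(mfrow = c(3, 4), mar = c(0.5, 0.5, 2, 0.5))
    for (pid in ids) {
      plot_one_network(Ws[[pid]], seed = seed, main = pid, cex = 0.8)
    }
  }
  if (!is.null(predictions)) {
    outs <- unique(predictions$outcome)
    graphics::par(mfrow = c(1, length(outs)), mar = c(4, 4, 3, 1))
    for (oc in outs) {
      d <- predictions[predictions$outcome == oc &
                         !is.na(predictions$observed_score), ]
      if (nrow(d) == 0) next
      graphics::plot(d$predicted_score, d$observed_score,
                     xlab = "predicted", ylab = "observed", main = oc,
                     pch = 19)
      if (nrow(d) >= 5) {
        sm <- loess(observed_score ~ predicted_score, data = d,
                    degree = 1, span = 1)
        ox <- order(d$predicted_score)
        graphics::lines(d$predicted_score[ox], predict(sm)[ox],
                        col = "grey40")
      }
    }
  }
  invisible(avg_W)
}

# draw one weighted directed network with FR placement; arrow width
# proportional to |weight|, dashed for negative weights
plot_one_network <- function(W, seed = 1, main = "", cex = 1) {
  n <- nrow(W)
  lay <- fruchterman_reingold_layout(W, seed = seed)
  xy <- lay$coords
  rng <- max(abs(xy)) * 1.25 + 0.1
  graphics::plot(NA, xlim = c(-rng, rng), ylim = c(-rng, rng), axes = FALSE,
                 xlab = "", ylab = "", main = main, asp = 1)
  wmax <- max(abs(W))
  if (wmax > 0) {
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (W[j, k] == 0) next
      v <- xy[k, ] - xy[j, ]
      d <- sqrt(sum(v^2))
      if (d < 1e-9) next
      shrink <- 0.12 * rng / d
      from <- xy[j, ] + v * shrink
      to <- xy[k, ] - v * shrink
      graphics::arrows(from[1], from[2], to[1], to[2],
                       lwd = 0.5 + 3 * abs(W[j, k]) / wmax,
                       lty = if (W[j, k] < 0) 2 else 1,
                       length = 0.08, col = "grey30")
    }
  }
  graphics::symbols(xy[, 1], xy[, 2], circles = rep(0.09 * rng, n),
                    inches = FALSE, add = TRUE, bg = "white", fg = "black")
  graphics::text(xy[, 1], xy[, 2], labels = seq_len(n), cex = cex)
}
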