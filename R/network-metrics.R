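# Network-level and node-level summaries of a partial-correlation network:
# global strength, node strength, and the path-based closeness/betweenness
# pair (computed but, by default, not reported downstream because they
# rarely survive the stability criteria on cohorts of this size).

.asWeights <- function(x) {
  if (methods::is(x, "WeightedNetwork")) x@weights else as.matrix(x)
}

#' @rdname globalStrength
#' @export
setMethod("globalStrength", "WeightedNetwork", function(x) {
  w <- x@weights
  sum(abs(w[upper.tri(w)]))
})

#' @rdname globalStrength
#' @export
setMethod("globalStrength", "matrix", function(x)
  globalStrength(WeightedNetwork(x)))

#' @rdname nodeStrength
#' @export
setMethod("nodeStrength", "WeightedNetwork", function(x) {
  w <- abs(x@weights)
  s <- rowSums(w)
  if (all(s == 0)) {
    warning("all-zero network: node-strength z-scores are undefined")
    z <- rep(NA_real_, length(s))
  } else {
    z <- (s - mean(s)) / stats::sd(s)
  }
  data.frame(node = rownames(x@weights), strength = unname(s), z = unname(z),
             row.names = NULL)
})

#' Closeness and betweenness centrality of a weighted network
#'
#' Path-based centralities with the conventional edge-length mapping
#' `1/|w_ij|` on nonzero edges: closeness is the inverse of the mean
#' shortest-path distance to the *reachable* nodes (disconnected pairs are
#' excluded from the mean; isolated nodes get 0), betweenness is the number
#' of shortest paths passing through a node (Brandes' algorithm via
#' igraph).
#'
#' @param net A [WeightedNetwork-class] (or bare weight matrix).
#' @return data.frame with columns `node`, `closeness`, `betweenness`; for
#'   an empty network both are all 0, with a warning.
#' @export
closenessBetweenness <- function(net) {
  w <- .asWeights(net)
  p <- nrow(w)
  labs <- rownames(w)
  if (all(w == 0)) {
    warning("empty network: closeness and betweenness are all 0")
    return(data.frame(node = labs, closeness = rep(0, p),
                      betweenness = rep(0, p), row.names = NULL))
  }
  g <- igraph::graph_from_adjacency_matrix(abs(w), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  len <- 1 / abs(igraph::E(g)$weight)
  D <- igraph::distances(g, weights = len)
  closeness <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / mean(d)
  }, numeric(1L))
  btw <- igraph::betweenness(g, weights = len, directed = FALSE)
  data.frame(node = labs, closeness = closeness,
             betweenness = unname(btw), row.names = NULL)
}

# centrality vector used by the stability bootstrap
.centralityVector <- function(net, measure) {
  switch(measure,
         strength = {
           w <- .asWeights(net)
           rowSums(abs(w))
         },
         closeness = suppressWarnings(closenessBetweenness(net)$closeness),
         betweenness = suppressWarnings(closenessBetweenness(net)$betweenness),
         stop("unknown centrality measure: ", measure))
}
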