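#' Deterministic sparse ring connectivity of the network
#'
#' Builds the fixed wiring: STN neuron i excites GPe i and GPi i; GPe neuron
#' i inhibits STN, GPe and GPi neurons i-1 and i+1; GPi neuron i inhibits
#' thalamic neuron i. Neighbour indices wrap around (ring topology), which
#' preserves the stated in-degrees (2 GPe afferents per STN/GPe/GPi cell) for
#' every neuron. Indices are 0-based everywhere.
#'
#' @param n Neurons per population (default 20, minimum 3 so that the two
#'   neighbour targets are distinct).
#' @return An object of class `connectivity_map`: a list of edge data frames
#'   (`pre`, `post`) per projection plus `n`.
#' @examples
#' cm <- buildConnectivity(20)
#' nrow(cm$GPe_STN)  # 40 edges: each of 20 STN cells has 2 GPe afferents
#' @export
buildConnectivity <- function(n = 20) {
  if (n < 3) stop("n must be at least 3 (neighbour indices collide)",
                  call. = FALSE)
  i <- 0:(n - 1)
  lo <- (i - 1) %% n
  hi <- (i + 1) %% n
  # GPe i -> targets i-1 and i+1; stored per projection as (pre, post)
  gpe_edges <- data.frame(pre = rep(i, 2), post = c(lo, hi))
  structure(list(
    n = n,
    STN_GPe = data.frame(pre = i, post = i),
    STN_GPi = data.frame(pre = i, post = i),
    GPe_STN = gpe_edges,
    GPe_GPe = gpe_edges,
    GPe_GPi = gpe_edges,
    GPi_Th = data.frame(pre = i, post = i)), class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> %d neurons per population, ring topology\n",
              x$n))
  for (pr in setdiff(names(x), "n"))
    cat(sprintf("  %-8s %d edges\n", sub("_", "->", pr), nrow(x[[pr]])))
  invisible(x)
}

# Afferent index tables consumed by the compiled integrator: for each
# postsynaptic neuron, the indices of its presynaptic partners.
.afferents <- function(cm) {
  n <- cm$n
  aff2 <- function(edges) {
    # two afferents per post neuron, ordered
    o <- order(edges$post, edges$pre)
    m <- matrix(edges$pre[o], nrow = n, ncol = 2, byrow = TRUE)
    m
  }
  one <- function(edges) {
    edges$pre[order(edges$post)]
  }
  g2 <- aff2(cm$GPe_STN)
  list(stn_gpe1 = as.integer(g2[, 1]), stn_gpe2 = as.integer(g2[, 2]),
       gpe_stn = as.integer(one(cm$STN_GPe)),
       gpe_gpe1 = as.integer(aff2(cm$GPe_GPe)[, 1]),
       gpe_gpe2 = as.integer(aff2(cm$GPe_GPe)[, 2]),
       gpi_stn = as.integer(one(cm$STN_GPi)),
       gpi_gpe1 = as.integer(aff2(cm$GPe_GPi)[, 1]),
       gpi_gpe2 = as.integer(aff2(cm$GPe_GPi)[, 2]),
       th_gpi = as.integer(one(cm$GPi_Th)))
}

#' Edge list of a connectivity map
#'
#' @param cm A `connectivity_map`.
#' @return Data frame with columns `projection`, `pre`, `post` (0-based).
#' @export
connectivityEdges <- function(cm) {
  proj <- setdiff(names(cm), "n")
  do.call(rbind, lapply(proj, function(p)
    cbind(projection = sub("_", "->", p), cm[[p]])))
}

#' Export connectivity as CSV and JSON
#'
#' Writes the edge list as CSV (`projection, pre, post`) and, optionally, a
#' JSON adjacency summary (population sizes plus per-projection in/out
#' degrees and edges).
#'
#' @param cm A `connectivity_map`.
#' @param csv,json Output paths (`NULL` to skip either).
#' @return Invisibly, the list of written paths.
#' @export
writeConnectivity <- function(cm, csv = NULL, json = NULL) {
  written <- list()
  if (!is.null(csv)) {
    write.csv(connectivityEdges(cm), csv, row.names = FALSE)
    written$csv <- csv
  }
  if (!is.null(json)) {
    proj <- setdiff(names(cm), "n")
    summ <- list(n_per_population = cm$n,
                 projections = lapply(stats::setNames(proj, proj), function(p) {
                   e <- cm[[p]]
                   list(edges = nrow(e),
                        in_degree = unname(max(table(e$post))),
                        out_degree = unname(max(table(e$pre))))
                 }))
    jsonlite::write_json(summ, json, auto_unbox = TRUE, pretty = TRUE)
    written$json <- json
  }
  invisible(written)
}
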