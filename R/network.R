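# Weighted graph segregation and integration on unthresholded connectivity
# matrices. Missing entries (region pairs not covered by the implantation)
# are treated as weight 0.

check_conn_matrix <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("W must be square")
  A <- W
  diag(A) <- 0
  A[is.na(A)] <- 0
  if (max(abs(A - t(A))) > 1e-10) stop("W must be symmetric")
  if (any(A < 0) || any(A > 1)) stop("weights must lie in [0, 1]")
  A
}

#' Weighted clustering coefficient (segregation)
#'
#' Onnela's weighted generalization of the clustering coefficient on the
#' max-normalized matrix `w = W / max(W)`:
#' `C_i = sum_{j,h} (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))` with `k_i`
#' the number of nonzero neighbours; `C_i = 0` when `k_i < 2`. The mean
#' over nodes summarizes the network's segregation.
#'
#' @param W Symmetric weighted matrix, entries in `[0, 1]`, `NA` allowed
#'   (treated as 0).
#' @return List with `clustering` (per node) and `mean_clustering`.
#' @export
clustering_coefficient <- function(W) {
  A <- check_conn_matrix(W)
  mx <- max(A)
  if (mx > 0) A <- A / mx
  R <- A^(1 / 3)
  num <- diag(R %*% R %*% R)          # 2 x number of weighted triangles
  k <- rowSums(A > 0)
  C <- ifelse(k >= 2, num / (k * (k - 1)), 0)
  names(C) <- rownames(W)
  list(clustering = C, mean_clustering = mean(C))
}

#' Nodal and global efficiency (integration)
#'
#' Edge lengths are the inverse weights `1/w` (infinite for absent edges);
#' `d_ij` is the weighted shortest path. Nodal efficiency is
#' `NE_i = mean_{j != i} 1/d_ij` and global efficiency is the mean of the
#' nodal efficiencies.
#'
#' @inheritParams clustering_coefficient
#' @return List with `nodal_efficiency` (per node) and `global_efficiency`.
#' @export
efficiency <- function(W) {
  A <- check_conn_matrix(W)
  n <- nrow(A)
  if (n < 2L) stop("need at least two nodes")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / D
  diag(inv) <- 0
  NE <- rowSums(inv) / (n - 1L)
  names(NE) <- rownames(W)
  list(nodal_efficiency = NE, global_efficiency = mean(NE))
}

#' All segregation/integration metrics of a connectivity matrix
#'
#' @inheritParams clustering_coefficient
#' @return Object of class `network_metrics`: per-node clustering and nodal
#'   efficiency plus their network-level means (`mean_clustering` =
#'   segregation, `global_efficiency` = integration).
#' @export
network_metrics <- function(W) {
  cc <- clustering_coefficient(W)
  ef <- efficiency(W)
  structure(list(unit_labels = rownames(W),
                 clustering = cc$clustering,
                 nodal_efficiency = ef$nodal_efficiency,
                 mean_clustering = cc$mean_clustering,
                 global_efficiency = ef$global_efficiency),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> %d node(s): segregation %.4f, integration %.4f\n",
              length(x$clustering), x$mean_clustering, x$global_efficiency))
  invisible(x)
}
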