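# Two-layer graph-convolutional drug encoder over the co-prescription (EHR)
# and DDI graphs, fused into the relation-aware drug embedding table E_m*.

# Symmetrically normalised adjacency with self-loops:
# N = D^(-1/2) (A + I) D^(-1/2), D = diag(rowSums(A + I)).
normalize_adjacency <- function(A) {
  Ahat <- A + diag(nrow(A))
  dinv <- 1 / sqrt(rowSums(Ahat))
  dinv * Ahat * rep(dinv, each = nrow(A))
}

#' One graph-convolution layer
#'
#' Computes `D^(-1/2) (A + I) D^(-1/2) E W`. The layer primitive is linear;
#' the nonlinearity of the two-layer encoder is applied between the layers
#' by [encode_drug_relations()].
#'
#' @param E `|M| x dim` input node features.
#' @param A_star `|M| x |M|` non-negative adjacency (no self-loops needed;
#'   they are added internally).
#' @param W `dim x dim` weight matrix.
#' @return `|M| x dim` matrix.
#' @export
gcn_layer <- function(E, A_star, W) {
  if (nrow(A_star) != ncol(A_star) || nrow(E) != nrow(A_star) ||
      ncol(E) != nrow(W))
    stop("gcn_layer: non-conformable shapes")
  if (any(A_star < 0)) stop("gcn_layer: adjacency must be non-negative")
  normalize_adjacency(A_star) %*% E %*% W
}

#' Parameters of the drug-graph encoder
#'
#' @param E_m `|M| x dim` base drug embedding table.
#' @param W_e1,W_e2,W_e,W_d1,W_d2,W_d `dim x dim` weights: two layer weights
#'   and one between-layer weight per graph branch.
#' @param delta scalar fusing the DDI branch into the EHR branch.
#' @return a `drug_graph_params` list.
#' @export
drug_graph_params <- function(E_m, W_e1, W_e2, W_e, W_d1, W_d2, W_d,
                              delta = 0.5) {
  structure(list(E_m = E_m, W_e1 = W_e1, W_e2 = W_e2, W_e = W_e,
                 W_d1 = W_d1, W_d2 = W_d2, W_d = W_d, delta = delta),
            class = "drug_graph_params")
}

#' Relation-aware drug embeddings
#'
#' `G_e = GCN(tanh(GCN(E_m, A_E)) W_e, A_E)`, `G_d` analogously over the DDI
#' graph, and `E_m* = G_e + delta * G_d`. Either branch can be disabled for
#' ablation; with both disabled the base table `E_m` is returned unchanged.
#'
#' @param params a [drug_graph_params()].
#' @param A_E,A_D binary co-prescription and DDI adjacency matrices.
#' @param use_ehr_graph,use_ddi_graph branch switches.
#' @return `|M| x dim` matrix `E_m*`.
#' @export
encode_drug_relations <- function(params, A_E, A_D,
                                  use_ehr_graph = TRUE, use_ddi_graph = TRUE) {
  branch <- function(A, W1, W2, Wmid, stage) {
    out <- gcn_layer(tanh(gcn_layer(params$E_m, A, W1)) %*% Wmid, A, W2)
    if (!all(is.finite(out))) stop("non-finite values in ", stage, " branch")
    out
  }
  if (!use_ehr_graph && !use_ddi_graph) return(params$E_m)
  Ge <- if (use_ehr_graph)
    branch(A_E, params$W_e1, params$W_e2, params$W_e, "EHR") else 0
  Gd <- if (use_ddi_graph)
    branch(A_D, params$W_d1, params$W_d2, params$W_d, "DDI") else 0
  Ge + params$delta * Gd
}
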