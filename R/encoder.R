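# Patient encoder: visit embeddings, code-level and visit-level attention
# over the history, and the fused patient representation q.
#
# Each visit is embedded additively: the multi-hot code vectors select rows
# of the embedding tables, and the diagnosis, procedure and (for history
# visits) drug components are summed into one dim-vector. Two GRU cells run
# over the history; one yields a per-visit tanh gate vector (code-level
# attention), the other a normalised scalar weight per visit (visit-level
# attention).

#' Embed one visit
#'
#' @param v a [visit()].
#' @param tables list with `E_d`, `E_p` and `E_m_star` embedding tables
#'   (rows indexed by 0-based code index + 1).
#' @param include_drugs embed the drug set too (history visits); the current
#'   visit is embedded from diagnoses and procedures only.
#' @param use_diagnoses,use_procedures ablation switches.
#' @return dim-vector (numeric).
#' @export
embed_visit <- function(v, tables, include_drugs = TRUE,
                        use_diagnoses = TRUE, use_procedures = TRUE) {
  dim <- ncol(tables$E_d)
  pick <- function(tab, idx) {
    if (length(idx) == 0L) numeric(dim)
    else colSums(tab[idx + 1L, , drop = FALSE])
  }
  de <- if (use_diagnoses) pick(tables$E_d, v$d) else numeric(dim)
  pe <- if (use_procedures) pick(tables$E_p, v$p) else numeric(dim)
  me <- if (include_drugs) pick(tables$E_m_star, v$m) else numeric(dim)
  de + pe + me
}

# plain GRU step; W is the list of cell matrices, x and h dim-vectors
gru_step <- function(W, x, h) {
  z <- plogis(W$Wz %*% x + W$Uz %*% h + W$bz)
  r <- plogis(W$Wr %*% x + W$Ur %*% h + W$br)
  c_ <- tanh(W$Wh %*% x + W$Uh %*% (r * h) + W$bh)
  as.vector((1 - z) * h + z * c_)
}

# hidden-state trajectory of a GRU over a list of dim-vectors
gru_unroll <- function(W, xs) {
  dim <- nrow(W$Wz)
  h <- numeric(dim)
  lapply(xs, function(x) h <<- gru_step(W, x, h))
}

#' Code-level attention over the history
#'
#' A GRU consumes the fused history embeddings; each hidden state is mapped
#' through `tanh(W_g g + b_g)` to a per-visit gate vector in `(-1, 1)^dim`.
#'
#' @param history list of fused history visit embeddings (dim-vectors, in
#'   chronological order, non-empty).
#' @param params list with GRU cell `rnn_c` and the affine map `W_g`, `b_g`.
#' @return list of dim-vectors, one per history visit.
#' @export
code_attention <- function(history, params) {
  if (length(history) == 0L) stop("code_attention: empty history")
  gs <- gru_unroll(params$rnn_c, history)
  lapply(gs, function(g) as.vector(tanh(params$W_g %*% g + params$b_g)))
}

#' Visit-level attention over the history
#'
#' A second GRU consumes the history; each hidden state is reduced to a raw
#' scalar by `W_h`, and the scalars are normalised by their plain sum (the
#' ratio rule). If the sum's magnitude falls below `eps` the weights fall
#' back to uniform. `norm = "softmax"` substitutes a softmax normalisation.
#'
#' @param history list of fused history embeddings (non-empty).
#' @param params list with GRU cell `rnn_v` and row vector `W_h`.
#' @param norm `"ratio"` (literal normalisation) or `"softmax"`.
#' @param eps degeneracy guard on the ratio denominator.
#' @return numeric weights summing to 1.
#' @export
visit_attention <- function(history, params, norm = c("ratio", "softmax"),
                            eps = 1e-8) {
  norm <- match.arg(norm)
  if (length(history) == 0L) stop("visit_attention: empty history")
  hs <- gru_unroll(params$rnn_v, history)
  raw <- vapply(hs, function(h) as.numeric(params$W_h %*% h), 0)
  if (norm == "softmax") {
    z <- exp(raw - max(raw))
    return(z / sum(z))
  }
  s <- sum(raw)
  if (abs(s) < eps) {
    message("visit_attention: degenerate ratio denominator, uniform fallback")
    return(rep(1 / length(raw), length(raw)))
  }
  raw / s
}

#' Fuse current visit and attended history into the patient representation
#'
#' `q = e_t + sum_j beta_j * (alpha_j (elementwise*) e_j)`; with no history,
#' `q` is the current-visit embedding alone.
#'
#' @param current fused current-visit embedding (dim-vector).
#' @param history list of fused history embeddings (may be empty).
#' @param alpha list of code-attention gate vectors (same length).
#' @param beta numeric visit-attention weights (same length).
#' @return dim-vector `q`.
#' @export
patient_representation <- function(current, history, alpha = NULL,
                                   beta = NULL) {
  if (length(history) == 0L) return(current)
  if (length(alpha) != length(history) || length(beta) != length(history))
    stop("attention/history length mismatch")
  q <- current
  for (j in seq_along(history)) {
    q <- q + beta[j] * (alpha[[j]] * history[[j]])
  }
  q
}
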