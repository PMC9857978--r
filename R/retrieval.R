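# Patient-similarity retrieval: the current-similarity channel against the
# drug embedding table, and the personal / cross-patient historical channels
# against a memory of stored (q, drug multi-hot) pairs.

#' Cosine similarity with a small-norm guard
#'
#' @param u,v numeric vectors.
#' @return scalar in `[-1, 1]`; 0 if either norm is below `1e-12`.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu < 1e-12 || nv < 1e-12) return(0)
  sum(u * v) / (nu * nv)
}

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

#' Current-similarity drug retrieval
#'
#' Attention of the patient representation over the drug embedding rows:
#' `weights = softmax(E_m* q)`, `C = t(E_m*) weights`.
#'
#' @param q patient representation (dim-vector).
#' @param E_m_star `|M| x dim` relation-aware drug embeddings.
#' @return list with `weights` (an `|M|`-simplex vector) and `C`
#'   (dim-vector).
#' @export
current_similarity <- function(q, E_m_star) {
  w <- softmax(as.vector(E_m_star %*% q))
  list(weights = w, C = as.vector(crossprod(E_m_star, w)))
}

# shared kernel of the two historical channels: softmax over cosine scores
# weighting the stored drug multi-hots, projected through E_m*
.history_retrieve <- function(q, qs, drugs, E_m_star) {
  if (length(qs) == 0L) return(numeric(ncol(E_m_star)))
  s <- vapply(qs, function(qk) cosine_similarity(q, qk), 0)
  w <- softmax(s)
  r <- numeric(nrow(E_m_star))
  for (k in seq_along(w)) r <- r + w[k] * drugs[[k]]
  as.vector(crossprod(E_m_star, r))
}

#' Personal historical similarity channel
#'
#' Retrieves drug information from the same patient's earlier visits,
#' weighted by softmax-normalised cosine similarity of the stored
#' representations to the current one.
#'
#' @param q current patient representation.
#' @param own_history list of entries, each `list(q = , drugs = )` with
#'   `drugs` an `|M|` multi-hot vector; visits strictly before the current
#'   one. May be empty (returns the zero vector).
#' @param E_m_star drug embedding table.
#' @return dim-vector `HPer`.
#' @export
personal_history_similarity <- function(q, own_history, E_m_star) {
  .history_retrieve(q, lapply(own_history, `[[`, "q"),
                    lapply(own_history, `[[`, "drugs"), E_m_star)
}

#' Patient memory
#'
#' A bank of stored per-visit disease-state representations and their
#' ground-truth drug sets, one entry per (training patient, visit).
#'
#' @param patient_ids character vector, one id per entry.
#' @param visit_indices integer visit positions.
#' @param Q `n x dim` matrix of stored representations (rows).
#' @param drugs `n x |M|` binary matrix of stored drug multi-hots.
#' @return a `patient_memory` object.
#' @export
patient_memory <- function(patient_ids, visit_indices, Q, drugs) {
  stopifnot(length(patient_ids) == nrow(Q), nrow(Q) == nrow(drugs),
            length(visit_indices) == nrow(Q))
  structure(list(patient_ids = patient_ids,
                 visit_indices = as.integer(visit_indices),
                 Q = Q, drugs = drugs), class = "patient_memory")
}

#' Cross-patient historical similarity channel
#'
#' Ranks memory entries of *other* patients by cosine similarity to `q`,
#' keeps the `top_n` (ties broken by lower patient id, then lower visit
#' index), softmax-normalises the kept similarities and projects the
#' weighted drug multi-hots through the drug embedding table.
#'
#' @param q current patient representation.
#' @param memory a [patient_memory()].
#' @param exclude_patient id whose entries are excluded (leakage guard).
#' @param top_n number of entries retained (`>= 1`).
#' @param E_m_star drug embedding table.
#' @return dim-vector `HPat`; zero vector if no eligible entries.
#' @export
patient_history_similarity <- function(q, memory, exclude_patient, top_n,
                                       E_m_star) {
  stopifnot(top_n >= 1L)
  keep <- memory$patient_ids != exclude_patient
  if (!any(keep)) return(numeric(ncol(E_m_star)))
  Q <- memory$Q[keep, , drop = FALSE]
  ids <- memory$patient_ids[keep]
  vix <- memory$visit_indices[keep]
  drugs <- memory$drugs[keep, , drop = FALSE]
  s <- apply(Q, 1L, function(qk) cosine_similarity(q, qk))
  ord <- order(-s, ids, vix)
  sel <- ord[seq_len(min(top_n, length(ord)))]
  w <- softmax(s[sel])
  r <- as.vector(crossprod(drugs[sel, , drop = FALSE], w))
  as.vector(crossprod(E_m_star, r))
}

#' Bundle the retrieval channels
#'
#' @param C,HPer,HPat the three retrieval vectors.
#' @return list with the three channels and `H = c(HPer, HPat)`.
#' @export
similarity_bundle <- function(C, HPer, HPat) {
  list(C = C, HPer = HPer, HPat = HPat, H = c(HPer, HPat))
}
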