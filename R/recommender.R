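# Patient-drug matching head, threshold decoding, and the training losses:
# DDI penalty, multi-label margin + BCE (the multi-label prediction loss),
# and the information-constraint term based on matrix Renyi alpha-entropy.

#' Matching scores
#'
#' Projects the concatenation `[q, C, H]` (length `4 * dim`) through a
#' learnable affine map and a sigmoid to per-drug scores in `(0, 1)`.
#'
#' @param q,C dim-vectors; `H` a `2 * dim`-vector.
#' @param W_o `(4 * dim) x |M|` projection matrix.
#' @param bias `|M|`-vector.
#' @return `|M|`-vector of scores.
#' @export
match_scores <- function(q, C, H, W_o, bias) {
  x <- c(q, C, H)
  if (length(x) != nrow(W_o)) stop("match_scores: concat length != nrow(W_o)")
  as.vector(plogis(crossprod(W_o, x) + bias))
}

#' Threshold decoding
#'
#' @param o score vector.
#' @param psi decision threshold in `(0, 1)`; a score equal to `psi` is
#'   predicted (the `>=` rule).
#' @return binary multi-hot vector.
#' @export
threshold_predictions <- function(o, psi = 0.5) {
  stopifnot(psi > 0, psi < 1)
  as.numeric(o >= psi)
}

#' DDI loss for one visit
#'
#' The literal double sum `sum_ij A_D[i,j] o_i o_j`; each unordered
#' interacting pair is counted twice.
#'
#' @param o score vector.
#' @param A_D binary symmetric DDI adjacency.
#' @return non-negative scalar.
#' @export
ddi_loss <- function(o, A_D) {
  as.numeric(crossprod(o, A_D %*% o))
}

#' Multi-label margin loss
#'
#' Mean-free sum over (positive, negative) label pairs of
#' `max(0, 1 - (o_i - o_j))`, divided by `|M|`. All-positive or all-negative
#' label vectors give 0.
#'
#' @param o score vector.
#' @param m binary truth vector.
#' @return non-negative scalar.
#' @export
margin_loss <- function(o, m) {
  stopifnot(length(o) == length(m))
  pos <- which(m == 1); neg <- which(m == 0)
  if (length(pos) == 0L || length(neg) == 0L) return(0)
  sum(pmax(0, 1 - outer(o[pos], o[neg], "-"))) / length(o)
}

#' Binary cross-entropy loss (summed over drugs)
#'
#' Natural log; scores clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param o score vector.
#' @param m binary truth vector.
#' @return non-negative scalar.
#' @export
bce_loss <- function(o, m) {
  stopifnot(length(o) == length(m))
  oc <- pmin(pmax(o, 1e-7), 1 - 1e-7)
  -sum(m * log(oc) + (1 - m) * log(1 - oc))
}

#' Multi-label prediction loss
#'
#' `(1 - mu) * L_multi + mu * L_bce`.
#'
#' @param l_multi,l_bce the margin and BCE losses.
#' @param mu balance in `[0, 1]` (default 0.05).
#' @return scalar.
#' @export
mp_loss <- function(l_multi, l_bce, mu = 0.05) {
  stopifnot(mu >= 0, mu <= 1)
  (1 - mu) * l_multi + mu * l_bce
}

#' Matrix-based Renyi alpha-entropy of a set of representations
#'
#' Builds a Gaussian Gram matrix over the rows of `Q` (bandwidth = median
#' pairwise distance unless `sigma` is given), trace-normalises it and
#' returns `H_alpha = log2(sum_i lambda_i^alpha) / (1 - alpha)` from its
#' eigenvalues. Values lie in `[0, log2 n]`. Negative eigenvalues from
#' numerical error are clamped at zero.
#'
#' @param Q `n x dim` matrix, one representation per row (`n >= 1`).
#' @param alpha entropy order, positive and different from 1 (default 1.01,
#'   near-Shannon).
#' @param sigma optional fixed kernel bandwidth.
#' @return scalar entropy in bits.
#' @export
renyi_entropy <- function(Q, alpha = 1.01, sigma = NULL) {
  if (!is.matrix(Q)) Q <- matrix(Q, nrow = 1L)
  if (nrow(Q) == 0L) stop("renyi_entropy: empty input")
  stopifnot(alpha > 0, alpha != 1)
  if (nrow(Q) == 1L) return(0)
  G <- tcrossprod(Q)
  sq <- diag(G)
  D2 <- pmax(outer(sq, sq, "+") - 2 * G, 0)
  if (is.null(sigma)) {
    sigma <- stats::median(sqrt(D2[upper.tri(D2)]))
    if (!is.finite(sigma) || sigma < 1e-8) sigma <- 1
  }
  K <- exp(-D2 / (2 * sigma^2))
  renyi_entropy_gram(K, alpha)
}

#' Renyi alpha-entropy from a precomputed Gram matrix
#'
#' @param K symmetric positive semi-definite kernel matrix.
#' @param alpha entropy order.
#' @return scalar entropy in bits.
#' @export
renyi_entropy_gram <- function(K, alpha = 1.01) {
  stopifnot(alpha > 0, alpha != 1)
  A <- K / sum(diag(K))
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  log2(sum(lam^alpha)) / (1 - alpha)
}

#' Total training loss
#'
#' `lambda1 * L_ddi + lambda2 * L_mp + lambda3 * L_ic`.
#'
#' @param l_ddi,l_mp,l_ic component losses.
#' @param lambda1,lambda2,lambda3 non-negative weights
#'   (defaults 0.2, 0.75, 0.05).
#' @return scalar.
#' @export
total_loss <- function(l_ddi, l_mp, l_ic, lambda1 = 0.2, lambda2 = 0.75,
                       lambda3 = 0.05) {
  stopifnot(lambda1 >= 0, lambda2 >= 0, lambda3 >= 0)
  lambda1 * l_ddi + lambda2 * l_mp + lambda3 * l_ic
}
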