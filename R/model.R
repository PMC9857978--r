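# Model parameter container and the forward pass.
#
# Two parallel forward implementations exist on purpose:
#   * a plain numeric path (`encode_patient`) used for prediction, memory
#     refresh and evaluation, built from the exported module functions; and
#   * a tape path (`patient_loss_tape`) used inside training, built from the
#     autodiff ops so that gradients of the composite loss are exact.
# A test asserts the two paths agree to float precision on random models.

gru_param_names <- c("Wz", "Uz", "bz", "Wr", "Ur", "br", "Wh", "Uh", "bh")

#' Initialise model parameters
#'
#' Weight matrices are drawn uniformly from `[-1/sqrt(dim), 1/sqrt(dim)]`;
#' embedding tables from `[-0.5, 0.5]`, so that a visit embedding (the sum
#' of roughly ten table rows) has entries of about unit scale; biases start
#' at zero; the graph-fusion scalar starts at `config$delta_init`.
#' Deterministic given `config$seed`.
#'
#' @param n_diag,n_proc,n_drug vocabulary sizes.
#' @param config a [train_config()].
#' @return named list of parameter matrices (a flat parameter set).
#' @export
init_params <- function(n_diag, n_proc, n_drug, config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  d <- config$dim
  a <- 1 / sqrt(d)
  U <- function(r, c) matrix(stats::runif(r * c, -a, a), r, c)
  E <- function(r, c) matrix(stats::runif(r * c, -0.5, 0.5), r, c)
  Z <- function(r, c) matrix(0, r, c)
  gru <- function(prefix) {
    W <- list(Wz = U(d, d), Uz = U(d, d), bz = Z(d, 1L),
              Wr = U(d, d), Ur = U(d, d), br = Z(d, 1L),
              Wh = U(d, d), Uh = U(d, d), bh = Z(d, 1L))
    names(W) <- paste0(prefix, names(W))
    W
  }
  p <- c(list(E_d = E(n_diag, d), E_p = E(n_proc, d), E_m = E(n_drug, d),
              W_e1 = U(d, d), W_e2 = U(d, d), W_e = U(d, d),
              W_d1 = U(d, d), W_d2 = U(d, d), W_d = U(d, d),
              delta = matrix(config$delta_init, 1L, 1L)),
         gru("C_"), gru("V_"),
         list(W_g = U(d, d), b_g = Z(d, 1L), W_hatt = U(1L, d),
              W_o = U(4L * d, n_drug), b_o = Z(n_drug, 1L)))
  p
}

# parameter subsets forming the two GRU cells, as plain matrices
.gru_cell <- function(params, prefix) {
  W <- params[paste0(prefix, gru_param_names)]
  names(W) <- gru_param_names
  W
}

# resolve the GCN branch weights honouring the share switch
.gcn_weights <- function(params, config) {
  if (isTRUE(config$share_gcn_weights))
    list(e = c("W_e1", "W_e2", "W_e"), d = c("W_e1", "W_e2", "W_e"))
  else
    list(e = c("W_e1", "W_e2", "W_e"), d = c("W_d1", "W_d2", "W_d"))
}

# E_m* from plain matrices
compute_drug_embeddings <- function(params, A_E, A_D, config) {
  w <- .gcn_weights(params, config)
  gp <- drug_graph_params(params$E_m,
                          params[[w$e[1L]]], params[[w$e[2L]]], params[[w$e[3L]]],
                          params[[w$d[1L]]], params[[w$d[2L]]], params[[w$d[3L]]],
                          delta = params$delta[1L])
  encode_drug_relations(gp, A_E, A_D,
                        use_ehr_graph = config$use_ehr_graph,
                        use_ddi_graph = config$use_ddi_graph)
}

# ---- plain forward path ------------------------------------------------

# Encode every visit of one patient: representations q, retrieval channels,
# matching scores and thresholded predictions. `memory` may be NULL (the
# cross-patient channel is then zero). Returns per-visit rows.
encode_patient <- function(params, record, E_m_star, memory, config) {
  d <- config$dim
  M <- nrow(E_m_star)
  nvis <- length(record$visits)
  tabs <- list(E_d = params$E_d, E_p = params$E_p, E_m_star = E_m_star)
  att <- list(rnn_c = .gru_cell(params, "C_"),
              rnn_v = .gru_cell(params, "V_"),
              W_g = params$W_g, b_g = params$b_g, W_h = params$W_hatt)

  hist_emb <- lapply(record$visits[seq_len(nvis - 1L)], embed_visit,
                     tables = tabs, include_drugs = config$use_drug_history,
                     use_diagnoses = config$use_diagnoses,
                     use_procedures = config$use_procedures)
  alpha_all <- if (nvis > 1L && config$use_code_attention)
    code_attention(hist_emb, att) else NULL
  raw_all <- if (nvis > 1L && config$use_visit_attention) {
    hs <- gru_unroll(att$rnn_v, hist_emb)
    vapply(hs, function(h) as.numeric(att$W_h %*% h), 0)
  } else NULL

  Qm <- matrix(0, nvis, d)
  O <- matrix(0, nvis, M)
  pred <- matrix(0, nvis, M)
  for (t in seq_len(nvis)) {
    cur <- embed_visit(record$visits[[t]], tabs, include_drugs = FALSE,
                       use_diagnoses = config$use_diagnoses,
                       use_procedures = config$use_procedures)
    if (t == 1L) {
      q <- cur
    } else {
      js <- seq_len(t - 1L)
      alpha <- if (is.null(alpha_all)) rep(list(rep(1, d)), t - 1L)
               else alpha_all[js]
      beta <- if (is.null(raw_all)) rep(1 / (t - 1L), t - 1L)
              else .normalize_beta(raw_all[js], config$visit_attention_norm)
      q <- patient_representation(cur, hist_emb[js], alpha, beta)
    }
    Qm[t, ] <- q
    cs <- current_similarity(q, E_m_star)
    if (config$use_h) {
      own <- if (t > 1L) lapply(seq_len(t - 1L), function(k) list(
        q = Qm[k, ], drugs = encode_multihot(record$visits[[k]]$m, M)))
        else list()
      HPer <- personal_history_similarity(q, own, E_m_star)
      HPat <- if (config$use_hpat && !is.null(memory))
        patient_history_similarity(q, memory, record$patient_id,
                                   config$top_n, E_m_star)
        else numeric(d)
    } else {
      HPer <- numeric(d)
      HPat <- numeric(d)
    }
    o <- match_scores(q, cs$C, c(HPer, HPat), params$W_o,
                      as.vector(params$b_o))
    O[t, ] <- o
    pred[t, ] <- threshold_predictions(o, config$psi)
  }
  list(q = Qm, scores = O, pred = pred)
}

.normalize_beta <- function(raw, norm, eps = 1e-8) {
  if (norm == "softmax") {
    z <- exp(raw - max(raw))
    return(z / sum(z))
  }
  s <- sum(raw)
  if (abs(s) < eps) rep(1 / length(raw), length(raw)) else raw / s
}

# ---- tape forward path (training) --------------------------------------

# Push all parameters onto a fresh tape; returns list(tape, ids) where ids
# mirrors the parameter names.
.tape_with_params <- function(params) {
  tp <- ad_tape()
  ids <- lapply(params, function(m) ad_param(tp, m))
  list(tp = tp, ids = ids)
}

# E_m* on the tape; NE/ND are the precomputed normalised adjacencies.
.tape_drug_embeddings <- function(tp, ids, NE, ND, config) {
  if (!config$use_ehr_graph && !config$use_ddi_graph) return(ids$E_m)
  w <- .gcn_weights(NULL, config)
  branch <- function(Nc, keys) {
    Nid <- ad_const(tp, Nc)
    inner <- ad_matmul(tp, Nid, ad_matmul(tp, ids$E_m, ids[[keys[1L]]]))
    mid <- ad_matmul(tp, ad_tanh(tp, inner), ids[[keys[3L]]])
    ad_matmul(tp, Nid, ad_matmul(tp, mid, ids[[keys[2L]]]))
  }
  if (!config$use_ddi_graph) return(branch(NE, w$e))
  Gd <- ad_scale(tp, branch(ND, w$d), ids$delta)
  if (!config$use_ehr_graph) return(Gd)
  ad_add(tp, branch(NE, w$e), Gd)
}

# Loss of one patient on a tape. Returns the tape, the total-loss node and
# the numeric loss breakdown. `memory` entries are treated as constants.
# With `only_visit = t`, the prediction losses cover visit t alone (the
# representations of visits 1..t are still built, for the personal channel
# and the entropy term) — used by per-visit optimiser stepping.
patient_loss_tape <- function(params, record, NE, ND, A_D, memory, config,
                              only_visit = NULL) {
  tw <- .tape_with_params(params)
  tp <- tw$tp; ids <- tw$ids
  d <- config$dim
  M <- nrow(params$E_m)
  nvis <- if (is.null(only_visit)) length(record$visits) else only_visit
  EmStar <- .tape_drug_embeddings(tp, ids, NE, ND, config)
  zero_d <- ad_const(tp, matrix(0, d, 1L))
  gruC <- lapply(gru_param_names, function(nm) ids[[paste0("C_", nm)]])
  names(gruC) <- gru_param_names
  gruV <- lapply(gru_param_names, function(nm) ids[[paste0("V_", nm)]])
  names(gruV) <- gru_param_names

  emb <- function(v, with_drugs) {
    parts <- list()
    if (config$use_diagnoses) parts <- c(parts, ad_embed_sum(tp, ids$E_d, v$d + 1L))
    if (config$use_procedures) parts <- c(parts, ad_embed_sum(tp, ids$E_p, v$p + 1L))
    if (with_drugs) parts <- c(parts, ad_embed_sum(tp, EmStar, v$m + 1L))
    if (length(parts) == 0L) return(zero_d)
    out <- parts[[1L]]
    for (k in seq_along(parts)[-1L]) out <- ad_add(tp, out, parts[[k]])
    out
  }

  # history embeddings, GRU trajectories, gates and raw visit scores
  hist_ids <- integer(0)
  alpha_ids <- integer(0)
  raw_ids <- integer(0)
  raw_vals <- numeric(0)
  if (nvis > 1L) {
    g <- zero_d; h <- zero_d
    for (j in seq_len(nvis - 1L)) {
      e <- emb(record$visits[[j]], config$use_drug_history)
      hist_ids[j] <- e
      if (config$use_code_attention) {
        g <- ad_gru_step(tp, gruC, e, g)
        alpha_ids[j] <- ad_tanh(tp, ad_affine(tp, ids$W_g, g, ids$b_g))
      }
      if (config$use_visit_attention) {
        h <- ad_gru_step(tp, gruV, e, h)
        raw_ids[j] <- ad_affine(tp, ids$W_hatt, h)
        raw_vals[j] <- ad_value(tp, raw_ids[j])[1L]
      }
    }
  }
  ones_d <- ad_const(tp, matrix(1, d, 1L))

  q_ids <- integer(nvis)
  n_loss <- 0L
  loss_ddi <- NULL; loss_mp <- NULL
  for (t in seq_len(nvis)) {
    with_loss <- is.null(only_visit) || t == only_visit
    cur <- emb(record$visits[[t]], FALSE)
    if (t == 1L) {
      q <- cur
    } else {
      js <- seq_len(t - 1L)
      beta <- .tape_beta(tp, raw_ids, raw_vals, js, config)
      q <- cur
      for (j in js) {
        a <- if (config$use_code_attention) alpha_ids[j] else ones_d
        contrib <- ad_hadamard(tp, a, hist_ids[j])
        contrib <- if (is.null(beta)) ad_scale_const(tp, contrib, 1 / (t - 1L))
                   else ad_scale(tp, contrib, beta[[j]])
        q <- ad_add(tp, q, contrib)
      }
    }
    q_ids[t] <- q
    if (!with_loss) next

    w_cur <- ad_softmax(tp, ad_matmul(tp, EmStar, q))
    Cn <- ad_affine_t(tp, EmStar, w_cur)
    if (config$use_h) {
      HPer <- .tape_hper(tp, q, q_ids, record, t, EmStar, M)
      HPat <- if (config$use_hpat && !is.null(memory))
        .tape_hpat(tp, q, memory, record$patient_id, config$top_n, EmStar)
        else ad_const(tp, matrix(0, d, 1L))
    } else {
      HPer <- ad_const(tp, matrix(0, d, 1L))
      HPat <- ad_const(tp, matrix(0, d, 1L))
    }
    x <- ad_concat(tp, list(q, Cn, HPer, HPat))
    o <- ad_sigmoid(tp, ad_affine_t(tp, ids$W_o, x, ids$b_o))

    m_true <- encode_multihot(record$visits[[t]]$m, M)
    l_ddi <- ad_ddi_loss(tp, o, A_D)
    l_mlm <- ad_margin_loss(tp, o, m_true)
    l_bce <- ad_bce_loss(tp, o, m_true)
    l_mp <- ad_add(tp, ad_scale_const(tp, l_mlm, 1 - config$mu),
                   ad_scale_const(tp, l_bce, config$mu))
    loss_ddi <- if (is.null(loss_ddi)) l_ddi else ad_add(tp, loss_ddi, l_ddi)
    loss_mp <- if (is.null(loss_mp)) l_mp else ad_add(tp, loss_mp, l_mp)
    n_loss <- n_loss + 1L
  }
  loss_ddi <- ad_scale_const(tp, loss_ddi, 1 / n_loss)
  loss_mp <- ad_scale_const(tp, loss_mp, 1 / n_loss)
  loss_ic <- if (config$lambda3 > 0 && nvis > 1L)
    ad_renyi(tp, ad_stack_rows(tp, as.list(q_ids)), config$renyi_alpha,
             config$renyi_sigma)
    else ad_const(tp, matrix(0, 1L, 1L))
  total <- ad_add(tp, ad_add(tp,
    ad_scale_const(tp, loss_ddi, config$lambda1),
    ad_scale_const(tp, loss_mp, config$lambda2)),
    ad_scale_const(tp, loss_ic, config$lambda3))
  list(tp = tp, ids = ids, total = total,
       breakdown = c(ddi = ad_value(tp, loss_ddi)[1L],
                     mp = ad_value(tp, loss_mp)[1L],
                     ic = ad_value(tp, loss_ic)[1L],
                     total = ad_value(tp, total)[1L]))
}

# visit-attention weights on the tape (list of scalar nodes), or NULL for
# the uniform cases (disabled attention or degenerate ratio denominator)
.tape_beta <- function(tp, raw_ids, raw_vals, js, config) {
  if (!config$use_visit_attention) return(NULL)
  if (config$visit_attention_norm == "softmax") {
    vec <- ad_concat(tp, as.list(raw_ids[js]))
    sm <- ad_softmax(tp, vec)
    return(lapply(seq_along(js), function(k)
      ad_push(tp, matrix(ad_value(tp, sm)[k], 1L, 1L), local({
        kk <- k
        function(g, genv) {
          G <- matrix(0, length(js), 1L); G[kk, 1L] <- g[1L]
          ad_acc(genv, sm, G)
        }
      }))))
  }
  s <- sum(raw_vals[js])
  if (abs(s) < 1e-8) return(NULL)
  ssum <- raw_ids[js[1L]]
  for (j in js[-1L]) ssum <- ad_add(tp, ssum, raw_ids[j])
  lapply(js, function(j) .ad_ratio(tp, raw_ids[j], ssum))
}

# elementwise a / b for 1x1 nodes
.ad_ratio <- function(tp, a, b) {
  av <- ad_value(tp, a)[1L]; bv <- ad_value(tp, b)[1L]
  ad_push(tp, matrix(av / bv, 1L, 1L), function(g, genv) {
    ad_acc(genv, a, matrix(g[1L] / bv, 1L, 1L))
    ad_acc(genv, b, matrix(-g[1L] * av / bv^2, 1L, 1L))
  })
}

.tape_hper <- function(tp, q, q_ids, record, t, EmStar, M) {
  d <- nrow(ad_value(tp, q))
  if (t == 1L) return(ad_const(tp, matrix(0, d, 1L)))
  ks <- seq_len(t - 1L)
  sims <- lapply(ks, function(k) ad_cosine(tp, q, q_ids[k]))
  w <- ad_softmax(tp, ad_concat(tp, sims))
  drugs <- vapply(ks, function(k) encode_multihot(record$visits[[k]]$m, M),
                  numeric(M))
  r <- ad_matmul(tp, ad_const(tp, matrix(drugs, nrow = M)), w)
  ad_affine_t(tp, EmStar, r)
}

.tape_hpat <- function(tp, q, memory, exclude, top_n, EmStar) {
  d <- nrow(ad_value(tp, q))
  keep <- memory$patient_ids != exclude
  if (!any(keep)) return(ad_const(tp, matrix(0, d, 1L)))
  Q <- memory$Q[keep, , drop = FALSE]
  ids <- memory$patient_ids[keep]
  vix <- memory$visit_indices[keep]
  drugs <- memory$drugs[keep, , drop = FALSE]
  qv <- as.vector(ad_value(tp, q))
  s <- apply(Q, 1L, function(qk) cosine_similarity(qv, qk))
  ord <- order(-s, ids, vix)
  sel <- ord[seq_len(min(top_n, length(ord)))]
  sims <- lapply(sel, function(k)
    ad_cosine(tp, q, ad_const(tp, matrix(Q[k, ], ncol = 1L))))
  w <- ad_softmax(tp, ad_concat(tp, sims))
  r <- ad_matmul(tp, ad_const(tp, t(drugs[sel, , drop = FALSE])), w)
  ad_affine_t(tp, EmStar, r)
}
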