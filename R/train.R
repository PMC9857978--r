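# Training loop: per-epoch drug-embedding and memory refresh, per-visit
# Adam steps on the combined loss, validation-based model selection.

# ---- Adam optimiser over a flat named list of matrices -----------------

adam_state <- function(params) {
  list(m = lapply(params, function(x) array(0, dim = dim(x))),
       v = lapply(params, function(x) array(0, dim = dim(x))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# empirical per-drug prescription log-odds over a cohort's visits, clamped
.prior_logits <- function(x) {
  M <- length(x$vocab_m)
  counts <- numeric(M)
  n <- 0L
  for (rec in x$records) for (v in rec$visits) {
    counts[v$m + 1L] <- counts[v$m + 1L] + 1
    n <- n + 1L
  }
  p <- pmin(pmax(counts / max(n, 1L), 0.02), 0.98)
  log(p / (1 - p))
}

# ---- patient memory refresh --------------------------------------------

#' Build the patient memory from a cohort
#'
#' Encodes every visit of every patient with the current parameters (the
#' encoder alone; retrieval does not enter `q`) and stores each
#' representation with its ground-truth drug multi-hot.
#'
#' @param params model parameter list.
#' @param x a [cohort()], conventionally the training split.
#' @param E_m_star current relation-aware drug embeddings.
#' @param config a [train_config()].
#' @return a [patient_memory()].
#' @export
build_patient_memory <- function(params, x, E_m_star, config) {
  M <- length(x$vocab_m)
  n <- sum(vapply(x$records, function(r) length(r$visits), 0L))
  Q <- matrix(0, n, config$dim)
  drugs <- matrix(0, n, M)
  pid <- character(n); vix <- integer(n)
  row <- 0L
  for (rec in x$records) {
    enc <- encode_patient(params, rec, E_m_star, memory = NULL,
                          config = .encoder_only(config))
    for (t in seq_along(rec$visits)) {
      row <- row + 1L
      Q[row, ] <- enc$q[t, ]
      drugs[row, ] <- encode_multihot(rec$visits[[t]]$m, M)
      pid[row] <- rec$patient_id
      vix[row] <- t
    }
  }
  patient_memory(pid, vix, Q, drugs)
}

# memory refresh only needs q, not the retrieval channels or scores
.encoder_only <- function(config) {
  config$use_h <- FALSE
  config$use_hpat <- FALSE
  config
}

# ---- the training loop -------------------------------------------------

#' Train the medication recommender
#'
#' One epoch recomputes the relation-aware drug embeddings and the patient
#' memory, then iterates patients in sorted-id order, taking Adam steps on
#' the combined DDI / prediction / information-constraint loss at the
#' granularity of `config$steps` (per visit by default). The checkpoint
#' with the best validation Jaccard is returned. Deterministic given
#' `config$seed`.
#'
#' @param train,validation [cohort()] objects (validation may be `NULL`, in
#'   which case the final epoch's parameters are returned).
#' @param A_E,A_D co-prescription and DDI adjacency matrices (built from the
#'   training split).
#' @param config a [train_config()].
#' @param verbose print per-epoch loss lines to stderr.
#' @return a `medrec_model`: list with `params` (best), `memory`, `config`,
#'   `graphs`, `vocab` sizes, `history` (per-epoch loss breakdown and
#'   validation Jaccard) and `best_epoch`.
#' @export
train_model <- function(train, validation = NULL, A_E, A_D, config,
                        verbose = TRUE) {
  stopifnot(inherits(train, "cohort"), inherits(config, "train_config"))
  if (config$epochs < 1L) stop("epochs must be >= 1")
  params <- init_params(length(train$vocab_d), length(train$vocab_p),
                        length(train$vocab_m), config)
  # start the matching head at the training-set label prior: scores open at
  # the marginal prescription rates instead of 0.5, so early epochs learn
  # the conditional signal rather than the base rates
  params$b_o <- matrix(.prior_logits(train), ncol = 1L)
  NE <- normalize_adjacency(A_E)
  ND <- normalize_adjacency(A_D)
  state <- adam_state(params)
  ord <- order(vapply(train$records, `[[`, "", "patient_id"))
  records <- train$records[ord]

  history <- data.frame(epoch = integer(), ddi = numeric(), mp = numeric(),
                        ic = numeric(), total = numeric(),
                        val_jaccard = numeric())
  best <- list(jaccard = -Inf, params = params, epoch = 0L)

  for (epoch in seq_len(config$epochs)) {
    E_m_star <- compute_drug_embeddings(params, A_E, A_D, config)
    memory <- build_patient_memory(params, train, E_m_star, config)
    sums <- c(ddi = 0, mp = 0, ic = 0, total = 0)
    acc_grads <- NULL
    for (rec in records) {
      if (config$steps == "per_visit") {
        psum <- c(ddi = 0, mp = 0, ic = 0, total = 0)
        for (t in seq_along(rec$visits)) {
          pl <- patient_loss_tape(params, rec, NE, ND, A_D, memory, config,
                                  only_visit = t)
          if (!all(is.finite(pl$breakdown)))
            stop(sprintf("non-finite loss at epoch %d, patient %s, visit %d",
                         epoch, rec$patient_id, t))
          g <- ad_backward(pl$tp, pl$total)
          grads <- lapply(pl$ids, function(id) g[[id]])
          upd <- adam_step(params, grads, state, config$lr)
          params <- upd$params
          state <- upd$state
          psum <- psum + pl$breakdown
        }
        sums <- sums + psum / length(rec$visits)
        if (config$memory_refresh == "per_step") {
          E_m_star <- compute_drug_embeddings(params, A_E, A_D, config)
          memory <- build_patient_memory(params, train, E_m_star, config)
        }
        next
      }
      pl <- patient_loss_tape(params, rec, NE, ND, A_D, memory, config)
      if (!all(is.finite(pl$breakdown)))
        stop(sprintf("non-finite loss at epoch %d, patient %s", epoch,
                     rec$patient_id))
      g <- ad_backward(pl$tp, pl$total)
      grads <- lapply(pl$ids, function(id) g[[id]])
      if (config$steps == "per_patient") {
        upd <- adam_step(params, grads, state, config$lr)
        params <- upd$params
        state <- upd$state
      } else {
        acc_grads <- if (is.null(acc_grads)) grads else
          mapply(function(a, b) {
            if (is.null(a)) b else if (is.null(b)) a else a + b
          }, acc_grads, grads, SIMPLIFY = FALSE)
      }
      sums <- sums + pl$breakdown
      if (config$memory_refresh == "per_step") {
        E_m_star <- compute_drug_embeddings(params, A_E, A_D, config)
        memory <- build_patient_memory(params, train, E_m_star, config)
      }
    }
    if (config$steps == "per_epoch") {
      upd <- adam_step(params, acc_grads, state, config$lr)
      params <- upd$params
      state <- upd$state
    }
    means <- sums / length(records)

    val_j <- NA_real_
    if (!is.null(validation)) {
      E_m_star <- compute_drug_embeddings(params, A_E, A_D, config)
      memory <- build_patient_memory(params, train, E_m_star, config)
      ev <- evaluate_cohort(params, validation, E_m_star, memory, A_D, config)
      val_j <- ev$jaccard
      if (val_j > best$jaccard) {
        best <- list(jaccard = val_j, params = params, epoch = epoch)
      }
    }
    history <- rbind(history, data.frame(epoch = epoch, ddi = means[["ddi"]],
                                         mp = means[["mp"]], ic = means[["ic"]],
                                         total = means[["total"]],
                                         val_jaccard = val_j))
    if (verbose)
      message(sprintf(
        "epoch %3d  L_ddi %.4f  L_mp %.4f  L_ic %.4f  L_total %.4f  val_jaccard %s",
        epoch, means[["ddi"]], means[["mp"]], means[["ic"]], means[["total"]],
        ifelse(is.na(val_j), "-", sprintf("%.4f", val_j))))
  }

  final_params <- if (is.null(validation)) params else best$params
  E_m_star <- compute_drug_embeddings(final_params, A_E, A_D, config)
  memory <- build_patient_memory(final_params, train, E_m_star, config)
  structure(list(params = final_params, memory = memory, config = config,
                 E_m_star = E_m_star, A_E = A_E, A_D = A_D,
                 vocab_d = train$vocab_d, vocab_p = train$vocab_p,
                 vocab_m = train$vocab_m, history = history,
                 best_epoch = if (is.null(validation)) config$epochs
                              else best$epoch),
            class = "medrec_model")
}

#' @export
print.medrec_model <- function(x, ...) {
  cat(sprintf(
    "<medrec_model: dim=%d, |D|=%d |P|=%d |M|=%d, %d epochs (best %d), %d memory entries>\n",
    x$config$dim, length(x$vocab_d), length(x$vocab_p), length(x$vocab_m),
    nrow(x$history), x$best_epoch, length(x$memory$patient_ids)))
  invisible(x)
}

# ---- prediction --------------------------------------------------------

#' Score and decode one patient's visits
#'
#' Runs the full pipeline (embed, attend, retrieve, match, threshold) on
#' every visit of `record`, using the model's stored memory for the
#' cross-patient channel and the record's own earlier visits for the
#' personal channel.
#'
#' @param model a trained `medrec_model`.
#' @param record a [patient_record()].
#' @return list with `scores` and `pred` matrices (visits x drugs) and the
#'   per-visit representations `q`.
#' @export
predict_patient <- function(model, record) {
  encode_patient(model$params, record, model$E_m_star, model$memory,
                 model$config)
}

#' Recommend drugs for a patient's current visit
#'
#' @param model a trained `medrec_model`.
#' @param record a [patient_record()]; the last visit is treated as the
#'   current one (its drug set, if present, is ignored for scoring).
#' @return data.frame of drug codes and scores, sorted by score, with a
#'   `predicted` flag at the model's threshold.
#' @export
recommend <- function(model, record) {
  enc <- predict_patient(model, record)
  t <- length(record$visits)
  o <- enc$scores[t, ]
  out <- data.frame(drug = model$vocab_m$codes, score = o,
                    predicted = as.logical(enc$pred[t, ]))
  out[order(-out$score), ]
}

# ---- checkpointing -----------------------------------------------------

#' Save a trained model
#'
#' Single-file archive (RDS) holding the parameter tensors, vocabularies,
#' memory, graphs and resolved configuration, with a schema version field.
#'
#' @param model a `medrec_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "medrec_model"))
  obj <- unclass(model)
  obj$schema <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return a `medrec_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema) || obj$schema != 1L)
    stop("unrecognised checkpoint schema")
  obj$schema <- NULL
  structure(obj, class = "medrec_model")
}
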