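# Evaluation: per-visit Jaccard, F1, PR-AUC, ROC-AUC averaged over visits,
# DDI rate of the predicted combinations, and the bootstrap protocol.

# average precision of scores against binary truth (PR-AUC, one visit)
average_precision <- function(scores, truth) {
  ord <- order(-scores)
  truth <- truth[ord]
  npos <- sum(truth)
  if (npos == 0L) return(NA_real_)
  tp <- cumsum(truth)
  prec <- tp / seq_along(truth)
  sum(prec[truth == 1]) / npos
}

# ROC-AUC via the rank (Mann-Whitney) statistic, ties mid-ranked
rank_auc <- function(scores, truth) {
  npos <- sum(truth == 1)
  nneg <- sum(truth == 0)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluation metrics over a set of visits
#'
#' Jaccard and F1 are per-visit set-overlap statistics averaged over visits
#' (two empty sets count as perfect agreement); PR-AUC and ROC-AUC are
#' per-visit areas from the scores, averaged over visits that contain both a
#' positive and a negative label (degenerate visits are skipped and
#' counted); the DDI rate is the fraction of all predicted unordered drug
#' pairs that interact; `avg_drugs` is the mean predicted set size.
#'
#' @param pred list of binary prediction vectors (one per visit).
#' @param truth list of binary ground-truth vectors.
#' @param scores list of score vectors.
#' @param A_D binary DDI adjacency.
#' @return a `metrics_report` list.
#' @export
compute_metrics <- function(pred, truth, scores, A_D) {
  n <- length(pred)
  if (n == 0L || length(truth) != n || length(scores) != n)
    stop("compute_metrics: empty or misaligned inputs")
  jac <- f1 <- prauc <- rocauc <- numeric(n)
  ddi_pairs <- 0; all_pairs <- 0; sizes <- numeric(n)
  for (k in seq_len(n)) {
    p <- pred[[k]]; m <- truth[[k]]; o <- scores[[k]]
    inter <- sum(p == 1 & m == 1)
    uni <- sum(p == 1 | m == 1)
    jac[k] <- if (uni == 0) 1 else inter / uni
    np <- sum(p); nm <- sum(m)
    prec <- if (np == 0) 0 else inter / np
    rec <- if (nm == 0) 0 else inter / nm
    f1[k] <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    prauc[k] <- average_precision(o, m)
    rocauc[k] <- rank_auc(o, m)
    sizes[k] <- np
    ix <- which(p == 1)
    if (length(ix) >= 2L) {
      all_pairs <- all_pairs + choose(length(ix), 2)
      ddi_pairs <- ddi_pairs + sum(A_D[ix, ix]) / 2
    }
  }
  skipped <- sum(is.na(rocauc))
  if (skipped > 0L)
    message(sprintf("AUC: skipped %d single-class visit(s)", skipped))
  structure(list(
    ddi_rate = if (all_pairs == 0) 0 else ddi_pairs / all_pairs,
    jaccard = mean(jac), f1 = mean(f1),
    pr_auc = mean(prauc, na.rm = TRUE), roc_auc = mean(rocauc, na.rm = TRUE),
    avg_drugs = mean(sizes), n_visits = n, n_auc_skipped = skipped),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("DDI rate %.4f | Jaccard %.4f | F1 %.4f | PR-AUC %.4f",
                     " | ROC-AUC %.4f | avg drugs %.2f (%d visits)\n"),
              x$ddi_rate, x$jaccard, x$f1, x$pr_auc, x$roc_auc, x$avg_drugs,
              x$n_visits))
  invisible(x)
}

# run the full pipeline over a cohort and compute metrics
evaluate_cohort <- function(params, x, E_m_star, memory, A_D, config) {
  pred <- list(); truth <- list(); scores <- list()
  M <- length(x$vocab_m)
  for (rec in x$records) {
    enc <- encode_patient(params, rec, E_m_star, memory, config)
    for (t in seq_along(rec$visits)) {
      pred <- c(pred, list(enc$pred[t, ]))
      truth <- c(truth, list(encode_multihot(rec$visits[[t]]$m, M)))
      scores <- c(scores, list(enc$scores[t, ]))
    }
  }
  suppressMessages(compute_metrics(pred, truth, scores, A_D))
}

#' Evaluate a trained model on a cohort
#'
#' @param model a `medrec_model`.
#' @param x a [cohort()] (typically the test split).
#' @return a `metrics_report`.
#' @export
evaluate_model <- function(model, x) {
  evaluate_cohort(model$params, x, model$E_m_star, model$memory, model$A_D,
                  model$config)
}

#' Bootstrap evaluation over test-set resamples
#'
#' Each round samples `fraction` of the test patients without replacement
#' (seeded) and computes the metric report on the subsample; per-metric mean
#' and standard deviation over rounds are reported.
#'
#' @param model a `medrec_model`.
#' @param x test [cohort()].
#' @param rounds number of rounds (`>= 1`).
#' @param fraction patient fraction per round; 1.0 reduces every round to
#'   the full test set.
#' @param seed integer seed.
#' @return list with `mean`, `sd` (named metric vectors) and the per-round
#'   data.frame `rounds`.
#' @export
bootstrap_evaluate <- function(model, x, rounds = 10L, fraction = 0.8,
                               seed = 1L) {
  stopifnot(rounds >= 1L, inherits(x, "cohort"))
  if (length(x$records) == 0L) stop("empty test cohort")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  keys <- c("ddi_rate", "jaccard", "f1", "pr_auc", "roc_auc", "avg_drugs")
  out <- matrix(0, rounds, length(keys), dimnames = list(NULL, keys))
  N <- length(x$records)
  n_take <- max(1L, round(fraction * N))
  for (r in seq_len(rounds)) {
    ix <- sort(sample.int(N, n_take))
    sub <- cohort(x$records[ix], x$vocab_d, x$vocab_p, x$vocab_m)
    rep_r <- evaluate_model(model, sub)
    out[r, ] <- unlist(rep_r[keys])
  }
  list(mean = colMeans(out), sd = apply(out, 2L, stats::sd),
       rounds = as.data.frame(out))
}

#' Frequency and random drug-set baselines
#'
#' The frequency baseline predicts the `k` most frequent training drugs for
#' every visit, with `k` the rounded mean training drug-set size; the random
#' baseline predicts a uniform random set of the same size.
#'
#' @param train training [cohort()] (defines frequencies and `k`).
#' @param x evaluation cohort.
#' @param A_D DDI adjacency.
#' @param which `"topk"` or `"random"`.
#' @param seed seed for the random baseline.
#' @return a `metrics_report`.
#' @export
baseline_metrics <- function(train, x, A_D, which = c("topk", "random"),
                             seed = 1L) {
  which <- match.arg(which)
  M <- length(train$vocab_m)
  counts <- numeric(M)
  sizes <- c()
  for (rec in train$records) for (v in rec$visits) {
    counts[v$m + 1L] <- counts[v$m + 1L] + 1
    sizes <- c(sizes, length(v$m))
  }
  k <- max(1L, round(mean(sizes)))
  topk <- numeric(M)
  topk[order(-counts)[seq_len(k)]] <- 1
  scores_topk <- counts / max(counts, 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  pred <- list(); truth <- list(); scores <- list()
  for (rec in x$records) for (v in rec$visits) {
    if (which == "topk") {
      p <- topk
      s <- scores_topk
    } else {
      p <- numeric(M)
      p[sample.int(M, min(k, M))] <- 1
      s <- stats::runif(M)
    }
    pred <- c(pred, list(p))
    truth <- c(truth, list(encode_multihot(v$m, M)))
    scores <- c(scores, list(s))
  }
  suppressMessages(compute_metrics(pred, truth, scores, A_D))
}
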