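# Training configuration: hyperparameters, loss weights and ablation
# switches, with the defaults used throughout.

#' Training configuration
#'
#' Defaults follow the reference setting: embedding dimension 64, Adam with
#' learning rate 2e-4, 50 epochs, loss balance `mu = 0.05` and loss weights
#' `(lambda1, lambda2, lambda3) = (0.2, 0.75, 0.05)`, decision threshold
#' `psi = 0.5`, graph-fusion scalar initialised at 0.5.
#'
#' @param dim embedding dimension.
#' @param lr Adam learning rate.
#' @param epochs training epochs (`>= 1`).
#' @param mu balance between margin and BCE inside the prediction loss.
#' @param lambda1,lambda2,lambda3 weights of the DDI, prediction and
#'   information-constraint losses.
#' @param psi decoding threshold in `(0, 1)`.
#' @param delta_init initial value of the learnable graph-fusion scalar.
#' @param renyi_alpha entropy order for the information constraint.
#' @param renyi_sigma fixed kernel bandwidth; `NULL` = median-distance rule.
#' @param top_n memory entries retained by the cross-patient channel.
#' @param split train/validation/test fractions.
#' @param seed integer seed controlling initialisation and data order.
#' @param visit_attention_norm `"ratio"` (literal) or `"softmax"`.
#' @param share_gcn_weights share GCN weights between the EHR and DDI
#'   branches.
#' @param memory_refresh `"per_epoch"` (default) or `"per_step"` memory
#'   recomputation.
#' @param steps optimiser step granularity: `"per_visit"` (one Adam step
#'   per visit, the convention of the memory-network drug-recommendation
#'   lineage, default), `"per_patient"` (accumulate over a patient's visits,
#'   one step) or `"per_epoch"` (accumulate over the whole epoch).
#' @param bootstrap_rounds,bootstrap_fraction test-resampling protocol.
#' @param use_diagnoses,use_procedures,use_drug_history drop an input code
#'   type when `FALSE`.
#' @param use_code_attention,use_visit_attention disable an attention
#'   mechanism (gates become 1, weights become uniform).
#' @param use_ehr_graph,use_ddi_graph drop a graph branch of the drug
#'   encoder.
#' @param use_hpat drop the cross-patient similarity channel.
#' @param use_h drop both historical similarity channels.
#' @return a `train_config` list.
#' @export
train_config <- function(dim = 64L, lr = 2e-4, epochs = 50L, mu = 0.05,
                         lambda1 = 0.2, lambda2 = 0.75, lambda3 = 0.05,
                         psi = 0.5, delta_init = 0.5, renyi_alpha = 1.01,
                         renyi_sigma = NULL, top_n = 10L,
                         split = c(2 / 3, 1 / 6, 1 / 6), seed = 1L,
                         visit_attention_norm = c("ratio", "softmax"),
                         share_gcn_weights = FALSE,
                         memory_refresh = c("per_epoch", "per_step"),
                         steps = c("per_visit", "per_patient", "per_epoch"),
                         bootstrap_rounds = 10L, bootstrap_fraction = 0.8,
                         use_diagnoses = TRUE, use_procedures = TRUE,
                         use_drug_history = TRUE,
                         use_code_attention = TRUE,
                         use_visit_attention = TRUE,
                         use_ehr_graph = TRUE, use_ddi_graph = TRUE,
                         use_hpat = TRUE, use_h = TRUE) {
  cfg <- list(dim = as.integer(dim), lr = lr, epochs = as.integer(epochs),
              mu = mu, lambda1 = lambda1, lambda2 = lambda2,
              lambda3 = lambda3, psi = psi, delta_init = delta_init,
              renyi_alpha = renyi_alpha, renyi_sigma = renyi_sigma,
              top_n = as.integer(top_n), split = split,
              seed = as.integer(seed),
              visit_attention_norm = match.arg(visit_attention_norm),
              share_gcn_weights = share_gcn_weights,
              memory_refresh = match.arg(memory_refresh),
              steps = match.arg(steps),
              bootstrap_rounds = as.integer(bootstrap_rounds),
              bootstrap_fraction = bootstrap_fraction,
              use_diagnoses = use_diagnoses,
              use_procedures = use_procedures,
              use_drug_history = use_drug_history,
              use_code_attention = use_code_attention,
              use_visit_attention = use_visit_attention,
              use_ehr_graph = use_ehr_graph,
              use_ddi_graph = use_ddi_graph,
              use_hpat = use_hpat, use_h = use_h)
  stopifnot(cfg$dim > 0L, cfg$epochs >= 1L, cfg$mu >= 0, cfg$mu <= 1,
            cfg$lambda1 >= 0, cfg$lambda2 >= 0, cfg$lambda3 >= 0,
            cfg$psi > 0, cfg$psi < 1, cfg$renyi_alpha > 0,
            cfg$renyi_alpha != 1, cfg$top_n >= 1L)
  structure(cfg, class = "train_config")
}
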