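# Shared fixtures: tiny hand-built cohorts and random model instances.

tiny_vocabs <- function(nd = 5L, np = 3L, nm = 4L) {
  list(d = code_vocabulary("diagnosis", sprintf("D%02d", seq_len(nd) - 1L)),
       p = code_vocabulary("procedure", sprintf("P%02d", seq_len(np) - 1L)),
       m = code_vocabulary("drug", sprintf("M%02d", seq_len(nm) - 1L)))
}

# a fixed 3-patient cohort over the tiny vocabularies
tiny_cohort <- function() {
  v <- tiny_vocabs()
  recs <- list(
    patient_record("A", list(visit(c(0, 2), 0, c(0, 1)),
                             visit(1, c(1, 2), c(1, 2)))),
    patient_record("B", list(visit(3, integer(), c(0, 3)),
                             visit(c(3, 4), 2, c(2, 3)),
                             visit(4, integer(), 3))),
    patient_record("C", list(visit(0, 1, integer()),
                             visit(2, integer(), c(0, 2)))))
  cohort(recs, v$d, v$p, v$m)
}

# small random cohort via the generator (seeded)
small_cohort <- function(n = 12L, seed = 2L) {
  generate_cohort(synth_params(
    n_patients = n, n_diag = 10L, n_proc = 6L, n_drug = 7L, n_latent = 3L,
    codes_per_visit = c(d = 3, p = 2, m = 3),
    signature_sizes = c(d = 4L, p = 3L, m = 3L), seed = seed))
}

# random parameter set plus graphs and memory for a small model
small_model_fixture <- function(seed = 5L, dim = 8L, ...) {
  cfg <- train_config(dim = dim, seed = seed, top_n = 3L, ...)
  ch <- small_cohort()
  A_E <- build_ehr_graph(ch)
  A_D <- build_ddi_graph(generate_ddi_pairs(ch$vocab_m, 0.3, 1L), ch$vocab_m)
  params <- init_params(length(ch$vocab_d), length(ch$vocab_p),
                        length(ch$vocab_m), cfg)
  E_m_star <- medrec:::compute_drug_embeddings(params, A_E, A_D, cfg)
  memory <- build_patient_memory(params, ch, E_m_star, cfg)
  list(cfg = cfg, cohort = ch, A_E = A_E, A_D = A_D, params = params,
       E_m_star = E_m_star, memory = memory,
       NE = medrec:::normalize_adjacency(A_E),
       ND = medrec:::normalize_adjacency(A_D))
}

rand_mat <- function(r, c) matrix(stats::rnorm(r * c), r, c)
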