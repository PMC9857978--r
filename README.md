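# medrec — medication recommendation from longitudinal EHR visit sequences

`medrec` predicts per-visit drug combinations from longitudinal electronic
health records. Given a patient's visit history — each visit a set of
diagnosis, procedure and drug codes — and the current visit's diagnoses and
procedures, it scores every drug in the vocabulary and decodes a
recommended combination, trading prediction accuracy against the rate of
known drug–drug interactions (DDIs) in the recommended set.

The model combines four ingredients:

* **a dual-attention patient encoder** — visits are embedded additively
  from code-embedding tables; two GRUs over the history produce a
  per-visit tanh gate (code-level attention) and normalised scalar weights
  (visit-level attention), fused with the current visit into a patient
  state `q_t = e_t + Σ_j β_j (α_j ⊙ e_j)`;
* **a graph-convolutional drug encoder** — two-layer GCNs over the
  co-prescription graph `A_E` and the DDI graph `A_D`, fused as
  `E_m* = G_e + δ G_d` with a learnable `δ`;
* **patient-similarity retrieval** — a memory of (state, drug-set) pairs
  from training visits; retrieval channels over the drug table
  (`C = E_m*ᵀ softmax(E_m* q)`), the patient's own earlier visits, and the
  top-n most cosine-similar visits of other patients;
* **a composite training objective** —
  `λ₁·Σ_ij A_D[i,j] o_i o_j  +  λ₂·[(1−μ)·margin + μ·BCE]  +  λ₃·H_α(q)`,
  where `H_α` is the matrix-based Rényi α-entropy of the patient's visit
  representations (an information-bottleneck constraint), with defaults
  `μ = 0.05`, `(λ₁, λ₂, λ₃) = (0.2, 0.75, 0.05)`, dim 64, Adam at 2e-4.

Training runs on a reverse-mode autodiff tape implemented in the package
(no external deep-learning framework), validated op-by-op against finite
differences in the test suite. Because credentialed ICU data cannot ship
with a package, a seeded synthetic-cohort generator with latent-condition
structure provides training and test data with the statistical shape of a
de-identified ICU cohort; see the methods vignette
(`vignettes/methods.Rmd`) for the generative law and its limits.

## Worked example

```r
library(medrec)

ch    <- generate_cohort(synth_params(seed = 1))   # 300 patients, |M| = 25
parts <- split_cohort(ch, c(2/3, 1/6, 1/6), seed = 1)
A_E   <- build_ehr_graph(parts$train)
A_D   <- build_ddi_graph(generate_ddi_pairs(ch$vocab_m, 0.08, 1), ch$vocab_m)

model <- train_model(parts$train, parts$validation, A_E, A_D,
                     train_config(epochs = 30), verbose = FALSE)
evaluate_model(model, parts$test)
#> DDI rate 0.0202 | Jaccard 0.7285 | F1 0.8349 | PR-AUC 0.8929 | ROC-AUC 0.9289 | avg drugs 9.61 (122 visits)

baseline_metrics(parts$train, parts$test, A_D, "topk")
#> DDI rate 0.0444 | Jaccard 0.3684 | F1 0.5301 | PR-AUC 0.6209 | ROC-AUC 0.6513 | avg drugs 10.00 (122 visits)
```

The trained model roughly doubles the Jaccard overlap of the
most-frequent-drugs baseline on the held-out patients while cutting the
DDI rate of its recommendations to about half of the baseline's. Per-visit
recommendations for one patient:

```r
head(recommend(model, parts$test$records[[1]]), 3)
#>    drug     score predicted
#> 16 M015 0.9999898      TRUE
#> 20 M019 0.9999848      TRUE
#> 1  M000 0.9997910      TRUE
```

A command-line interface wraps the same functions
(`exec/medrec`, installed with the package):

```sh
medrec simulate --n-patients 300 --seed 1 --out cohort.jsonl --ddi-out ddi.tsv
medrec train    --cohort cohort.jsonl --ddi ddi.tsv --epochs 30 --out model.rds
medrec evaluate --checkpoint model.rds --cohort cohort.jsonl --ddi ddi.tsv --rounds 10
medrec recommend --checkpoint model.rds --patient patient.json
```

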