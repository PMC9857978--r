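# Seeded synthetic EHR cohort generator.
#
# A latent-condition topic model: each of a small number of chronic
# conditions owns fixed sparse code signatures over the diagnosis, procedure
# and drug vocabularies, allocated with balanced coverage so no code
# dominates the marginals. A patient carries one or more active conditions;
# at every visit each active condition emits each code of its signature
# independently with a per-type emission rate (derived from the target
# per-visit code counts), each emitted code is replaced by a uniform random
# code with probability `noise_rate`, and each condition persists to the
# next visit with a fixed probability. The drug set of a visit is therefore
# close to the union of the active conditions' drug signatures — diagnoses
# are predictive of drugs, and the visit history is informative about the
# current state, which is exactly the structure a history-aware recommender
# assumes.

#' Parameters of the synthetic cohort generator
#'
#' Defaults are the desk-scale profile used throughout the package: 300
#' patients, vocabularies of 40 diagnoses / 20 procedures / 25 drugs, 8
#' latent conditions. Per-visit code-count targets follow the shape of a
#' de-identified ICU cohort (about 10.5 diagnoses, 3.8 procedures and 11.2
#' drugs per visit, mean 2.37 visits per patient with a long tail capped at
#' 29).
#'
#' @param n_patients number of patients.
#' @param n_diag,n_proc,n_drug vocabulary sizes.
#' @param n_latent number of latent conditions.
#' @param visit_mean target mean number of visits (truncated geometric,
#'   minimum 2).
#' @param visit_max cap on the visit count.
#' @param codes_per_visit named numeric vector `c(d=, p=, m=)` of mean code
#'   counts per visit.
#' @param signature_sizes named integer vector `c(d=, p=, m=)`: codes owned
#'   by each latent condition.
#' @param comorbidity_rate probability a patient carries a second latent
#'   condition in addition to the first.
#' @param persistence probability an active condition carries over to the
#'   next visit.
#' @param onset_rate probability a new condition starts at a follow-up visit.
#' @param noise_rate probability an emitted code is replaced by a uniform
#'   random code from the whole vocabulary.
#' @param ddi_density expected fraction of unordered drug pairs interacting.
#' @param seed integer RNG seed.
#' @return a `synth_params` list.
#' @export
synth_params <- function(n_patients = 300L, n_diag = 40L, n_proc = 20L,
                         n_drug = 25L, n_latent = 8L,
                         visit_mean = 2.37, visit_max = 29L,
                         codes_per_visit = c(d = 10.5, p = 3.8, m = 11.2),
                         signature_sizes = c(d = 8L, p = 5L, m = 8L),
                         comorbidity_rate = 0.7,
                         persistence = 0.8, onset_rate = 0.1,
                         noise_rate = 0.05, ddi_density = 0.08,
                         seed = 1L) {
  name3 <- function(x) {
    if (is.null(names(x))) names(x) <- c("d", "p", "m")
    x
  }
  codes_per_visit <- name3(codes_per_visit)
  signature_sizes <- name3(signature_sizes)
  p <- list(n_patients = as.integer(n_patients), n_diag = as.integer(n_diag),
            n_proc = as.integer(n_proc), n_drug = as.integer(n_drug),
            n_latent = as.integer(n_latent), visit_mean = visit_mean,
            visit_max = as.integer(visit_max),
            codes_per_visit = codes_per_visit,
            signature_sizes = signature_sizes,
            comorbidity_rate = comorbidity_rate, persistence = persistence,
            onset_rate = onset_rate, noise_rate = noise_rate,
            ddi_density = ddi_density, seed = as.integer(seed))
  stopifnot(p$n_patients > 0L, p$n_latent > 0L, p$visit_mean >= 2,
            p$comorbidity_rate >= 0, p$comorbidity_rate <= 1,
            p$persistence >= 0, p$persistence <= 1,
            p$noise_rate >= 0, p$noise_rate <= 1,
            p$ddi_density >= 0, p$ddi_density <= 1)
  sizes <- c(d = p$n_diag, p = p$n_proc, m = p$n_drug)
  if (any(p$signature_sizes > sizes))
    stop("signature size exceeds vocabulary size")
  structure(p, class = "synth_params")
}

# success probability of the geometric law with the given truncated mean
.visit_geom_p <- function(visit_mean, visit_max) {
  target <- visit_mean
  f <- function(p) {
    k <- 2:visit_max
    w <- p * (1 - p)^(k - 2)
    sum(k * w) / sum(w) - target
  }
  stats::uniroot(f, c(1e-6, 1 - 1e-6))$root
}

#' Generate a synthetic cohort
#'
#' Fully deterministic given `params$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param params a [synth_params()] object.
#' @return a [cohort()].
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  vd <- code_vocabulary("diagnosis", sprintf("D%03d", seq_len(params$n_diag) - 1L))
  vp <- code_vocabulary("procedure", sprintf("P%03d", seq_len(params$n_proc) - 1L))
  vm <- code_vocabulary("drug", sprintf("M%03d", seq_len(params$n_drug) - 1L))

  # fixed sparse signatures per latent condition (0-based indices), built
  # with inverse-frequency weighting so coverage of the vocabulary stays
  # balanced and no code dominates the marginal distribution
  balanced_signatures <- function(V, size) {
    counts <- numeric(V)
    lapply(seq_len(params$n_latent), function(c) {
      w <- 1 / (1 + counts)
      s <- sample.int(V, size, prob = w)
      counts[s] <<- counts[s] + 1
      sort(s - 1L)
    })
  }
  sig_d <- balanced_signatures(params$n_diag, params$signature_sizes[["d"]])
  sig_p <- balanced_signatures(params$n_proc, params$signature_sizes[["p"]])
  sig_m <- balanced_signatures(params$n_drug, params$signature_sizes[["m"]])
  sig <- lapply(seq_len(params$n_latent), function(c)
    list(d = sig_d[[c]], p = sig_p[[c]], m = sig_m[[c]]))

  pgeo <- .visit_geom_p(params$visit_mean, params$visit_max)
  sizes <- c(d = params$n_diag, p = params$n_proc, m = params$n_drug)

  # per-type emission rates chosen so the expected number of distinct
  # signature codes per visit matches codes_per_visit, given the expected
  # number of active conditions and the expected signature union size
  mean_active <- 1 + params$comorbidity_rate
  emit_rate <- vapply(c(d = "d", p = "p", m = "m"), function(fld) {
    s <- params$signature_sizes[[fld]]
    V <- sizes[[fld]]
    union2 <- 2 * s - s^2 / V
    slots <- (1 - params$comorbidity_rate) * s + params$comorbidity_rate * union2
    min(0.95, params$codes_per_visit[[fld]] / slots)
  }, 0)

  emit <- function(active, fld) {
    pool <- unique(unlist(lapply(sig[active], `[[`, fld)))
    out <- pool[stats::runif(length(pool)) < emit_rate[[fld]]]
    flip <- stats::runif(length(out)) < params$noise_rate
    if (any(flip))
      out[flip] <- sample.int(sizes[[fld]], sum(flip), replace = TRUE) - 1L
    sort(unique(out))
  }

  records <- vector("list", params$n_patients)
  for (i in seq_len(params$n_patients)) {
    Ti <- 2L
    while (stats::runif(1) > pgeo && Ti < params$visit_max) Ti <- Ti + 1L
    n_active <- 1L + stats::rbinom(1L, 1L, params$comorbidity_rate)
    active <- sample.int(params$n_latent, min(n_active, params$n_latent))
    visits <- vector("list", Ti)
    for (t in seq_len(Ti)) {
      visits[[t]] <- visit(emit(active, "d"), emit(active, "p"),
                           emit(active, "m"))
      keep <- active[stats::runif(length(active)) < params$persistence]
      if (stats::runif(1) < params$onset_rate) {
        fresh <- setdiff(seq_len(params$n_latent), keep)
        if (length(fresh)) keep <- c(keep, sample(fresh, 1L))
      }
      if (length(keep) == 0L) keep <- sample.int(params$n_latent, 1L)
      active <- keep
    }
    records[[i]] <- patient_record(sprintf("PT%04d", i), visits)
  }
  cohort(records, vd, vp, vm)
}

#' Generate a random DDI pair list
#'
#' Each unordered drug pair is included independently with probability
#' `density`; deterministic given `seed`.
#'
#' @param vocab_m drug [code_vocabulary()].
#' @param density inclusion probability in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return two-column character matrix of drug-code pairs.
#' @export
generate_ddi_pairs <- function(vocab_m, density = 0.08, seed = 1L) {
  stopifnot(density >= 0, density <= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  M <- length(vocab_m)
  if (M < 2L) return(matrix(character(), ncol = 2L,
                            dimnames = list(NULL, c("drug_a", "drug_b"))))
  pairs <- which(upper.tri(matrix(0, M, M)), arr.ind = TRUE)
  take <- stats::runif(nrow(pairs)) < density
  out <- cbind(drug_a = vocab_m$codes[pairs[take, 1L]],
               drug_b = vocab_m$codes[pairs[take, 2L]])
  if (!is.matrix(out)) out <- matrix(out, ncol = 2L,
                                     dimnames = list(NULL, c("drug_a", "drug_b")))
  out
}

#' Summary statistics of a cohort
#'
#' Reports patient and visit counts, vocabulary sizes, mean/max visits per
#' patient, mean/max codes per visit by type, and the visit-count histogram.
#'
#' @param x a [cohort()].
#' @return a list with a `table` data.frame and a `visit_histogram`.
#' @export
summarize_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  Ts <- vapply(x$records, function(r) length(r$visits), 0L)
  per_visit <- function(fld) unlist(lapply(x$records, function(r)
    vapply(r$visits, function(v) length(v[[fld]]), 0L)))
  nd <- per_visit("d"); np <- per_visit("p"); nm <- per_visit("m")
  tab <- data.frame(
    item = c("patients", "clinical events", "diagnoses", "procedures",
             "drugs", "avg visits", "max visits",
             "avg diagnoses per visit", "max diagnoses per visit",
             "avg procedures per visit", "max procedures per visit",
             "avg drugs per visit", "max drugs per visit"),
    value = c(length(x$records), sum(Ts), length(x$vocab_d),
              length(x$vocab_p), length(x$vocab_m), mean(Ts), max(Ts),
              mean(nd), max(nd), mean(np), max(np), mean(nm), max(nm)))
  list(table = tab, visit_histogram = table(Ts))
}
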