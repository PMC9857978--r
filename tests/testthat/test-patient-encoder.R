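rand_gru <- function(d) {
  W <- lapply(medrec:::gru_param_names, function(nm)
    if (startsWith(nm, "b")) matrix(0, d, 1) else rand_mat(d, d))
  names(W) <- medrec:::gru_param_names
  W
}

test_that("visit embedding is the multi-hot row sum of the tables", {
  d <- 6
  tabs <- list(E_d = rand_mat(5, d), E_p = rand_mat(3, d),
               E_m_star = rand_mat(4, d))
  v1 <- visit(2, integer(), integer())
  expect_equal(embed_visit(v1, tabs), tabs$E_d[3, ])
  expect_equal(embed_visit(visit(), tabs), numeric(d))
  v2 <- visit(c(0, 3), integer(), integer())
  expect_equal(embed_visit(v2, tabs), tabs$E_d[1, ] + tabs$E_d[4, ])
  v3 <- visit(1, 0, c(1, 2))
  expect_equal(embed_visit(v3, tabs),
               tabs$E_d[2, ] + tabs$E_p[1, ] + tabs$E_m_star[2, ] +
                 tabs$E_m_star[3, ])
  expect_equal(embed_visit(v3, tabs, include_drugs = FALSE),
               tabs$E_d[2, ] + tabs$E_p[1, ])
})

test_that("code attention follows the gated recurrence", {
  set.seed(31)
  d <- 5
  prm <- list(rnn_c = rand_gru(d), W_g = rand_mat(d, d),
              b_g = matrix(0, d, 1))
  hist <- replicate(3, rnorm(d), simplify = FALSE)

  # zero affine map annihilates every gate
  prm0 <- prm; prm0$W_g <- matrix(0, d, d)
  a0 <- code_attention(hist, prm0)
  expect_true(all(vapply(a0, function(a) all(a == 0), TRUE)))
  # large positive bias saturates tanh at 1
  prm1 <- prm0; prm1$b_g <- matrix(50, d, 1)
  expect_equal(code_attention(hist, prm1)[[2]], rep(1, d), tolerance = 1e-12)

  # hand-unrolled recurrence oracle
  a <- code_attention(hist, prm)
  h <- numeric(d)
  for (j in 1:3) {
    W <- prm$rnn_c
    z <- plogis(W$Wz %*% hist[[j]] + W$Uz %*% h + W$bz)
    r <- plogis(W$Wr %*% hist[[j]] + W$Ur %*% h + W$br)
    cc <- tanh(W$Wh %*% hist[[j]] + W$Uh %*% (r * h) + W$bh)
    h <- as.vector((1 - z) * h + z * cc)
    expect_equal(a[[j]], as.vector(tanh(prm$W_g %*% h + prm$b_g)),
                 tolerance = 1e-6)
  }
  expect_true(all(unlist(a) > -1 & unlist(a) < 1))
})

test_that("visit attention normalises to one and falls back gracefully", {
  set.seed(32)
  d <- 5
  prm <- list(rnn_v = rand_gru(d), W_h = rand_mat(1, d))
  hist4 <- replicate(4, rnorm(d), simplify = FALSE)
  b <- visit_attention(hist4, prm)
  expect_equal(sum(b), 1, tolerance = 1e-6)

  # identical raw readouts (equal hidden states) normalise to uniform
  expect_equal(medrec:::.normalize_beta(rep(0.4, 3), "ratio"), rep(1 / 3, 3),
               tolerance = 1e-12)
  # single history visit trivially gets all the weight
  expect_equal(visit_attention(hist4[1], prm), 1)
  # zero readout triggers the uniform fallback
  prm0 <- prm; prm0$W_h <- matrix(0, 1, d)
  expect_message(bu <- visit_attention(hist4, prm0), "uniform")
  expect_equal(bu, rep(1 / 4, 4))
  # softmax variant also sums to one
  expect_equal(sum(visit_attention(hist4, prm, norm = "softmax")), 1,
               tolerance = 1e-12)

  # oracle unroll of the ratio rule
  h <- numeric(d); raws <- numeric(4)
  for (j in 1:4) {
    h <- medrec:::gru_step(prm$rnn_v, hist4[[j]], h)
    raws[j] <- as.numeric(prm$W_h %*% h)
  }
  expect_equal(b, raws / sum(raws), tolerance = 1e-6)
})

test_that("patient representation composes attention as a weighted gated sum", {
  set.seed(33)
  d <- 4
  cur <- rnorm(d)
  hist <- replicate(2, rnorm(d), simplify = FALSE)
  expect_equal(patient_representation(cur, list()), cur)
  ones <- list(rep(1, d))
  expect_equal(patient_representation(cur, hist[1], ones, 1),
               cur + hist[[1]])
  zer <- replicate(2, rep(0, d), simplify = FALSE)
  expect_equal(patient_representation(cur, hist, zer, c(0.3, 0.7)), cur)
  a <- replicate(2, rnorm(d), simplify = FALSE)
  b <- c(0.2, 0.8)
  expect_equal(patient_representation(cur, hist, a, b),
               cur + b[1] * a[[1]] * hist[[1]] + b[2] * a[[2]] * hist[[2]])
  expect_error(patient_representation(cur, hist, a[1], b), "mismatch")
})

test_that("history order matters to the sequential encoder", {
  fx <- small_model_fixture()
  att <- list(rnn_c = medrec:::.gru_cell(fx$params, "C_"),
              rnn_v = medrec:::.gru_cell(fx$params, "V_"),
              W_g = fx$params$W_g, b_g = fx$params$b_g,
              W_h = fx$params$W_hatt)
  set.seed(34)
  n_diff <- 0L
  for (i in 1:10) {
    hist <- replicate(3, rnorm(fx$cfg$dim), simplify = FALSE)
    a1 <- code_attention(hist, att)
    a2 <- code_attention(rev(hist), att)
    if (!isTRUE(all.equal(a1[[3]], a2[[3]]))) n_diff <- n_diff + 1L
  }
  expect_gt(n_diff, 8L)
})

test_that("full encoder matches an independently unrolled reference", {
  fx <- small_model_fixture()
  p <- fx$params; cfg <- fx$cfg
  rec <- fx$cohort$records[[which.max(vapply(fx$cohort$records,
                                             function(r) length(r$visits), 0L))]]
  t <- 3L
  stopifnot(length(rec$visits) >= t)
  enc <- medrec:::encode_patient(p, rec, fx$E_m_star, fx$memory, cfg)

  # reference: direct multi-hot algebra, step-by-step recurrences
  mh <- function(idx, n) encode_multihot(idx, n)
  M <- nrow(fx$E_m_star)
  fuse <- function(v, drugs) {
    as.vector(mh(v$d, nrow(p$E_d)) %*% p$E_d + mh(v$p, nrow(p$E_p)) %*% p$E_p +
      if (drugs) as.vector(mh(v$m, M) %*% fx$E_m_star) else numeric(cfg$dim))
  }
  hist <- lapply(rec$visits[1:(t - 1)], fuse, drugs = TRUE)
  gC <- numeric(cfg$dim); gV <- numeric(cfg$dim)
  alph <- list(); raw <- numeric(t - 1)
  for (j in 1:(t - 1)) {
    gC <- medrec:::gru_step(medrec:::.gru_cell(p, "C_"), hist[[j]], gC)
    alph[[j]] <- as.vector(tanh(p$W_g %*% gC + p$b_g))
    gV <- medrec:::gru_step(medrec:::.gru_cell(p, "V_"), hist[[j]], gV)
    raw[j] <- as.numeric(p$W_hatt %*% gV)
  }
  beta <- raw / sum(raw)
  q <- fuse(rec$visits[[t]], FALSE)
  for (j in 1:(t - 1)) q <- q + beta[j] * alph[[j]] * hist[[j]]
  expect_equal(enc$q[t, ], q, tolerance = 1e-6)
})
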