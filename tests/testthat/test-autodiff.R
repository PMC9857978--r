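# The autodiff tape underlies training; every op gets a finite-difference
# check, and the composite patient loss is checked end-to-end.

fd_check <- function(build, x0, tol = 1e-5) {
  # build(tape, x_id) -> scalar node; checks d(out)/dx against central FD
  tp <- medrec:::ad_tape()
  xid <- medrec:::ad_param(tp, x0)
  out <- build(tp, xid)
  g <- medrec:::ad_backward(tp, out)
  an <- g[[xid]]
  if (is.null(an)) an <- array(0, dim = dim(x0))
  num <- array(0, dim = dim(x0))
  eps <- 1e-6
  for (k in seq_along(x0)) {
    xp <- x0; xp[k] <- xp[k] + eps
    xm <- x0; xm[k] <- xm[k] - eps
    f <- function(x) {
      tp2 <- medrec:::ad_tape()
      id2 <- medrec:::ad_param(tp2, x)
      medrec:::ad_value(tp2, build(tp2, id2))[1L]
    }
    num[k] <- (f(xp) - f(xm)) / (2 * eps)
  }
  expect_equal(as.vector(an), as.vector(num), tolerance = tol)
}

test_that("elementary tape ops differentiate correctly", {
  set.seed(61)
  W <- rand_mat(3, 4)
  fd_check(function(tp, x) {
    medrec:::ad_sum(tp, medrec:::ad_tanh(tp, medrec:::ad_matmul(
      tp, medrec:::ad_const(tp, W), x)))
  }, rand_mat(4, 2))

  fd_check(function(tp, x) {
    s <- medrec:::ad_softmax(tp, x)
    medrec:::ad_dot(tp, s, medrec:::ad_const(tp, matrix(1:5, 5, 1)))
  }, rand_mat(5, 1))

  b0 <- rand_mat(3, 1)
  fd_check(function(tp, x) {
    y <- medrec:::ad_sigmoid(tp, medrec:::ad_affine(
      tp, medrec:::ad_const(tp, W), x, medrec:::ad_const(tp, b0)))
    medrec:::ad_sum(tp, medrec:::ad_hadamard(tp, y, y))
  }, rand_mat(4, 1))

  fd_check(function(tp, x) {
    medrec:::ad_sum(tp, medrec:::ad_embed_sum(tp, x, c(1L, 3L)))
  }, rand_mat(4, 3))

  v0 <- rand_mat(4, 1)
  fd_check(function(tp, x) {
    medrec:::ad_cosine(tp, x, medrec:::ad_const(tp, v0))
  }, rand_mat(4, 1))

  fd_check(function(tp, x) {
    a <- medrec:::ad_scale_const(tp, x, 2.5)
    b <- medrec:::ad_scale(tp, a, medrec:::ad_const(tp, matrix(0.3)))
    medrec:::ad_sum(tp, medrec:::ad_concat(tp, list(a, b)))
  }, rand_mat(3, 1))
})

test_that("the fused GRU step differentiates correctly", {
  set.seed(62)
  d <- 4
  cell <- lapply(medrec:::gru_param_names, function(nm)
    if (startsWith(nm, "b")) rand_mat(d, 1) * 0.1 else rand_mat(d, d))
  names(cell) <- medrec:::gru_param_names
  h0 <- rand_mat(d, 1)
  # gradient w.r.t. the input x, through two chained steps
  fd_check(function(tp, x) {
    W <- lapply(cell, function(m) medrec:::ad_param(tp, m))
    h <- medrec:::ad_gru_step(tp, W, x, medrec:::ad_const(tp, h0))
    h2 <- medrec:::ad_gru_step(tp, W, x, h)
    medrec:::ad_sum(tp, h2)
  }, rand_mat(d, 1))
  # gradient w.r.t. a cell parameter
  fd_x <- rand_mat(d, 1)
  tp <- medrec:::ad_tape()
  W <- lapply(cell, function(m) medrec:::ad_param(tp, m))
  out <- medrec:::ad_sum(tp, medrec:::ad_gru_step(
    tp, W, medrec:::ad_const(tp, fd_x), medrec:::ad_const(tp, h0)))
  g <- medrec:::ad_backward(tp, out)
  eps <- 1e-6
  for (nm in c("Wz", "Uh", "br")) {
    k <- 3L
    cp <- cell; cp[[nm]][k] <- cp[[nm]][k] + eps
    cm <- cell; cm[[nm]][k] <- cm[[nm]][k] - eps
    val <- function(cc) {
      tp2 <- medrec:::ad_tape()
      W2 <- lapply(cc, function(m) medrec:::ad_param(tp2, m))
      medrec:::ad_value(tp2, medrec:::ad_sum(tp2, medrec:::ad_gru_step(
        tp2, W2, medrec:::ad_const(tp2, fd_x),
        medrec:::ad_const(tp2, h0))))[1L]
    }
    fd <- (val(cp) - val(cm)) / (2 * eps)
    expect_equal(g[[W[[nm]]]][k], fd, tolerance = 1e-5)
  }
})

test_that("fused loss ops differentiate correctly", {
  set.seed(63)
  M <- 5
  A <- matrix(rbinom(M * M, 1, 0.5), M, M); A <- 1 * ((A + t(A)) > 0)
  diag(A) <- 0
  m <- c(1, 0, 1, 0, 0)
  o0 <- matrix(runif(M, 0.1, 0.9), M, 1)
  fd_check(function(tp, o) medrec:::ad_ddi_loss(tp, o, A), o0)
  fd_check(function(tp, o) medrec:::ad_margin_loss(tp, o, m), o0)
  fd_check(function(tp, o) medrec:::ad_bce_loss(tp, o, m), o0)
})

test_that("the Renyi entropy op differentiates correctly at fixed bandwidth", {
  set.seed(64)
  Q0 <- rand_mat(5, 3)
  for (alpha in c(1.01, 2)) {
    fd_check(function(tp, Q) medrec:::ad_renyi(tp, Q, alpha, sigma = 1.2), Q0,
             tol = 1e-4)
  }
})

test_that("tape and plain forward passes agree on whole patients", {
  for (seed in c(5L, 6L)) {
    fx <- small_model_fixture(seed = seed)
    for (rec in fx$cohort$records[1:4]) {
      pl <- medrec:::patient_loss_tape(fx$params, rec, fx$NE, fx$ND, fx$A_D,
                                       fx$memory, fx$cfg)
      enc <- medrec:::encode_patient(fx$params, rec, fx$E_m_star, fx$memory,
                                     fx$cfg)
      Tn <- length(rec$visits)
      M <- nrow(fx$E_m_star)
      lddi <- mean(vapply(1:Tn, function(t) ddi_loss(enc$scores[t, ], fx$A_D),
                          0))
      lmp <- mean(vapply(1:Tn, function(t) {
        m <- encode_multihot(rec$visits[[t]]$m, M)
        mp_loss(margin_loss(enc$scores[t, ], m), bce_loss(enc$scores[t, ], m),
                fx$cfg$mu)
      }, 0))
      lic <- renyi_entropy(enc$q, fx$cfg$renyi_alpha)
      expect_equal(unname(pl$breakdown[c("ddi", "mp", "ic")]),
                   c(lddi, lmp, lic), tolerance = 1e-9)
    }
  }
})

test_that("the full patient loss passes a sampled finite-difference check", {
  fx <- small_model_fixture(renyi_sigma = 1.3)  # fixed bandwidth: exact FD
  rec <- fx$cohort$records[[which.max(vapply(fx$cohort$records,
                                             function(r) length(r$visits),
                                             0L))]]
  pl <- medrec:::patient_loss_tape(fx$params, rec, fx$NE, fx$ND, fx$A_D,
                                   fx$memory, fx$cfg)
  g <- medrec:::ad_backward(pl$tp, pl$total)
  lossfun <- function(p) medrec:::patient_loss_tape(
    p, rec, fx$NE, fx$ND, fx$A_D, fx$memory, fx$cfg)$breakdown[["total"]]
  set.seed(65)
  eps <- 1e-5
  for (nm in names(fx$params)) {
    an_mat <- g[[pl$ids[[nm]]]]
    n_checks <- max(1L, ceiling(0.01 * length(fx$params[[nm]])))
    for (k in sample(length(fx$params[[nm]]), n_checks)) {
      p2 <- fx$params; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- fx$params; p3[[nm]][k] <- p3[[nm]][k] - eps
      fd <- (lossfun(p2) - lossfun(p3)) / (2 * eps)
      an <- if (is.null(an_mat)) 0 else an_mat[k]
      expect_equal(an, fd, tolerance = 1e-4,
                   label = sprintf("grad of %s[%d] (analytic)", nm, k))
    }
  }
})
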