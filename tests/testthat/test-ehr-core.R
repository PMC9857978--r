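test_that("multi-hot encoding matches its definition and inverts", {
  expect_equal(encode_multihot(c(0, 2), 3), c(1, 0, 1))
  expect_equal(encode_multihot(integer(), 4), c(0, 0, 0, 0))
  expect_equal(encode_multihot(1, 2), c(0, 1))
  expect_error(encode_multihot(5, 3), "out of range")
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    idx <- sort(sample(0:(n - 1), sample(0:n, 1)))
    expect_identical(which(encode_multihot(idx, n) == 1) - 1L, as.integer(idx))
  }
})

test_that("cohort JSON-lines round-trips and filters single-visit patients", {
  ch <- tiny_cohort()
  f <- withr::local_tempfile(fileext = ".jsonl")
  save_cohort(ch, f)
  ch2 <- load_cohort(f)
  expect_equal(ch2, ch)

  # append a single-visit patient: dropped with a message
  line <- jsonlite::toJSON(list(patient_id = "solo",
                                visits = list(list(d = list("D00"),
                                                   p = list(), m = list()))),
                           auto_unbox = TRUE)
  write(line, f, append = TRUE)
  expect_message(ch3 <- load_cohort(f), "dropped 1 patient")
  expect_length(ch3$records, 3L)
})

test_that("unknown codes error in strict mode and drop in lenient mode", {
  ch <- tiny_cohort()
  f <- withr::local_tempfile(fileext = ".jsonl")
  save_cohort(ch, f)
  line <- jsonlite::toJSON(list(patient_id = "X",
                                visits = list(list(d = list("NOPE"), p = list(),
                                                   m = list("M00")),
                                              list(d = list(), p = list(),
                                                   m = list()))),
                           auto_unbox = TRUE)
  write(line, f, append = TRUE)
  expect_error(load_cohort(f), "unknown diagnosis code 'NOPE'")
  expect_message(ch2 <- load_cohort(f, strict = FALSE), "1 unknown code")
  expect_length(ch2$records[[4]]$visits[[1]]$d, 0L)
})

test_that("co-prescription graph matches a brute-force pair enumeration", {
  v <- tiny_vocabs()
  one <- cohort(list(patient_record("A", list(visit(0, 0, c(0, 1)),
                                              visit(0, 0, c(1, 2))))),
                v$d, v$p, v$m)
  A <- build_ehr_graph(one)
  want <- matrix(0, 4, 4)
  want[1, 2] <- want[2, 1] <- 1  # drugs {a,b} in visit 1
  want[2, 3] <- want[3, 2] <- 1  # drugs {b,c} in visit 2
  expect_equal(unname(A), want)

  solo <- cohort(list(patient_record("A", list(visit(0, 0, 2), visit(0, 0, 2)))),
                 v$d, v$p, v$m)
  expect_true(all(build_ehr_graph(solo) == 0))

  # brute force double loop on random cohorts
  for (seed in 1:5) {
    ch <- small_cohort(8L, seed)
    A <- build_ehr_graph(ch)
    M <- length(ch$vocab_m)
    B <- matrix(0, M, M)
    for (rec in ch$records) for (vv in rec$visits) {
      ix <- vv$m + 1L
      if (length(ix) >= 2L) for (i in ix) for (j in ix) if (i != j) B[i, j] <- 1
    }
    expect_equal(unname(A), B)
    expect_equal(A, t(A))
    expect_true(all(diag(A) == 0))
  }
})

test_that("DDI graph symmetrizes pairs and skips unknown codes", {
  v <- tiny_vocabs()
  A <- build_ddi_graph(rbind(c("M00", "M01")), v$m)
  expect_equal(sum(A), 2)
  expect_equal(A["M00", "M01"], 1)
  expect_equal(A["M01", "M00"], 1)
  expect_true(all(build_ddi_graph(NULL, v$m) == 0))
  expect_message(B <- build_ddi_graph(rbind(c("M00", "ZZZ")), v$m), "skipped 1")
  expect_true(all(B == 0))
  expect_error(build_ddi_graph(NULL, code_vocabulary("drug", character())),
               "empty")
})

test_that("DDI pair list TSV round-trips", {
  v <- tiny_vocabs()
  pairs <- generate_ddi_pairs(v$m, 0.5, 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  save_ddi_pairs(pairs, f)
  expect_equal(unname(load_ddi_pairs(f)), unname(pairs))
})

test_that("cohort split is a deterministic patient-level partition", {
  ch <- small_cohort(12L)
  s1 <- split_cohort(ch, c(2 / 3, 1 / 6, 1 / 6), seed = 7L)
  s2 <- split_cohort(ch, c(2 / 3, 1 / 6, 1 / 6), seed = 7L)
  expect_equal(s1, s2)
  sizes <- vapply(s1, function(x) length(x$records), 0L)
  expect_equal(unname(sizes), c(8L, 2L, 2L))  # floor rule, remainder to train
  ids <- function(x) sort(vapply(x$records, `[[`, "", "patient_id"))
  all_ids <- sort(c(ids(s1$train), ids(s1$validation), ids(s1$test)))
  expect_equal(all_ids, ids(ch))
  expect_length(intersect(ids(s1$train), ids(s1$test)), 0L)
  expect_error(split_cohort(ch, c(1, 0, 0), seed = 1L), "empty")
  expect_error(split_cohort(ch, c(0.5, 0.2, 0.2), seed = 1L), "sum to 1")
})
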