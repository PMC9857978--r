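# Domain types and I/O for longitudinal EHR cohorts.
#
# A cohort is a list of patient records, each an ordered sequence of visits;
# every visit is a triple of 0-based index sets into the diagnosis, procedure
# and drug vocabularies. All indices are 0-based at the file boundary and in
# the Visit sets; matrices produced from them are 1-based as usual in R.

#' Build a code vocabulary
#'
#' @param kind one of `"diagnosis"`, `"procedure"`, `"drug"`.
#' @param codes character vector of unique code strings; order is preserved
#'   and defines the 0-based index of each code.
#' @return a `code_vocabulary` object with `$codes` and `$index`
#'   (a named integer vector mapping code -> 0-based position).
#' @export
code_vocabulary <- function(kind = c("diagnosis", "procedure", "drug"), codes) {
  kind <- match.arg(kind)
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("vocabulary codes must be unique")
  idx <- seq_along(codes) - 1L
  names(idx) <- codes
  structure(list(kind = kind, codes = codes, index = idx),
            class = "code_vocabulary")
}

#' @export
length.code_vocabulary <- function(x) length(x$codes)

#' @export
print.code_vocabulary <- function(x, ...) {
  cat(sprintf("<code_vocabulary: %s, %d codes>\n", x$kind, length(x$codes)))
  invisible(x)
}

#' Construct a single visit
#'
#' @param diagnoses,procedures,drugs integer vectors of 0-based vocabulary
#'   indices (may be empty).
#' @return a `visit` object.
#' @export
visit <- function(diagnoses = integer(), procedures = integer(),
                  drugs = integer()) {
  as_set <- function(x) sort(unique(as.integer(x)))
  structure(list(d = as_set(diagnoses), p = as_set(procedures),
                 m = as_set(drugs)), class = "visit")
}

#' Construct a patient record
#'
#' @param patient_id character id.
#' @param visits list of [visit()] objects in chronological order.
#' @return a `patient_record`.
#' @export
patient_record <- function(patient_id, visits) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  structure(list(patient_id = patient_id, visits = visits),
            class = "patient_record")
}

#' Construct a cohort
#'
#' Validates that every visit references only in-range vocabulary indices.
#'
#' @param records list of [patient_record()] objects.
#' @param vocab_d,vocab_p,vocab_m the three [code_vocabulary()] objects.
#' @return a `cohort`.
#' @export
cohort <- function(records, vocab_d, vocab_p, vocab_m) {
  if (length(records) == 0L) stop("cohort must contain at least one patient")
  sizes <- c(d = length(vocab_d), p = length(vocab_p), m = length(vocab_m))
  for (rec in records) {
    for (v in rec$visits) {
      for (fld in c("d", "p", "m")) {
        ix <- v[[fld]]
        if (length(ix) && (min(ix) < 0L || max(ix) >= sizes[[fld]]))
          stop(sprintf("patient %s: %s index out of range", rec$patient_id, fld))
      }
    }
  }
  structure(list(records = records, vocab_d = vocab_d, vocab_p = vocab_p,
                 vocab_m = vocab_m), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  nv <- sum(vapply(x$records, function(r) length(r$visits), 0L))
  cat(sprintf("<cohort: %d patients, %d visits, |D|=%d |P|=%d |M|=%d>\n",
              length(x$records), nv, length(x$vocab_d), length(x$vocab_p),
              length(x$vocab_m)))
  invisible(x)
}

#' Multi-hot encoding of an index set
#'
#' @param code_indices integer vector of 0-based indices.
#' @param vocab_size length of the output vector.
#' @return binary numeric vector with 1 exactly at the given indices.
#' @examples
#' encode_multihot(c(0, 2), 3)  # 1 0 1
#' @export
encode_multihot <- function(code_indices, vocab_size) {
  code_indices <- as.integer(code_indices)
  if (length(code_indices)) {
    bad <- which(code_indices < 0L | code_indices >= vocab_size)
    if (length(bad))
      stop(sprintf("code index out of range at position %d (index %d, size %d)",
                   bad[1L], code_indices[bad[1L]], vocab_size))
  }
  v <- numeric(vocab_size)
  v[code_indices + 1L] <- 1
  v
}

# ---- JSON-lines cohort I/O ---------------------------------------------
# First line: header {"diagnosis_vocab": [...], "procedure_vocab": [...],
# "drug_vocab": [...]}. Then one patient per line:
# {"patient_id": str, "visits": [{"d": [codes], "p": [...], "m": [...]}]}.

#' Write a cohort to a JSON-lines file
#'
#' @param x a [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- jsonlite::toJSON(list(diagnosis_vocab = x$vocab_d$codes,
                               procedure_vocab = x$vocab_p$codes,
                               drug_vocab = x$vocab_m$codes))
  writeLines(hdr, con)
  for (rec in x$records) {
    visits <- lapply(rec$visits, function(v) list(
      d = x$vocab_d$codes[v$d + 1L],
      p = x$vocab_p$codes[v$p + 1L],
      m = x$vocab_m$codes[v$m + 1L]))
    line <- jsonlite::toJSON(list(patient_id = rec$patient_id, visits = visits),
                             auto_unbox = TRUE)
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a cohort from a JSON-lines file
#'
#' Patients with fewer than two visits are dropped (multi-visit filtering);
#' the number dropped is reported with a message.
#'
#' @param path input file path.
#' @param strict if `TRUE` (default) an unknown code is an error; otherwise
#'   unknown codes are dropped with a message.
#' @return a [cohort()].
#' @export
load_cohort <- function(path, strict = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("cohort file must contain a header and patients")
  hdr <- tryCatch(jsonlite::fromJSON(lines[1L]),
                  error = function(e) stop("malformed header at line 1: ",
                                           conditionMessage(e)))
  need <- c("diagnosis_vocab", "procedure_vocab", "drug_vocab")
  if (!all(need %in% names(hdr))) stop("header missing vocabulary fields")
  vd <- code_vocabulary("diagnosis", unlist(hdr$diagnosis_vocab))
  vp <- code_vocabulary("procedure", unlist(hdr$procedure_vocab))
  vm <- code_vocabulary("drug", unlist(hdr$drug_vocab))
  lookup <- function(codes, voc, ln, what) {
    codes <- as.character(unlist(codes))
    if (length(codes) == 0L) return(integer())
    ix <- voc$index[codes]
    if (anyNA(ix)) {
      if (strict)
        stop(sprintf("unknown %s code '%s' at line %d", what,
                     codes[which(is.na(ix))[1L]], ln))
      ix <- ix[!is.na(ix)]
    }
    unname(ix)
  }
  records <- vector("list", length(lines) - 1L)
  dropped_codes <- 0L
  for (k in seq_along(records)) {
    ln <- k + 1L
    obj <- tryCatch(jsonlite::fromJSON(lines[ln], simplifyVector = FALSE),
                    error = function(e) stop(sprintf(
                      "malformed patient record at line %d: %s", ln,
                      conditionMessage(e))))
    if (is.null(obj$patient_id)) stop(sprintf("missing patient_id at line %d", ln))
    vs <- lapply(obj$visits, function(v) {
      n0 <- length(unlist(v$d)) + length(unlist(v$p)) + length(unlist(v$m))
      d <- lookup(v$d, vd, ln, "diagnosis")
      p <- lookup(v$p, vp, ln, "procedure")
      m <- lookup(v$m, vm, ln, "drug")
      dropped_codes <<- dropped_codes + (n0 - length(d) - length(p) - length(m))
      visit(d, p, m)
    })
    records[[k]] <- patient_record(as.character(obj$patient_id), vs)
  }
  keep <- vapply(records, function(r) length(r$visits) >= 2L, TRUE)
  if (any(!keep))
    message(sprintf("dropped %d patient(s) with fewer than 2 visits", sum(!keep)))
  if (dropped_codes > 0L)
    message(sprintf("dropped %d unknown code occurrence(s)", dropped_codes))
  records <- records[keep]
  if (length(records) == 0L) stop("empty cohort after multi-visit filtering")
  cohort(records, vd, vp, vm)
}

# ---- interaction graphs ------------------------------------------------

#' Build the co-prescription (EHR) graph
#'
#' `A_E[i, j] = 1` iff drugs i and j appear together in at least one visit of
#' the cohort. Symmetric with a zero diagonal.
#'
#' @param x a [cohort()]; conventionally the training split, so that no
#'   test-set prescription information leaks into the drug encoder.
#' @return binary `|M| x |M|` matrix.
#' @export
build_ehr_graph <- function(x) {
  stopifnot(inherits(x, "cohort"))
  M <- length(x$vocab_m)
  A <- matrix(0, M, M)
  for (rec in x$records) {
    for (v in rec$visits) {
      ix <- v$m + 1L
      if (length(ix) >= 2L) A[ix, ix] <- 1
    }
  }
  diag(A) <- 0
  dimnames(A) <- list(x$vocab_m$codes, x$vocab_m$codes)
  A
}

#' Build the drug-drug-interaction graph from a pair list
#'
#' @param pairs 2-column character matrix or data.frame of drug-code pairs.
#'   Pairs naming a code absent from `vocab_m` are skipped with a message.
#' @param vocab_m the drug [code_vocabulary()].
#' @return symmetric binary `|M| x |M|` matrix with zero diagonal.
#' @export
build_ddi_graph <- function(pairs, vocab_m) {
  if (length(vocab_m) == 0L) stop("empty drug vocabulary")
  M <- length(vocab_m)
  A <- matrix(0, M, M, dimnames = list(vocab_m$codes, vocab_m$codes))
  if (is.data.frame(pairs)) pairs <- as.matrix(pairs)
  skipped <- 0L
  if (!is.null(pairs) && NROW(pairs) > 0L) {
    for (k in seq_len(NROW(pairs))) {
      i <- vocab_m$index[as.character(pairs[k, 1L])]
      j <- vocab_m$index[as.character(pairs[k, 2L])]
      if (is.na(i) || is.na(j)) { skipped <- skipped + 1L; next }
      if (i == j) next
      A[i + 1L, j + 1L] <- 1
      A[j + 1L, i + 1L] <- 1
    }
  }
  if (skipped > 0L)
    message(sprintf("skipped %d DDI pair(s) with unknown codes", skipped))
  A
}

#' Read a DDI pair list from TSV
#'
#' Expects a header line `drug_a<TAB>drug_b`.
#' @param path TSV file path.
#' @return two-column character matrix.
#' @export
load_ddi_pairs <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("drug_a", "drug_b") %in% names(df)))
    stop("DDI file must have columns drug_a and drug_b")
  as.matrix(df[, c("drug_a", "drug_b")])
}

#' Write a DDI pair list to TSV
#' @param pairs two-column character matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_ddi_pairs <- function(pairs, path) {
  df <- data.frame(drug_a = pairs[, 1L], drug_b = pairs[, 2L])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Patient-level train/validation/test split
#'
#' Split sizes are floors of `ratios * N`; remainders go to the training
#' split. Deterministic for a given seed.
#'
#' @param x a [cohort()].
#' @param ratios numeric triple summing to 1.
#' @param seed integer RNG seed.
#' @return list with `train`, `validation`, `test` cohorts sharing the
#'   vocabularies of `x`.
#' @export
split_cohort <- function(x, ratios = c(2 / 3, 1 / 6, 1 / 6), seed = 1L) {
  stopifnot(inherits(x, "cohort"), length(ratios) == 3L)
  if (abs(sum(ratios) - 1) > 1e-9) stop("split ratios must sum to 1")
  N <- length(x$records)
  n_val <- floor(ratios[2L] * N)
  n_test <- floor(ratios[3L] * N)
  n_train <- N - n_val - n_test
  if (n_train < 1L || n_val < 1L || n_test < 1L)
    stop("split produces an empty partition")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  perm <- sample.int(N)
  mk <- function(ix) cohort(x$records[ix], x$vocab_d, x$vocab_p, x$vocab_m)
  list(train = mk(perm[seq_len(n_train)]),
       validation = mk(perm[n_train + seq_len(n_val)]),
       test = mk(perm[n_train + n_val + seq_len(n_test)]))
}

# save/restore the global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
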