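#' Classify a cohort for one ordered diagnosis pair
#'
#' Assigns every cohort patient to exactly one of six categories by comparing
#' the first-occurrence dates of codes `i` and `j`:
#' \describe{
#'   \item{n_i_then_j}{first `i` strictly precedes first `j`}
#'   \item{n_i_never_j}{has `i`, never `j`}
#'   \item{n_j_then_i}{first `j` strictly precedes first `i`}
#'   \item{n_j_never_i}{has `j`, never `i`}
#'   \item{n_neither}{has neither}
#'   \item{n_coincident}{first `i` and first `j` on the same day; these
#'     patients are excluded from the relative-risk calculation entirely}
#' }
#'
#' @param first_i,first_j named vectors (names = patient ids) of first
#'   occurrence dates for codes `i` and `j`; patients absent from a vector
#'   never had that code.
#' @param patients character vector of all cohort patient ids.
#' @return list of class `"pair_counts"` with the six counts.
#' @export
classify_pair <- function(first_i, first_j, patients) {
  if (!all(names(first_i) %in% patients) || !all(names(first_j) %in% patients))
    stop("date maps contain patients outside the cohort list")
  di <- as.numeric(first_i)[match(patients, names(first_i))]
  dj <- as.numeric(first_j)[match(patients, names(first_j))]
  .pair_counts(di, dj)
}

.pair_counts <- function(di, dj) {
  hi <- !is.na(di); hj <- !is.na(dj)
  both <- hi & hj
  structure(list(
    n_i_then_j  = sum(both & di < dj),
    n_i_never_j = sum(hi & !hj),
    n_j_then_i  = sum(both & dj < di),
    n_j_never_i = sum(!hi & hj),
    n_neither   = sum(!hi & !hj),
    n_coincident = sum(both & di == dj)
  ), class = "pair_counts")
}

#' Chronological relative risk from pair counts
#'
#' The risk of developing diagnosis `j` after a prior diagnosis `i`, relative
#' to the risk of `j` without a prior `i`:
#' \deqn{RR(i,j) = \frac{N(i\to j) / (N(i\to j) + N(i\to\sim j))}
#'   {(N(\sim i\to j) + N(j\to i)) / (N(\sim i\to j) + N(j\to i) + N(\sim i \& \sim j))}}
#' Patients whose first occurrences of `i` and `j` fall on the same day enter
#' neither fraction. Returns `NA` when no patient ever has `i` (undefined),
#' `Inf` when the comparator risk is zero but the exposed risk is positive,
#' and `NA` when both are zero.
#'
#' @param counts a `"pair_counts"` object or a list with the six count
#'   fields.
#' @return a single numeric relative risk (possibly `Inf` or `NA`).
#' @export
relative_risk <- function(counts) {
  num_den <- counts$n_i_then_j + counts$n_i_never_j
  if (num_den == 0) return(NA_real_)
  f1 <- counts$n_i_then_j / num_den
  cmp_num <- counts$n_j_never_i + counts$n_j_then_i
  cmp_den <- cmp_num + counts$n_neither
  if (cmp_num == 0) return(if (f1 > 0) Inf else NA_real_)
  f1 / (cmp_num / cmp_den)
}

#' Relative-risk adjacency matrix over retained codes
#'
#' Computes [relative_risk()] for every ordered pair of retained codes,
#' classifying each unordered pair once and exploiting the swap symmetry of
#' the six counts. Entry `(i, j)` is the chronological relative risk of `j`
#' given prior `i`; the diagonal is `NA`.
#'
#' @param first_occ first-occurrence table (`patient_id`, `code3`,
#'   `first_date`), as from [first_occurrences()].
#' @param codes character vector of retained codes (no duplicates).
#' @param patients character vector of cohort patient ids. Patients with no
#'   retained-code occurrences still count in `n_neither`.
#' @return object of class `"rr_matrix"`: list with `codes`, `rr`
#'   (named square matrix), `counts` (`n x n x 6` array; slice `[i, j, ]`
#'   holds the ordered-pair counts), and `n_patients`.
#' @export
rr_matrix <- function(first_occ, codes, patients) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("duplicate codes in retained-code list")
  patients <- as.character(patients)
  extra <- setdiff(unique(first_occ$patient_id), patients)
  if (length(extra))
    stop("first-occurrence table contains patients outside the cohort list")
  n <- length(codes)
  np <- length(patients)

  D <- matrix(NA_real_, np, n, dimnames = list(patients, codes))
  fo <- first_occ[first_occ$code3 %in% codes, , drop = FALSE]
  if (anyDuplicated(fo[, c("patient_id", "code3")])) {
    dt <- as.data.table(fo)
    fo <- as.data.frame(dt[, .(first_date = min(first_date)),
                           by = .(patient_id, code3)])
  }
  if (nrow(fo))
    D[cbind(match(fo$patient_id, patients), match(fo$code3, codes))] <-
      as.numeric(fo$first_date)

  cat_names <- c("n_i_then_j", "n_i_never_j", "n_j_then_i", "n_j_never_i",
                 "n_neither", "n_coincident")
  counts <- array(0L, dim = c(n, n, 6), dimnames = list(codes, codes, cat_names))
  rr <- matrix(NA_real_, n, n, dimnames = list(codes, codes))

  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      di <- D[, i]
      hi <- !is.na(di)
      for (j in (i + 1):n) {
        dj <- D[, j]
        hj <- !is.na(dj)
        both <- hi & hj
        nij <- sum(both & di < dj)
        nji <- sum(both & dj < di)
        nco <- sum(both) - nij - nji
        ni_ <- sum(hi) - sum(both)
        n_j <- sum(hj) - sum(both)
        nn <- np - sum(hi) - n_j
        counts[i, j, ] <- c(nij, ni_, nji, n_j, nn, nco)
        counts[j, i, ] <- c(nji, n_j, nij, ni_, nn, nco)  # swap symmetry
        rr[i, j] <- relative_risk(list(
          n_i_then_j = nij, n_i_never_j = ni_, n_j_then_i = nji,
          n_j_never_i = n_j, n_neither = nn))
        rr[j, i] <- relative_risk(list(
          n_i_then_j = nji, n_i_never_j = n_j, n_j_then_i = nij,
          n_j_never_i = ni_, n_neither = nn))
      }
    }
  }
  structure(list(codes = codes, rr = rr, counts = counts, n_patients = np),
            class = "rr_matrix")
}

#' @export
print.rr_matrix <- function(x, ...) {
  def <- sum(!is.na(x$rr))
  cat(sprintf("Chronological RR matrix: %d codes, %d patients, %d/%d ordered pairs defined\n",
              length(x$codes), x$n_patients, def,
              length(x$codes) * (length(x$codes) - 1)))
  invisible(x)
}

#' Long-format pair table of a relative-risk matrix
#'
#' One row per ordered pair of distinct codes: the relative risk and the six
#' classification counts. Rows are ordered by `code_i`, then `code_j`.
#'
#' @param rrm an `"rr_matrix"` object.
#' @return data frame `(code_i, code_j, rr, n_i_then_j, n_i_never_j,
#'   n_j_then_i, n_j_never_i, n_neither, n_coincident)`.
#' @export
rr_pairs <- function(rrm) {
  stopifnot(inherits(rrm, "rr_matrix"))
  n <- length(rrm$codes)
  if (n < 2)
    return(data.frame(code_i = character(), code_j = character(), rr = numeric()))
  idx <- which(row(rrm$rr) != col(rrm$rr), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cnt <- matrix(rrm$counts[cbind(rep(idx[, 1], 6), rep(idx[, 2], 6),
                                 rep(1:6, each = nrow(idx)))],
                ncol = 6,
                dimnames = list(NULL, dimnames(rrm$counts)[[3]]))
  data.frame(code_i = rrm$codes[idx[, 1]], code_j = rrm$codes[idx[, 2]],
             rr = rrm$rr[idx], cnt, row.names = NULL)
}
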