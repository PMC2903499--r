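#' Enumerate phenotyped pairs at a given pedigree relationship
#'
#' All unordered pairs of phenotyped animals whose numerator relationship
#' equals `k` (within `tol`; inbreeding-perturbed near-miss values are
#' excluded by the exact match).
#'
#' @param A numerator relationship matrix with ids as dimnames.
#' @param k target relationship (e.g. 1/16, 1/8, 1/4, 1/2).
#' @param ids optional subset of ids (e.g. animals phenotyped for the
#'   focal trait); defaults to all ids in `A`.
#' @param tol matching tolerance.
#' @return Two-column matrix of ids (zero rows when no pair matches).
#' @export
enumerate_pairs <- function(A, k, ids = NULL, tol = 1e-9) {
  A <- unclass(A)
  if (!is.null(ids)) {
    ids <- intersect(as.character(ids), rownames(A))
    A <- A[ids, ids, drop = FALSE]
  }
  hit <- which(abs(A - k) <= tol & upper.tri(A), arr.ind = TRUE)
  cbind(rownames(A)[hit[, 1L]], rownames(A)[hit[, 2L]])
}

#' Sample mutually independent pairs
#'
#' Randomly permutes the candidate pairs and greedily accepts any pair
#' both of whose members are unrelated (relationship 0 within `tol`) to
#' every member of every previously accepted pair, giving a random
#' maximal set of pairs with relationship `k` inside and 0 across pairs.
#'
#' @param candidates two-column id matrix from [enumerate_pairs()].
#' @param A numerator relationship matrix.
#' @param tol zero-relationship tolerance.
#' @return Two-column id matrix of accepted pairs.
#' @export
sample_independent_pairs <- function(candidates, A, tol = 1e-9) {
  if (nrow(candidates) == 0L) stop("no candidate pairs")
  A <- unclass(A)
  ord <- sample.int(nrow(candidates))
  accepted_rows <- integer(0)
  members <- integer(0)  # column indices in A of accepted members
  i1 <- match(candidates[, 1L], rownames(A))
  i2 <- match(candidates[, 2L], rownames(A))
  for (r in ord) {
    if (length(members)) {
      if (max(abs(A[members, i1[r]])) > tol) next
      if (max(abs(A[members, i2[r]])) > tol) next
    }
    accepted_rows <- c(accepted_rows, r)
    members <- c(members, i1[r], i2[r])
  }
  candidates[accepted_rows, , drop = FALSE]
}

#' Intra-class correlation of paired observations
#'
#' One-way ANOVA over groups of size two:
#' `ICC = (MSB - MSW) / (MSB + MSW)` where MSB and MSW are the between-
#' and within-pair mean squares — the between-pair variance scaled by the
#' total variance.
#'
#' @param pairs two-column id matrix.
#' @param phenotype named numeric vector of trait values.
#' @return The intra-class correlation, or `NA` (with a warning) for
#'   fewer than two pairs.
#' @export
pair_icc <- function(pairs, phenotype) {
  if (nrow(pairs) < 2L) {
    warning("fewer than 2 pairs: intra-class correlation undefined")
    return(NA_real_)
  }
  y1 <- phenotype[pairs[, 1L]]
  y2 <- phenotype[pairs[, 2L]]
  m <- (y1 + y2) / 2
  gm <- mean(c(y1, y2))
  npair <- nrow(pairs)
  msb <- 2 * sum((m - gm)^2) / (npair - 1L)
  msw <- sum((y1 - m)^2 + (y2 - m)^2) / npair
  (msb - msw) / (msb + msw)
}

#' Intra-class correlation against relationship
#'
#' For each relationship class `k`, repeatedly samples a maximal set of
#' mutually independent pairs ([sample_independent_pairs()]) and averages
#' the pair intra-class correlation over `replicates` samplings; records
#' the total candidate count and the mean number of pairs accepted per
#' sampling.
#'
#' @param A numerator relationship matrix.
#' @param phenotype named numeric vector (names = animal ids); animals
#'   with missing values are excluded from the candidate scan.
#' @param ks relationship classes.
#' @param replicates number of sampling replicates per class.
#' @return Data frame `k`, `mean_icc`, `sd_icc`, `candidates`,
#'   `mean_sampled`; classes without candidates carry `NA` summaries.
#' @export
icc_curve <- function(A, phenotype, ks = c(1 / 16, 1 / 8, 1 / 4, 1 / 2),
                      replicates = 10000L) {
  ids <- names(phenotype)[!is.na(phenotype)]
  out <- lapply(ks, function(k) {
    cand <- enumerate_pairs(A, k, ids = ids)
    if (nrow(cand) == 0L)
      return(data.frame(k = k, mean_icc = NA_real_, sd_icc = NA_real_,
                        candidates = 0L, mean_sampled = NA_real_))
    icc <- numeric(replicates)
    nsamp <- numeric(replicates)
    for (rep_i in seq_len(replicates)) {
      smp <- sample_independent_pairs(cand, A)
      nsamp[rep_i] <- nrow(smp)
      icc[rep_i] <- if (nrow(smp) >= 2L) pair_icc(smp, phenotype) else NA_real_
    }
    data.frame(k = k, mean_icc = mean(icc, na.rm = TRUE),
               sd_icc = stats::sd(icc, na.rm = TRUE),
               candidates = nrow(cand), mean_sampled = mean(nsamp))
  })
  do.call(rbind, out)
}
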