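#' Pedigree numerator relationship matrix
#'
#' Henderson's tabular method: for animal i with parents s and d (in
#' generation order), `A[i,i] = 1 + 0.5*A[s,d]` and
#' `A[i,j] = 0.5*(A[j,s] + A[j,d])` for earlier j; unknown parents
#' contribute 0.  Founders are taken unrelated and non-inbred.  The result
#' is the expected additive genetic covariance (twice the kinship) and is
#' positive semi-definite by construction.
#'
#' @param ped a [as_pedigree()] object (sorted internally).
#' @return A symmetric matrix of class `relmat` with attribute
#'   `kind = "A"` and sample ids as dimnames.
#' @export
numerator_relationship <- function(ped) {
  ped <- as_pedigree(as.data.frame(ped))  # guarantees generation sort
  n <- nrow(ped)
  ip <- match(ped$sire, ped$id)
  im <- match(ped$dam, ped$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ip[i]; d <- im[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) 0 else A[j, s]
      ad_ <- if (is.na(d)) 0 else A[j, d]
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  dimnames(A) <- list(ped$id, ped$id)
  structure(A, class = c("relmat", "matrix"), kind = "A", psd_adjustment = 0)
}

#' SNP-based realized relationship matrix
#'
#' The default estimator is an allele-sharing similarity index.  At locus
#' l the similarity between individuals x and y is the mean of the four
#' cross-individual allele identity indicators,
#' `s = (g_x*g_y + (2-g_x)*(2-g_y))/4` for alternate-allele dosages g
#' (values 0, 1/2 or 1).  With sample allele frequency p the expected
#' similarity between unrelated individuals is `s0 = 1 - 2p(1-p)`, and
#' relatedness is estimated on the relationship (twice-kinship) scale by
#' the combined ratio estimator
#' `G_xy = 2 * sum_l (s_l - s0_l) / sum_l (1 - s0_l)`,
#' equivalent to weighting per-locus ratios `(s-s0)/(1-s0)` by
#' `w_l = 1 - s0_l`.  Sums run over loci non-missing in both individuals;
#' monomorphic loci carry zero weight.  The raw similarity matrix
#' contains rank-one components aligned with the overall mean (the
#' all-ones direction and its allele-frequency loading); these are not
#' identifiable as variance in any model containing an intercept and are
#' the sole source of negative eigenvalues of the allele-sharing form, so
#' they are removed by double centering (rows and columns then average
#' zero, as usual for genomic relationship matrices).  The diagonal
#' (x with itself) estimates `1 + F_x` where F is the excess homozygosity
#' relative to the sample allele frequencies.  The estimator is invariant
#' to SNP order and to swapping allele labels (g -> 2-g).  Any residual
#' negativity (possible under missingness) is bent away by a uniform
#' diagonal shift recorded in attribute `psd_adjustment`.
#'
#' `method = "vanraden"` gives the centered cross-product alternative
#' `Z Z' / (2 sum p(1-p))` with `Z = dosage - 2p` (missing dosages imputed
#' at 2p), for estimator-sensitivity checks.
#'
#' @param geno a [genotype_matrix()] object.
#' @param method `"similarity_index"` (default) or `"vanraden"`.
#' @return A matrix of class `relmat` with `kind = "G"`, attributes
#'   `method` and `psd_adjustment`.
#' @export
realized_relationship <- function(geno,
                                  method = c("similarity_index", "vanraden")) {
  method <- match.arg(method)
  g <- geno$dosage
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- apply(g, 2L, function(col) {
    v <- col[!is.na(col)]
    length(v) && stats::var(v) > 0
  })
  if (sum(poly) < 2L)
    stop("degenerate input: fewer than 2 polymorphic SNPs")
  G <- if (method == "similarity_index") .grm_similarity(g, p)
       else .grm_vanraden(g, p)
  dimnames(G) <- list(geno$ids, geno$ids)
  ev <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  adj <- 0
  if (ev < -1e-8) {
    adj <- -ev + 1e-8
    G <- G + diag(adj, nrow(G))
  }
  structure(G, class = c("relmat", "matrix"), kind = "G",
            method = method, psd_adjustment = adj)
}

.grm_similarity <- function(g, p) {
  s0 <- 1 - 2 * p * (1 - p)          # expected similarity, unrelated pair
  w <- 1 - s0                        # per-locus weight 2p(1-p)
  A1 <- g; A2 <- 2 - g
  miss <- is.na(g)
  A1[miss] <- 0; A2[miss] <- 0
  M <- (!miss) * 1
  ## sum_l s_l over loci non-missing in both (missing rows contribute 0)
  Ssum <- (tcrossprod(A1) + tcrossprod(A2)) / 4
  S0sum <- tcrossprod(M * rep(s0, each = nrow(M)) , M)  # sum_l m_x m_y s0_l
  Wsum <- tcrossprod(M * rep(w, each = nrow(M)), M)     # sum_l m_x m_y (1-s0_l)
  if (any(Wsum == 0)) {
    idx <- which(Wsum == 0, arr.ind = TRUE)[1L, ]
    stop("pair shares no informative non-missing loci: samples ",
         rownames(g)[idx[1L]] %||% idx[1L], " and ",
         rownames(g)[idx[2L]] %||% idx[2L])
  }
  G <- 2 * (Ssum - S0sum) / Wsum
  ## remove the mean-confounded rank-one components (double centering)
  rm_ <- rowMeans(G)
  G - outer(rm_, rep(1, length(rm_))) - outer(rep(1, length(rm_)), rm_) +
    mean(G)
}

.grm_vanraden <- function(g, p) {
  Z <- sweep(g, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  tcrossprod(Z) / (2 * sum(p * (1 - p)))
}

#' @export
print.relmat <- function(x, ...) {
  cat(attr(x, "kind"), "relationship matrix: ", nrow(x), "x", ncol(x))
  if (!is.null(attr(x, "method"))) cat(", method =", attr(x, "method"))
  if ((a <- attr(x, "psd_adjustment")) > 0)
    cat(sprintf(", PSD diagonal adjustment %.3g", a))
  cat("\n")
  invisible(x)
}

#' LD pruning by pairwise r-squared in sliding windows
#'
#' Within each `window`-SNP window advanced by `step` SNPs (windows never
#' span chromosomes), any pair of retained SNPs with squared dosage
#' correlation above `r2_threshold` causes the later (right) SNP to be
#' dropped; pairs are visited left to right so the earlier SNP always
#' survives.  Correlations are computed on mean-imputed dosages.  With
#' `step = 1` this matches a greedy scan over all pairs at most
#' `window - 1` SNPs apart.
#'
#' @param geno a [genotype_matrix()] object (columns already sorted by
#'   chromosome and position).
#' @param r2_threshold squared-correlation threshold (exclusive).
#' @param window window size in SNPs.
#' @param step window advance in SNPs.
#' @return Sorted integer vector of retained column indices.
#' @export
ld_prune <- function(geno, r2_threshold = 0.95, window = 50L, step = 1L) {
  stopifnot(r2_threshold > 0, window >= 2L, step >= 1L)
  g <- geno$dosage
  keep <- rep(TRUE, ncol(g))
  for (ch in unique(geno$map$chrom)) {
    cols <- which(geno$map$chrom == ch)
    if (length(cols) < 2L) next
    X <- .standardize_impute(g[, cols, drop = FALSE])
    starts <- seq(1L, max(1L, length(cols) - window + 1L), by = step)
    keep[cols] <- .greedy_lex(X, starts, window, r2_threshold,
                              attr(X, "constant"))
  }
  which(keep)
}

.pair_in_window <- function(i, j, starts, window) {
  ## exists s in starts with s <= i and j <= s + window - 1
  lo <- j - window + 1L  # need a start in [lo, i]
  vapply(seq_along(i), function(k) {
    any(starts >= lo[k] & starts <= i[k])
  }, logical(1))
}

## collect offending pairs (within some window, r2 above threshold), then
## apply the keep-the-left greedy rule in lexicographic (i, j) order
.greedy_lex <- function(X, starts, window, thr, const) {
  mc <- ncol(X)
  nrec <- nrow(X)
  pairs_i <- integer(0); pairs_j <- integer(0)
  maxlag <- min(window - 1L, mc - 1L)
  for (lag in seq_len(maxlag)) {
    i <- seq_len(mc - lag); j <- i + lag
    ok <- .pair_in_window(i, j, starts, window)
    if (!any(ok)) next
    r <- colSums(X[, i, drop = FALSE] * X[, j, drop = FALSE]) / (nrec - 1L)
    hit <- ok & (r * r) > thr & !const[i] & !const[j]
    pairs_i <- c(pairs_i, i[hit]); pairs_j <- c(pairs_j, j[hit])
  }
  keep <- rep(TRUE, mc)
  if (length(pairs_i)) {
    o <- order(pairs_i, pairs_j)
    for (k in o) {
      if (keep[pairs_i[k]] && keep[pairs_j[k]]) keep[pairs_j[k]] <- FALSE
    }
  }
  keep
}

.standardize_impute <- function(g) {
  mu <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- mu[j]
  sdv <- apply(g, 2L, stats::sd)
  const <- sdv == 0 | is.na(sdv)
  sdv[const] <- 1
  X <- sweep(sweep(g, 2L, mu), 2L, sdv, "/")
  attr(X, "constant") <- const
  X
}
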