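## Independent oracles used across tests.  These deliberately avoid the
## package's own code paths: gene dropping for kinship, per-locus loops
## for the similarity matrix, all-pairs scans for LD pruning, dense
## conditional-normal algebra for prediction.

## Monte-Carlo gene dropping: estimate twice-the-kinship by dropping
## founder alleles down the pedigree `reps` times.
gene_drop_A <- function(ped, reps = 200000L) {
  n <- nrow(ped)
  ip <- match(ped$sire, ped$id)
  im <- match(ped$dam, ped$id)
  a1 <- matrix(0L, reps, n)
  a2 <- matrix(0L, reps, n)
  for (i in seq_len(n)) {
    if (is.na(ip[i])) a1[, i] <- 2L * i - 1L
    else {
      pick <- stats::runif(reps) < 0.5
      a1[, i] <- ifelse(pick, a1[, ip[i]], a2[, ip[i]])
    }
    if (is.na(im[i])) a2[, i] <- 2L * i
    else {
      pick <- stats::runif(reps) < 0.5
      a2[, i] <- ifelse(pick, a1[, im[i]], a2[, im[i]])
    }
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    if (i == j) A[i, i] <- 1 + mean(a1[, i] == a2[, i])
    else {
      kin <- (mean(a1[, i] == a1[, j]) + mean(a1[, i] == a2[, j]) +
                mean(a2[, i] == a1[, j]) + mean(a2[, i] == a2[, j])) / 4
      A[i, j] <- A[j, i] <- 2 * kin
    }
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

## Per-locus loop construction of the similarity-index relationship
## matrix (same estimator definition, scalar arithmetic throughout).
similarity_G_loop <- function(g) {
  n <- nrow(g); m <- ncol(g)
  p <- colMeans(g, na.rm = TRUE) / 2
  s0 <- 1 - 2 * p * (1 - p)
  G <- matrix(0, n, n)
  for (x in seq_len(n)) for (y in x:n) {
    num <- den <- 0
    for (l in seq_len(m)) {
      gx <- g[x, l]; gy <- g[y, l]
      if (is.na(gx) || is.na(gy)) next
      s <- (gx * gy + (2 - gx) * (2 - gy)) / 4
      num <- num + (s - s0[l])
      den <- den + (1 - s0[l])
    }
    G[x, y] <- G[y, x] <- 2 * num / den
  }
  rm_ <- rowMeans(G)
  G - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(G)
}

## Brute-force LD pruning: all pairs within some sliding window, greedy
## keep-the-left in lexicographic order.
ld_prune_bruteforce <- function(geno, r2_threshold, window, step = 1L) {
  g <- geno$dosage
  keep <- rep(TRUE, ncol(g))
  for (ch in unique(geno$map$chrom)) {
    cols <- which(geno$map$chrom == ch)
    if (length(cols) < 2L) next
    gc <- g[, cols, drop = FALSE]
    mu <- colMeans(gc, na.rm = TRUE)
    for (j in seq_len(ncol(gc))) gc[is.na(gc[, j]), j] <- mu[j]
    mc <- length(cols)
    starts <- seq(1L, max(1L, mc - window + 1L), by = step)
    offending <- list()
    for (i in seq_len(mc - 1L)) for (j in (i + 1L):mc) {
      if (!any(starts <= i & j <= starts + window - 1L)) next
      if (stats::sd(gc[, i]) == 0 || stats::sd(gc[, j]) == 0) next
      if (stats::cor(gc[, i], gc[, j])^2 > r2_threshold)
        offending[[length(offending) + 1L]] <- c(i, j)
    }
    kl <- rep(TRUE, mc)
    for (pr in offending) if (kl[pr[1L]] && kl[pr[2L]]) kl[pr[2L]] <- FALSE
    keep[cols] <- kl
  }
  which(keep)
}

## Closed-form REML log-likelihood for a balanced one-way layout with an
## intercept, matching the package's constant convention.
oneway_reml_loglik <- function(y, group, s2b, s2e) {
  a <- length(unique(group))
  n <- length(y) / a
  gm <- tapply(y, group, mean)
  ssw <- sum((y - gm[group])^2)
  ssb <- n * sum((gm - mean(y))^2)
  lam <- s2e + n * s2b
  -0.5 * (a * (n - 1) * log(s2e) + a * log(lam) +
            log(a * n / lam) + ssw / s2e + ssb / lam)
}

## All maximal independent sets of a conflict graph by exhaustive search
## (vertices = candidate pairs, edges = shared/related animals).
maximal_independent_sets <- function(adj) {
  n <- nrow(adj)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    v <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(v) == 0L) next
    if (any(adj[v, v, drop = FALSE][upper.tri(diag(length(v)))] > 0)) next
    others <- setdiff(seq_len(n), v)
    if (any(vapply(others, function(o) all(adj[o, v] == 0), logical(1)))) next
    out[[length(out) + 1L]] <- v
  }
  out
}

## simple HS-like dataset for reuse in tests (small by default)
small_hs <- function(n_top = 12L, n_fs = 24L, mean_size = 8, sd_size = 4,
                     n_snps = 400L, arch = architecture_spec(
                       h2_poly = 0.3, f2 = 0.15, c2 = 0.05), ...) {
  ped <- simulate_pedigree(n_top, n_fs, mean_size, sd_size, 4L)
  cages <- assign_cages(ped)
  geno <- simulate_genotypes(ped, n_snps = n_snps)
  sim <- simulate_phenotypes(geno, ped, cages, arch, ...)
  list(ped = ped, cages = cages, geno = geno, phen = sim$phen,
       truth = sim$truth)
}
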