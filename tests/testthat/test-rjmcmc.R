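test_that("dominance eligibility follows the strict 10% heterozygosity rule", {
  expect_false(dominance_eligible(rep(1L, 100)))
  expect_false(dominance_eligible(c(rep(0L, 45), rep(2L, 45), rep(1L, 10))))
  expect_true(dominance_eligible(c(rep(0L, 40), rep(2L, 40), rep(1L, 20))))
  expect_false(dominance_eligible(c(rep(0L, 50), rep(1L, 50))))  # two classes
  expect_true(dominance_eligible(c(rep(0L, 40), rep(2L, 40), rep(1L, 20),
                                   rep(NA, 30))))
})

make_qtl_spec <- function(seed = 12, n_top = 8, n_fs = 16, n_snps = 120) {
  set.seed(seed)
  sim <- small_hs(n_top, n_fs, 7, 3, n_snps = n_snps)
  G <- realized_relationship(sim$geno)
  spec <- mm_spec(y ~ cage_density, sim$phen,
                  list(f = ~fullsib_family, c = ~cage, g = vc_relmat(G, "id")))
  list(spec = spec, sim = sim)
}

test_that("empty selection reproduces the REML log-likelihood at frozen variances", {
  x <- make_qtl_spec()
  th <- c(f = 0.1, c = 0.05, g = 0.3, e = 0.55)
  cand <- x$sim$geno$dosage[, 1:30]
  pl <- profile_loglik_qtl(x$spec, th, cand, integer(0))
  expect_equal(pl$ll, reml_loglik(x$spec, th), tolerance = 1e-10)
})

test_that("monomorphic or duplicated SNP states are invalid, not errors", {
  x <- make_qtl_spec()
  cand <- x$sim$geno$dosage[, 1:30]
  cand[, 5] <- 1L                 # constant column
  cand[, 7] <- cand[, 6]          # exact duplicate
  th <- c(f = 0.1, c = 0.05, g = 0.3, e = 0.55)
  expect_null(profile_loglik_qtl(x$spec, th, cand, 5L))
  expect_null(profile_loglik_qtl(x$spec, th, cand, c(6L, 7L)))
  expect_false(is.null(profile_loglik_qtl(x$spec, th, cand, 6L)))
})

test_that("GLS effects match an explicit weighted normal-equation oracle", {
  set.seed(13)
  n <- 50
  ids <- paste0("a", seq_len(n))
  dat <- data.frame(id = ids, y = rnorm(n), cage_density = sample(2:7, n, TRUE),
                    fullsib_family = rep(paste0("f", 1:10), each = 5),
                    cage = rep(paste0("c", 1:25), each = 2))
  spec <- mm_spec(y ~ cage_density, dat, list(f = ~fullsib_family, c = ~cage))
  snp <- matrix(sample(0:2, n, TRUE), n, 1)
  th <- c(f = 0.2, c = 0.1, e = 0.7)
  pl <- profile_loglik_qtl(spec, th, snp, 1L)
  Zf <- outer(dat$fullsib_family, unique(dat$fullsib_family), "==") * 1
  Zc <- outer(dat$cage, unique(dat$cage), "==") * 1
  V <- 0.2 * tcrossprod(Zf) + 0.1 * tcrossprod(Zc) + 0.7 * diag(n)
  Xa <- cbind(1, dat$cage_density, snp)
  Vi <- solve(V)
  bhat <- solve(crossprod(Xa, Vi %*% Xa), crossprod(Xa, Vi %*% dat$y))
  expect_equal(pl$effects, drop(bhat), tolerance = 1e-10)
  ## and the profile log-likelihood from first principles
  Py <- Vi %*% dat$y - Vi %*% Xa %*% bhat
  ll <- -0.5 * (determinant(V)$modulus +
                  determinant(crossprod(Xa, Vi %*% Xa))$modulus +
                  sum(dat$y * Py))
  expect_equal(pl$ll, as.numeric(ll), tolerance = 1e-8)
})

test_that("the chain is bitwise reproducible under a fixed seed", {
  x <- make_qtl_spec()
  cand <- x$sim$geno$dosage[, 1:25]
  a <- run_rjmcmc(x$spec, cand, rounds = 1500, burnin = 200,
                  reml_every = 500, seed = 42)
  b <- run_rjmcmc(x$spec, cand, rounds = 1500, burnin = 200,
                  reml_every = 500, seed = 42)
  expect_identical(a$ll, b$ll)
  expect_identical(a$state, b$state)
  expect_identical(a$inclusion, b$inclusion)
})

test_that("stored variance-ratio estimates always close to one with the residual", {
  x <- make_qtl_spec(seed = 14)
  cand <- x$sim$geno$dosage[, 1:25]
  tr <- run_rjmcmc(x$spec, cand, rounds = 3000, burnin = 500,
                   reml_every = 1000, seed = 7,
                   mode = "additive_dominance")
  expect_equal(length(tr$stored), 3L)
  for (f in tr$stored)
    expect_equal(sum(f$varcomp$ratio), 1, tolerance = 1e-8)
})

test_that("posterior summaries reduce correctly and use the averaged-AIC rule", {
  x <- make_qtl_spec(seed = 15)
  cand <- x$sim$geno$dosage[, 1:20]
  tr <- run_rjmcmc(x$spec, cand, rounds = 800, burnin = 100,
                   reml_every = 10^6, seed = 3)
  s <- posterior_summaries(tr)
  post <- seq(101, 900)
  expect_equal(s$avg_loglik, mean(tr$ll[post]))
  expect_equal(s$avg_nq, round(mean(tr$nq[post]), 2))
  expect_equal(s$aic, 2 * (3 + s$avg_nq) - 2 * s$avg_loglik)
  ## a chain that never moves summarizes to its single state
  tr0 <- tr
  tr0$ll[] <- tr$ll[1]; tr0$nq[] <- 2L
  s0 <- posterior_summaries(tr0)
  expect_equal(s0$avg_loglik, tr$ll[1])
  expect_equal(s0$avg_nq, 2)
})

test_that("dominance mode pairs additive and dominance columns of eligible SNPs", {
  set.seed(16)
  n <- 80
  dat <- data.frame(id = paste0("a", 1:n), y = rnorm(n),
                    cage_density = sample(2:7, n, TRUE),
                    fullsib_family = rep(paste0("f", 1:16), each = 5),
                    cage = rep(paste0("c", 1:20), each = 4))
  spec <- mm_spec(y ~ cage_density, dat, list(f = ~fullsib_family))
  cand <- cbind(sample(0:2, n, TRUE),                  # eligible
                sample(0:2, n, TRUE),                  # eligible
                rep(c(0L, 2L), n / 2))                 # not eligible
  th <- c(f = 0.1, e = 0.9)
  ## an eligible selected SNP contributes two columns, the ineligible one
  pl2 <- profile_loglik_qtl(spec, th, cand, 1L, mode = "additive_dominance")
  expect_equal(length(pl2$effects), 2 + 2)
  pl3 <- profile_loglik_qtl(spec, th, cand, 3L, mode = "additive_dominance")
  expect_equal(length(pl3$effects), 2 + 1)
  ## and nq counts additive and dominance terms separately
  tr <- run_rjmcmc(spec, cand, mode = "additive_dominance", rounds = 300,
                   burnin = 50, reml_every = 10^6, seed = 1)
  sel_rounds <- which(tr$state == 1)   # only SNP 1 selected
  if (length(sel_rounds)) expect_true(all(tr$nq[sel_rounds] == 2L))
  sel3 <- which(tr$state == 4)         # only SNP 3 selected
  if (length(sel3)) expect_true(all(tr$nq[sel3] == 1L))
})
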