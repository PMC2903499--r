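test_that("restricted log-likelihood matches the balanced one-way closed form", {
  set.seed(1)
  a <- 8; n <- 6
  group <- rep(paste0("g", 1:a), each = n)
  y <- rnorm(a * n) + rep(rnorm(a, 0, 0.8), each = n)
  dat <- data.frame(y = y, grp = group)
  spec <- mm_spec(y ~ 1, dat, list(b = ~grp))
  for (s2 in list(c(b = 0.5, e = 1), c(b = 0.1, e = 0.3), c(b = 2, e = 0.5)))
    expect_equal(reml_loglik(spec, s2),
                 oneway_reml_loglik(y, group, s2["b"], s2["e"]),
                 tolerance = 1e-8, ignore_attr = TRUE)

  ## converged fit reproduces the analytic REML estimates
  fit <- reml_fit(spec, tol = 1e-10)
  msw <- sum((y - ave(y, group))^2) / (a * (n - 1))
  msb <- n * sum((tapply(y, group, mean) - mean(y))^2) / (a - 1)
  expect_equal(unname(fit$theta["e"]), msw, tolerance = 1e-6)
  expect_equal(unname(fit$theta["b"]), (msb - msw) / n, tolerance = 1e-5)
})

test_that("null-model limit and translation invariance hold", {
  set.seed(2)
  dat <- data.frame(y = rnorm(40), x = runif(40),
                    grp = rep(letters[1:8], 5))
  spec <- mm_spec(y ~ x, dat, list(b = ~grp))
  ## group variance at (near) zero: REML reduces to the residual-only
  ## value computed from least-squares residuals
  r <- resid(lm(y ~ x, dat))
  s2 <- sum(r^2) / (40 - 2)
  direct <- -0.5 * (40 * log(s2) +
                      log(det(crossprod(model.matrix(~x, dat)))) - 2 * log(s2) +
                      sum(r^2) / s2)
  expect_equal(reml_loglik(spec, c(b = 1e-12, e = s2)), direct,
               tolerance = 1e-6)
  ## adding a constant to y is absorbed by the intercept
  dat2 <- dat; dat2$y <- dat$y + 100
  spec2 <- mm_spec(y ~ x, dat2, list(b = ~grp))
  expect_equal(reml_loglik(spec2, c(b = 0.4, e = 0.8)),
               reml_loglik(spec, c(b = 0.4, e = 0.8)), tolerance = 1e-10)
})

test_that("degenerate inputs raise typed errors", {
  dat <- data.frame(y = rep(1, 30), grp = rep(letters[1:6], 5))
  expect_error(reml_fit(mm_spec(y ~ 1, dat, list(b = ~grp))),
               "zero variance")
  set.seed(3)
  dat2 <- data.frame(y = rnorm(30), x = 1:30, x2 = 2 * (1:30),
                     grp = rep(letters[1:6], 5))
  expect_error(reml_loglik(mm_spec(y ~ x + x2, dat2, list(b = ~grp)),
                           c(b = 1, e = 1)),
               "rank-deficient")
})

test_that("AI sampling correlations match closed forms", {
  AI <- diag(c(2, 3, 4))
  rownames(AI) <- colnames(AI) <- c("f", "c", "e")
  tab <- sampling_correlations(AI)
  expect_true(all(abs(tab$correlation) < 1e-12))
  a <- 2; b <- 0.7; c2 <- 1.5
  AI2 <- matrix(c(a, b, b, c2), 2, 2,
                dimnames = list(c("u", "e"), c("u", "e")))
  tab2 <- sampling_correlations(AI2)
  expect_equal(tab2$correlation, -b / sqrt(a * c2), tolerance = 1e-12)
  ## direct inversion cross-check
  expect_equal(tab2$correlation, cov2cor(solve(AI2))[1, 2], tolerance = 1e-12)
})

test_that("a variance pinned at zero is reported as 0 (0) and costs no likelihood", {
  ## family-only architecture on a dataset where the pedigree model
  ## resolves the family/polygenic ridge at u = 0 (on other draws the
  ## same ridge can swallow the family term instead — that confounding
  ## is the point of the genomic models)
  set.seed(24)
  sim <- small_hs(20, 40, 8, 3, n_snps = 300,
                  arch = architecture_spec(h2_poly = 0, f2 = 0.3, c2 = 0.05))
  A <- numerator_relationship(sim$ped)
  fit1 <- fit_model("1", sim$phen, A = A)
  urow <- fit1$varcomp[fit1$varcomp$component == "u", ]
  expect_equal(urow$ratio, 0)
  expect_equal(urow$se_ratio, 0)
  ## dropping the zero component leaves the likelihood unchanged
  fit1u <- fit_model("1-u", sim$phen)
  expect_lt(abs(fit1$loglik - fit1u$loglik), 1e-3)
})

test_that("logLik/AIC methods follow the variance-component convention", {
  set.seed(5)
  dat <- data.frame(y = rnorm(40), grp = rep(letters[1:8], 5),
                    cg = rep(LETTERS[1:10], 4))
  fit <- reml_fit(mm_spec(y ~ 1, dat, list(f = ~grp, c = ~cg)))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 2)
  expect_equal(AIC(fit), 2 * 2 - 2 * fit$loglik)
  expect_equal(AIC(fit), aic(fit$loglik, 2))
})

test_that("prediction equals the conditional-normal oracle for record-less animals", {
  set.seed(6)
  sim <- small_hs(8, 16, 6, 2, n_snps = 400)
  G <- realized_relationship(sim$geno)
  phen <- sim$phen[!is.na(sim$phen$y), ]
  est <- phen[seq_len(60), ]
  tgt <- phen[61:80, ]
  fit <- fit_model("2", est, G = G)
  pred <- predict(fit, tgt)
  ## dense oracle: y_hat = x'beta + s2f W' + s2c U' + s2g G[t, est] V^-1 r
  th <- fit$theta
  idx <- match(est$id, rownames(G))
  tix <- match(tgt$id, rownames(G))
  Zf <- outer(est$fullsib_family, sort(unique(est$fullsib_family)), "==") * 1
  Zc <- outer(est$cage, sort(unique(est$cage)), "==") * 1
  V <- th["f"] * tcrossprod(Zf) + th["c"] * tcrossprod(Zc) +
    th["g"] * unclass(G)[idx, idx] + th["e"] * diag(nrow(est))
  X <- cbind(1, est$cage_density)
  Vi <- solve(V)
  beta <- solve(crossprod(X, Vi %*% X), crossprod(X, Vi %*% est$y))
  r <- est$y - X %*% beta
  Vir <- Vi %*% r
  ghat <- th["g"] * unclass(G)[tix, idx] %*% Vir
  fhat <- drop(th["f"] * (outer(tgt$fullsib_family,
                                sort(unique(est$fullsib_family)), "==") * 1) %*%
                 crossprod(Zf, Vir))
  chat <- drop(th["c"] * (outer(tgt$cage, sort(unique(est$cage)), "==") * 1) %*%
                 crossprod(Zc, Vir))
  oracle <- unname(drop(cbind(1, tgt$cage_density) %*% beta) + drop(ghat) +
                     fhat + chat)
  expect_equal(pred, oracle, tolerance = 1e-6)
})

test_that("prediction falls back to the fixed part for fully unseen animals", {
  set.seed(7)
  sim <- small_hs(8, 16, 6, 2, n_snps = 300)
  G <- realized_relationship(sim$geno)
  phen <- sim$phen[!is.na(sim$phen$y), ]
  fit <- fit_model("2", phen[1:50, ], G = G)
  ## unseen family and cage; genetic part still looked up by id
  nd <- data.frame(id = phen$id[60], cage_density = 4,
                   fullsib_family = "nosuchfam", cage = "nosuchcage")
  p <- predict(fit, nd)
  expect_equal(p, unname(fit$beta[1] + 4 * fit$beta[2] +
                           fit$ranef$g[phen$id[60]]))
  nd2 <- nd; nd2$id <- "ghost"
  expect_error(predict(fit, nd2), "absent from relationship matrix")
})

test_that("duplicate relationship rows give identical genetic predictions", {
  set.seed(8)
  sim <- small_hs(6, 12, 6, 2, n_snps = 300)
  phen <- sim$phen[!is.na(sim$phen$y), ]
  g2 <- sim$geno$dosage
  ## make animal B a genetic duplicate of animal A
  a <- phen$id[1]; b <- phen$id[nrow(phen)]
  g2[b, ] <- g2[a, ]
  G <- realized_relationship(genotype_matrix(g2, sim$geno$map))
  fit <- fit_model("2", phen[phen$id != b, ], G = G)
  expect_equal(unname(fit$ranef$g[b]), unname(fit$ranef$g[a]),
               tolerance = 1e-8)
})

test_that("converged likelihood is no worse than the start and iterations are reported", {
  set.seed(9)
  sim <- small_hs(8, 16, 6, 2, n_snps = 200)
  A <- numerator_relationship(sim$ped)
  spec <- mm_spec(y ~ cage_density, sim$phen,
                  list(f = ~fullsib_family, c = ~cage, u = vc_relmat(A, "id")))
  start <- c(f = 0.05, c = 0.05, u = 0.05, e = 0.85)
  fit <- reml_fit(spec, start = start)
  expect_gte(fit$loglik, reml_loglik(spec, start) - 1e-8)
  expect_true(fit$converged)
  expect_gte(fit$iterations, 1L)
  ## ratios plus residual ratio sum to one
  expect_equal(sum(fit$varcomp$ratio), 1, tolerance = 1e-8)
})
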