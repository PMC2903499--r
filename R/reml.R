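#' Mixed-model specification
#'
#' Builds the design of a linear mixed model `y = X b + sum_j Z_j u_j + e`
#' with `u_j ~ N(0, K_j s2_j)` and `e ~ N(0, I s2_e)`.  The fixed part is
#' given as `formula` (response on the left; an intercept is included
#' unless removed); each random term is one of
#'
#' * a one-sided formula `~ column` naming a grouping factor in `data`
#'   (i.i.d. effects, `K = I`), e.g. family or cage;
#' * [vc_relmat()]: effects for every individual in a relationship matrix
#'   (pedigree `A` or SNP-based `G`), records mapped by an id column;
#' * [vc_design()]: an explicit numeric design matrix with i.i.d. effect
#'   columns (used for sets of SNP covariates with a common variance).
#'
#' Records with missing response or fixed covariates are dropped.
#'
#' @param formula fixed-effects formula, e.g. `y ~ cage_density`.
#' @param data data frame with one row per phenotypic record.
#' @param random named list of random terms.
#' @return An object of class `mm_spec`.
#' @export
mm_spec <- function(formula, data, random = list()) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  keep <- which(stats::complete.cases(cbind(y, X)))
  y <- as.numeric(y[keep])
  X <- X[keep, , drop = FALSE]
  if (length(random) && is.null(names(random)))
    names(random) <- paste0("r", seq_along(random))
  terms <- lapply(seq_along(random), function(k) {
    tm <- random[[k]]
    nm <- names(random)[k]
    if (inherits(tm, "formula")) {
      var <- all.vars(tm)[1L]
      if (!var %in% names(data)) stop("random term ", nm, ": no column ", var)
      fac <- factor(as.character(data[[var]][keep]))
      Z <- outer(fac, levels(fac), "==") * 1
      Z[is.na(Z)] <- 0   # records outside every group (e.g. founders)
      colnames(Z) <- levels(fac)
      list(name = nm, type = "factor", var = var, Z = Z,
           R = tcrossprod(Z), scale = 1)
    } else if (inherits(tm, "vc_relmat")) {
      ids <- as.character(data[[tm$id]][keep])
      idx <- match(ids, rownames(tm$K))
      if (anyNA(idx))
        stop("random term ", nm, ": ids absent from relationship matrix: ",
             paste(utils::head(unique(ids[is.na(idx)])), collapse = ", "))
      R <- unclass(tm$K)[idx, idx, drop = FALSE]
      list(name = nm, type = "relmat", var = tm$id, K = unclass(tm$K),
           idx = idx, R = R, scale = mean(diag(R)))
    } else if (inherits(tm, "vc_design")) {
      Z <- tm$Z[keep, , drop = FALSE]
      sc <- tm$scale %||% sum(apply(Z, 2L, stats::var))
      list(name = nm, type = "design", Z = Z, R = tcrossprod(Z),
           scale = sc)
    } else stop("unsupported random term: ", nm)
  })
  names(terms) <- names(random)
  structure(list(y = y, X = X, terms = terms, keep = keep,
                 formula = formula, data_cols = data[keep, , drop = FALSE]),
            class = "mm_spec")
}

#' @rdname mm_spec
#' @param K relationship matrix with individual ids as dimnames.
#' @param id name of the column in `data` holding the individual id of
#'   each record.
#' @export
vc_relmat <- function(K, id) {
  if (is.null(rownames(K))) stop("relationship matrix needs id dimnames")
  structure(list(K = K, id = id), class = "vc_relmat")
}

#' @rdname mm_spec
#' @param Z numeric design matrix, one row per row of `data`.
#' @param scale observation-scale variance contributed per unit effect
#'   variance; defaults to the sum of the column variances of `Z`.
#' @export
vc_design <- function(Z, scale = NULL) {
  structure(list(Z = as.matrix(Z), scale = scale), class = "vc_design")
}

## core evaluation of REML quantities at variance vector theta
## theta: length k+1, residual last; R_list: record-level kernels
.mm_eval <- function(spec, theta, derivs = FALSE) {
  y <- spec$y; X <- spec$X
  n <- length(y); p <- ncol(X)
  k <- length(spec$terms)
  V <- diag(theta[k + 1L], n)
  for (j in seq_len(k)) V <- V + theta[j] * spec$terms[[j]]$R
  Cv <- tryCatch(chol(V), error = function(e)
    stop("variance matrix not positive definite at theta = ",
         paste(signif(theta, 3), collapse = ", ")))
  logdetV <- 2 * sum(log(diag(Cv)))
  Vi <- chol2inv(Cv)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  Cx <- tryCatch(chol(XtViX), error = function(e)
    stop("rank-deficient fixed-effect design (collinear columns: ",
         paste(colnames(X), collapse = ", "), ")"))
  logdetX <- 2 * sum(log(diag(Cx)))
  XtViX_inv <- chol2inv(Cx)
  Viy <- Vi %*% y
  beta <- XtViX_inv %*% crossprod(X, Viy)
  Py <- Viy - ViX %*% (XtViX_inv %*% crossprod(ViX, y))
  yPy <- sum(y * Py)
  ll <- -0.5 * (logdetV + logdetX + yPy)
  out <- list(ll = ll, Py = Py, Vi = Vi, ViX = ViX, XtViX_inv = XtViX_inv,
              beta = drop(beta), logdetV = logdetV)
  if (!derivs) return(out)
  ## score and average-information for all k+1 components (residual last)
  W <- matrix(0, n, k + 1L)            # R_j %*% Py
  trPR <- numeric(k + 1L)
  for (j in seq_len(k + 1L)) {
    if (j <= k) {
      Rj <- spec$terms[[j]]$R
      W[, j] <- Rj %*% Py
      RViX <- Rj %*% ViX
      trPR[j] <- sum(Vi * Rj) - sum(XtViX_inv * crossprod(ViX, RViX))
    } else {
      W[, j] <- Py
      trPR[j] <- sum(diag(Vi)) - sum(XtViX_inv * crossprod(ViX, ViX))
    }
  }
  score <- -0.5 * (trPR - colSums(W * drop(Py)))
  PW <- Vi %*% W - ViX %*% (XtViX_inv %*% crossprod(ViX, W))
  AI <- 0.5 * crossprod(W, PW)
  out$score <- score
  out$AI <- (AI + t(AI)) / 2
  out
}

#' REML log-likelihood at fixed variance components
#'
#' Returns `-0.5 * (log|V| + log|X'V^-1 X| + y'Py)` with
#' `V = sum_j s2_j Z_j K_j Z_j' + I s2_e`.  The additive constant
#' `-0.5 * (n - p) * log(2*pi)` is excluded (stated here as the package
#' convention; differences of log-likelihoods are unaffected).
#'
#' @param spec an [mm_spec()] object.
#' @param sigma2 variances: named vector over the random-term names plus
#'   `"e"` for the residual, or unnamed in term order with the residual
#'   last.
#' @return The restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(spec, sigma2) {
  stopifnot(inherits(spec, "mm_spec"))
  theta <- .theta_from(spec, sigma2)
  if (any(theta < 0) || theta[length(theta)] <= 0)
    stop("variances must be >= 0 with residual > 0")
  .mm_eval(spec, theta)$ll
}

.theta_from <- function(spec, sigma2) {
  k <- length(spec$terms)
  if (!is.null(names(sigma2))) {
    nm <- c(names(spec$terms), "e")
    if (!all(nm %in% names(sigma2)))
      stop("sigma2 must name components: ", paste(nm, collapse = ", "))
    as.numeric(sigma2[nm])
  } else {
    stopifnot(length(sigma2) == k + 1L)
    as.numeric(sigma2)
  }
}

#' Fit a variance-component mixed model by average-information REML
#'
#' Maximizes the restricted likelihood over the variance components of an
#' [mm_spec()] model by average-information (AI) updates with
#' step-halving.  Components whose updates repeatedly go negative are
#' pinned to a small floor (`1e-8` of the phenotypic variance) and
#' reported as zero with zero standard error.  The inverse of the AI
#' matrix at convergence provides asymptotic standard errors and sampling
#' correlations of the estimates.  Variance ratios are
#' `scale_j * s2_j / total` where `scale_j` is the mean prior variance an
#' effect contributes per observation (1 for factor terms, the mean
#' relationship-matrix diagonal for correlated terms, the summed column
#' variance for design terms) and `total` is the sum over all components
#' plus the residual.
#'
#' @param spec an [mm_spec()] object, or a fixed-effects formula (then
#'   `data` and `random` are forwarded to [mm_spec()]).
#' @param data,random see [mm_spec()]; ignored when `spec` is already an
#'   `mm_spec`.
#' @param start optional starting variances (see [reml_loglik()] for the
#'   format); default splits the phenotypic variance equally.
#' @param max_iter maximum AI iterations.
#' @param tol convergence tolerance: maximum observation-scale variance
#'   change relative to the phenotypic variance.
#' @param verbose print per-iteration progress.
#' @return An object of class `reml_fit` with components `varcomp`
#'   (data frame of variances, ratios and standard errors), `loglik`,
#'   `ai` (average-information matrix of the free components), `beta`,
#'   `ranef`, `fitted`, `converged`, `iterations`.
#' @seealso [sampling_correlations()], [predict.reml_fit()],
#'   [fit_model()]
#' @export
reml_fit <- function(spec, data = NULL, random = list(), start = NULL,
                     max_iter = 100L, tol = 1e-6, verbose = FALSE) {
  if (inherits(spec, "formula")) spec <- mm_spec(spec, data, random)
  stopifnot(inherits(spec, "mm_spec"))
  y <- spec$y
  if (length(y) < ncol(spec$X) + length(spec$terms) + 1L)
    stop("fewer records than parameters")
  vary <- stats::var(y)
  if (!is.finite(vary) || vary <= 0)
    stop("degenerate input: response has zero variance")
  k <- length(spec$terms)
  scales <- c(vapply(spec$terms, `[[`, numeric(1), "scale"), 1)
  floor_ <- 1e-8 * vary
  theta <- if (is.null(start)) (vary / (k + 1L)) / scales
           else pmax(.theta_from(spec, start), floor_)
  pin_count <- integer(k + 1L)
  pinned <- rep(FALSE, k + 1L)
  ev <- .mm_eval(spec, theta, derivs = TRUE)
  ll0 <- ev$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    free <- which(!pinned)
    ai_step <- function(idx) {
      AIf <- ev$AI[idx, idx, drop = FALSE]
      tryCatch(solve(AIf, ev$score[idx]),
               error = function(e) ev$score[idx] / pmax(diag(AIf), 1e-12))
    }
    delta <- rep(0, k + 1L)
    delta[free] <- ai_step(free)
    ## active-set handling: components the full step drives negative are
    ## clamped to the floor, and the step for the remaining components is
    ## re-solved with the clamped ones held fixed
    clamped <- (theta + delta < floor_) & !pinned
    clamped[k + 1L] <- FALSE
    if (any(clamped)) {
      active <- setdiff(free, which(clamped))
      delta <- rep(0, k + 1L)
      if (length(active)) delta[active] <- ai_step(active)
      delta[clamped] <- floor_ - theta[clamped]
    }
    ## step-halving of the active part until the likelihood does not drop
    h <- 0L
    fixed_part <- clamped
    repeat {
      cand <- theta + delta
      below <- cand < floor_
      cand[below] <- floor_
      clamped <- fixed_part | below
      ev_new <- tryCatch(.mm_eval(spec, cand, derivs = TRUE),
                         error = function(e) NULL)
      if (!is.null(ev_new) && is.finite(ev_new$ll) &&
          ev_new$ll >= ev$ll - 1e-10) break
      h <- h + 1L
      if (h > 25L) break
      delta[!fixed_part] <- delta[!fixed_part] / 2
    }
    if (is.null(ev_new) || !is.finite(ev_new$ll)) {
      warning("AI update failed; stopping")
      break
    }
    pin_count <- ifelse(clamped & !pinned, pin_count + 1L, pin_count)
    pinned <- pinned | (pin_count >= 3L)
    pinned[k + 1L] <- FALSE  # residual always free
    change <- max(abs((cand - theta) * scales)) / vary
    if (verbose)
      message(sprintf("it %d  logL %.6f  change %.2e", iter, ev_new$ll, change))
    theta <- cand
    ev <- ev_new
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations")
  ## standard errors from inverse AI over free components
  free <- which(!pinned)
  covA <- tryCatch(solve(ev$AI[free, free, drop = FALSE]),
                   error = function(e) matrix(NA_real_, length(free),
                                              length(free)))
  se <- rep(0, k + 1L)
  se[free] <- sqrt(pmax(diag(covA), 0))
  est <- ifelse(pinned | theta <= floor_ * 1.0001, 0, theta)
  obs_var <- est * scales
  total <- sum(obs_var)
  ratios <- obs_var / total
  ## delta-method SEs for ratios r_j = s_j t_j / sum(s t)
  covT <- matrix(0, k + 1L, k + 1L)
  covT[free, free] <- covA
  se_ratio <- vapply(seq_len(k + 1L), function(j) {
    g <- -scales[j] * theta[j] * scales / total^2
    g[j] <- g[j] + scales[j] / total
    v <- drop(t(g) %*% covT %*% g)
    if (est[j] == 0) 0 else sqrt(max(v, 0))
  }, numeric(1))
  nm <- c(names(spec$terms), "e")
  varcomp <- data.frame(component = nm, sigma2 = est, scale = scales,
                        variance = obs_var, ratio = ratios,
                        se_sigma2 = ifelse(est == 0, 0, se),
                        se_ratio = se_ratio,
                        pinned = pinned | est == 0,
                        row.names = NULL, stringsAsFactors = FALSE)
  ## BLUP/BLUE solutions at converged variances
  Py <- ev$Py
  ranef <- lapply(seq_len(k), function(j) {
    tm <- spec$terms[[j]]
    u <- switch(tm$type,
      factor = drop(theta[j] * crossprod(tm$Z, Py)),
      relmat = drop(theta[j] * tm$K[, tm$idx, drop = FALSE] %*% Py),
      design = drop(theta[j] * crossprod(tm$Z, Py)))
    if (tm$type == "factor") names(u) <- colnames(tm$Z)
    if (tm$type == "relmat") names(u) <- rownames(tm$K)
    u
  })
  names(ranef) <- names(spec$terms)
  fitted_r <- drop(spec$X %*% ev$beta)
  for (j in seq_len(k)) {
    tm <- spec$terms[[j]]
    fitted_r <- fitted_r + switch(tm$type,
      factor = drop(tm$Z %*% ranef[[j]]),
      relmat = ranef[[j]][tm$idx],
      design = drop(tm$Z %*% ranef[[j]]))
  }
  se_beta <- sqrt(diag(ev$XtViX_inv))
  structure(list(varcomp = varcomp, loglik = ev$ll, ai = ev$AI,
                 ai_free = free, beta = stats::setNames(ev$beta,
                                                        colnames(spec$X)),
                 se_beta = stats::setNames(se_beta, colnames(spec$X)),
                 ranef = ranef, fitted = fitted_r,
                 residuals = y - fitted_r, y = y,
                 theta = stats::setNames(theta, nm),
                 converged = converged, iterations = iter,
                 spec = spec, call = match.call()),
            class = "reml_fit")
}

#' Akaike information criterion from a log-likelihood
#'
#' `2 * n_parameters - 2 * loglik`.  For REML fits the parameter count is
#' the number of fitted non-residual variance components; for
#' MCMC-averaged SNP-selection models it is the component count plus the
#' average number of fitted SNP effect terms (which may be fractional).
#'
#' @param loglik log-likelihood (REML or averaged profile).
#' @param n_parameters parameter count, possibly fractional.
#' @export
aic <- function(loglik, n_parameters) {
  stopifnot(n_parameters > 0)
  2 * n_parameters - 2 * loglik
}

#' Sampling correlations between estimated variance components
#'
#' Inverts the average-information matrix to the asymptotic sampling
#' covariance of the variance-component estimates and returns the
#' correlations for every pair of components (pinned/zero components are
#' reported as `NA`).
#'
#' @param fit a [reml_fit()] object (or a bare AI matrix).
#' @return A data frame with columns `comp1`, `comp2`, `correlation`,
#'   plus attribute `singular` if the AI matrix could not be inverted.
#' @export
sampling_correlations <- function(fit) {
  if (inherits(fit, "reml_fit")) {
    AI <- fit$ai[fit$ai_free, fit$ai_free, drop = FALSE]
    nm_all <- fit$varcomp$component
    nm <- nm_all[fit$ai_free]
  } else {
    AI <- as.matrix(fit)
    nm_all <- nm <- rownames(AI) %||% paste0("vc", seq_len(nrow(AI)))
  }
  covm <- tryCatch(solve(AI), error = function(e) NULL)
  singular <- is.null(covm)
  corm <- if (singular) matrix(NA_real_, length(nm), length(nm))
          else stats::cov2cor(covm)
  dimnames(corm) <- list(nm, nm)
  pairs <- utils::combn(nm_all, 2L)
  out <- data.frame(comp1 = pairs[1L, ], comp2 = pairs[2L, ],
                    correlation = apply(pairs, 2L, function(pr) {
                      if (all(pr %in% nm)) corm[pr[1L], pr[2L]] else NA_real_
                    }), stringsAsFactors = FALSE)
  attr(out, "singular") <- singular
  out
}

#' @export
print.reml_fit <- function(x, digits = 4, ...) {
  cat("AI-REML fit:", length(x$y), "records,",
      nrow(x$varcomp) - 1L, "random terms + residual\n")
  cat(sprintf("logL %.4f  (%sconverged, %d iterations)\n", x$loglik,
              if (x$converged) "" else "NOT ", x$iterations))
  vc <- x$varcomp
  tab <- data.frame(component = vc$component,
                    variance = signif(vc$variance, digits),
                    ratio = round(vc$ratio, 2),
                    se = round(vc$se_ratio, 2))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  structure(list(fit = object,
                 correlations = sampling_correlations(object),
                 aic = aic(object$loglik, nrow(object$varcomp) - 1L)),
            class = "summary.reml_fit")
}

#' @export
print.summary.reml_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("AIC (variance-component parameters): %.2f\n", x$aic))
  cat("Fixed effects:\n")
  print(data.frame(estimate = signif(x$fit$beta, 4),
                   se = signif(x$fit$se_beta, 3)))
  cat("Sampling correlations of variance components:\n")
  print(x$correlations, row.names = FALSE)
  invisible(x)
}

#' @export
coef.reml_fit <- function(object, ...) object$beta

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$loglik, df = nrow(object$varcomp) - 1L,
            nobs = length(object$y), class = "logLik")
}

#' @export
fitted.reml_fit <- function(object, ...) object$fitted

#' @export
residuals.reml_fit <- function(object, ...) object$residuals

#' @export
vcov.reml_fit <- function(object, ...) {
  free <- object$ai_free
  covm <- solve(object$ai[free, free, drop = FALSE])
  dimnames(covm) <- list(object$varcomp$component[free],
                         object$varcomp$component[free])
  covm
}

#' @export
plot.reml_fit <- function(x, ...) {
  vc <- x$varcomp
  bp <- graphics::barplot(vc$ratio, names.arg = vc$component,
                          ylab = "proportion of phenotypic variance",
                          ylim = c(0, min(1, max(vc$ratio + 2 * vc$se_ratio) * 1.1)),
                          ...)
  graphics::arrows(bp, pmax(0, vc$ratio - vc$se_ratio),
                   bp, vc$ratio + vc$se_ratio,
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' Predict phenotypes for new individuals
#'
#' `yhat_i = x_i' beta + f_hat(family) + c_hat(cage) + u_hat(individual)`:
#' fixed part from `newdata`, factor-term effects looked up by level (0
#' when the level carries no estimation records), correlated-term effects
#' taken from the all-individual BLUP vector (individuals absent from the
#' relationship matrix are an error).  Design-matrix terms require a
#' matching matrix in `design_Z`.
#'
#' @param object a [reml_fit()] object.
#' @param newdata data frame with the fixed-effect covariates and the
#'   grouping/id columns used by the random terms.
#' @param design_Z named list of design matrices for `vc_design` terms.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.reml_fit <- function(object, newdata, design_Z = list(), ...) {
  spec <- object$spec
  ff <- spec$formula
  rhs <- stats::delete.response(stats::terms(ff))
  mf <- stats::model.frame(rhs, newdata, na.action = stats::na.pass)
  X <- stats::model.matrix(rhs, mf)
  yhat <- drop(X %*% object$beta[colnames(X)])
  for (j in seq_along(spec$terms)) {
    tm <- spec$terms[[j]]
    u <- object$ranef[[j]]
    if (tm$type == "factor") {
      lev <- as.character(newdata[[tm$var]])
      add <- u[lev]
      add[is.na(add)] <- 0
      yhat <- yhat + add
    } else if (tm$type == "relmat") {
      ids <- as.character(newdata[[tm$var]])
      if (any(!ids %in% names(u)))
        stop("individuals absent from relationship matrix: ",
             paste(utils::head(setdiff(ids, names(u))), collapse = ", "))
      yhat <- yhat + u[ids]
    } else {
      Zn <- design_Z[[names(spec$terms)[j]]]
      if (is.null(Zn))
        stop("design term ", names(spec$terms)[j],
             " requires a matrix in design_Z")
      yhat <- yhat + drop(Zn %*% u)
    }
  }
  unname(yhat)
}

#' Fit the standard model ladder
#'
#' Convenience wrapper around [reml_fit()] for the four pedigree/genomic
#' models routinely compared on family-and-cage structured data:
#'
#' * `"1"`   family + cage + pedigree polygenic (`A`)
#' * `"1-u"` family + cage (no genetic term)
#' * `"1-f"` cage + pedigree polygenic
#' * `"2"`   family + cage + genomic (`G`)
#'
#' All models include the overall mean and cage density as fixed
#' covariates.
#'
#' @param model one of `"1"`, `"1-u"`, `"1-f"`, `"2"`.
#' @param phen phenotype data frame with columns `id`, `trait` value,
#'   `cage`, `cage_density`, `fullsib_family`.
#' @param A,G pedigree / SNP relationship matrices (as required).
#' @param trait name of the response column.
#' @param ... passed to [reml_fit()].
#' @export
fit_model <- function(model = c("1", "1-u", "1-f", "2"), phen,
                      A = NULL, G = NULL, trait = "y", ...) {
  model <- match.arg(model)
  f <- stats::as.formula(paste(trait, "~ cage_density"))
  random <- switch(model,
    "1" = list(f = ~fullsib_family, c = ~cage, u = vc_relmat(A, "id")),
    "1-u" = list(f = ~fullsib_family, c = ~cage),
    "1-f" = list(c = ~cage, u = vc_relmat(A, "id")),
    "2" = list(f = ~fullsib_family, c = ~cage, g = vc_relmat(G, "id")))
  if (model %in% c("1", "1-f") && is.null(A)) stop("model ", model, " needs A")
  if (model == "2" && is.null(G)) stop("model 2 needs G")
  reml_fit(mm_spec(f, phen, random), ...)
}
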