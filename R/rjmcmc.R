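#' Dominance-term eligibility of a SNP
#'
#' A SNP can carry a dominance (heterozygote-deviation) effect only when
#' all three genotype classes are observed and the observed heterozygote
#' fraction strictly exceeds 10%.
#'
#' @param snp_column dosage vector (0/1/2, `NA` missing).
#' @return Logical flag.
#' @export
dominance_eligible <- function(snp_column) {
  v <- snp_column[!is.na(snp_column)]
  if (length(v) == 0L) return(FALSE)
  all(c(0L, 1L, 2L) %in% v) && mean(v == 1L) > 0.10
}

## frozen-variance profile engine: V fixed, SNP columns enter as fixed
## effects; everything needed per proposal is a submatrix of one Gram
## matrix computed per variance refresh
.profile_engine <- function(spec, theta, Tmat) {
  n <- length(spec$y)
  k <- length(spec$terms)
  V <- diag(theta[k + 1L], n)
  for (j in seq_len(k)) V <- V + theta[j] * spec$terms[[j]]$R
  Cv <- chol(V)
  Vi <- chol2inv(Cv)
  ViT <- Vi %*% Tmat
  list(logdetV = 2 * sum(log(diag(Cv))),
       Vi = Vi,
       Gram = crossprod(Tmat, ViT),
       ty = drop(crossprod(ViT, spec$y)),
       yViy = sum(spec$y * (Vi %*% spec$y)))
}

## REML-style profile log-likelihood and GLS effects for a column set
.profile_ll <- function(eng, idx) {
  M <- eng$Gram[idx, idx, drop = FALSE]
  ch <- tryCatch(chol(M), error = function(e) NULL)
  ## collinear state: conditional sum of squares vanishes relative to scale
  if (is.null(ch) || any(diag(ch)^2 < 1e-10 * max(diag(M)))) return(NULL)
  z <- backsolve(ch, eng$ty[idx], transpose = TRUE)
  list(ll = -0.5 * (eng$logdetV + 2 * sum(log(diag(ch))) +
                      eng$yViy - sum(z * z)),
       bhat = backsolve(ch, z))
}

#' Profile log-likelihood of a set of SNP effects at frozen variances
#'
#' Augments the fixed-effect design with the additive (and, in
#' `additive_dominance` mode, dominance) coding columns of the selected
#' SNPs and evaluates the restricted profile log-likelihood
#' `-0.5 (log|V| + log|X'V^-1 X| + y'Py)` at fixed variance components;
#' SNP effects are the generalized-least-squares solutions.  Collinear
#' selections return `NULL` (treated as invalid proposals by the
#' sampler).
#'
#' @param spec base-model [mm_spec()].
#' @param sigma2 frozen variances (see [reml_loglik()] format).
#' @param candidates candidate dosage matrix, one row per row of the data
#'   used to build `spec`.
#' @param selected integer indices (columns of `candidates`) in the
#'   model; may be empty.
#' @param mode `"additive"` or `"additive_dominance"`.
#' @return List with `ll` and `effects` (GLS solutions for the augmented
#'   design, base fixed effects first), or `NULL` for a collinear
#'   selection.
#' @export
profile_loglik_qtl <- function(spec, sigma2, candidates, selected = integer(0),
                               mode = c("additive", "additive_dominance")) {
  mode <- match.arg(mode)
  theta <- .theta_from(spec, sigma2)
  cd <- .candidate_design(spec, candidates, mode)
  eng <- .profile_engine(spec, theta, cbind(spec$X, cd$Lam, cd$Del))
  idx <- .state_cols(selected, ncol(spec$X), cd)
  res <- .profile_ll(eng, idx)
  if (is.null(res)) return(NULL)
  list(ll = res$ll, effects = drop(res$bhat))
}

## mean-imputed additive and dominance candidate codings, aligned with
## the records kept in spec
.candidate_design <- function(spec, candidates, mode) {
  Lam <- as.matrix(candidates)[spec$keep, , drop = FALSE]
  for (j in seq_len(ncol(Lam))) {
    mj <- is.na(Lam[, j])
    if (any(mj)) Lam[mj, j] <- mean(Lam[, j], na.rm = TRUE)
  }
  eligible <- apply(as.matrix(candidates)[spec$keep, , drop = FALSE], 2L,
                    dominance_eligible)
  Del <- NULL
  dcol <- rep(NA_integer_, ncol(Lam))
  if (mode == "additive_dominance" && any(eligible)) {
    raw <- as.matrix(candidates)[spec$keep, eligible, drop = FALSE]
    Del <- (raw == 1L) * 1
    for (j in seq_len(ncol(Del))) {
      mj <- is.na(Del[, j])
      if (any(mj)) Del[mj, j] <- mean(Del[, j], na.rm = TRUE)
    }
    dcol[eligible] <- seq_len(sum(eligible))
  }
  list(Lam = Lam, Del = Del, eligible = eligible, dcol = dcol)
}

.state_cols <- function(sel, p0, cd) {
  idx <- seq_len(p0)
  if (length(sel)) {
    idx <- c(idx, p0 + sel)
    dc <- cd$dcol[sel]
    dc <- dc[!is.na(dc)]
    if (length(dc)) idx <- c(idx, p0 + ncol(cd$Lam) + dc)
  }
  idx
}

#' Reversible-jump MCMC over SNP effect sets
#'
#' Samples sets of candidate SNPs whose additive (and optionally
#' dominance) effects enter the mixed model as fixed-effect columns,
#' conditional on frozen REML variance components.  Each round proposes
#' with equal probability to add an unselected SNP, drop a selected SNP,
#' or swap one selected for one unselected (infeasible moves count as
#' null rounds, preserving detailed balance); acceptance is
#' `min(1, exp(d_profile_loglik) * prior_ratio * proposal_ratio)` with a
#' Poisson(`prior_mean`) prior on the number of selected SNPs.  The add
#' kernel is an equal mixture of a uniform draw and a draw weighted by
#' single-SNP profile evidence at the initial variances; the
#' proposal-ratio term corrects both add and drop moves exactly, so the
#' informed kernel changes mixing speed only, not the target
#' distribution.  In
#' `additive_dominance` mode an added SNP that is [dominance_eligible()]
#' contributes its additive and dominance columns jointly.  Every
#' `reml_every` rounds the variance components (base terms plus one
#' common variance for the selected additive effects and one for the
#' dominance effects) are re-estimated by REML, stored, and used to
#' refresh the frozen conditioning variances.
#'
#' @param spec base-model [mm_spec()] (fixed effects + family/cage/
#'   genomic random terms).
#' @param candidates candidate-SNP dosage matrix (rows = rows of the data
#'   frame behind `spec`; typically the LD-pruned set).
#' @param mode `"additive"` (QTL model without dominance) or
#'   `"additive_dominance"`.
#' @param rounds post-burn-in rounds.
#' @param burnin burn-in rounds.
#' @param reml_every interval (in rounds) at which variance components
#'   are re-estimated by REML and stored; use a value larger than
#'   `rounds + burnin` to disable.
#' @param update_conditioning if `TRUE`, each periodic REML fit also
#'   refreshes the frozen variances the sampler conditions on.  The
#'   default `FALSE` keeps the conditioning (and hence `V`) fixed for
#'   the whole chain — SNP effects are fixed effects exactly so that `V`
#'   never needs updating — which makes the chain a standard
#'   fixed-target MCMC; the periodic fits then serve only the posterior
#'   summaries.
#' @param prior_mean mean of the Poisson prior on the SNP count.
#' @param init initial variances: a [reml_fit()] of `spec` or a named
#'   `sigma2` vector; default fits `spec` by REML.
#' @param init_selection `"greedy"` (default) starts the chain from a
#'   prior-penalized greedy forward selection and re-estimates the
#'   conditioning variances there, so strong signals do not have to wait
#'   for slow transdimensional entry (the starting state does not affect
#'   the stationary distribution; burn-in applies as usual); `"empty"`
#'   starts from no selected SNPs.
#' @param predict_newdata,predict_candidates optional held-out animals
#'   (data frame for the base model plus their candidate dosage rows);
#'   per-round model-averaged predictions are returned for them.
#' @param seed optional integer seed.
#' @param verbose print progress.
#' @return An object of class `rjmcmc` with per-round traces (`ll`,
#'   `nq`, `accepted`, `move`), posterior inclusion counts, stored REML
#'   estimates, and averaged predictions.  Summarize with
#'   [posterior_summaries()].
#' @export
run_rjmcmc <- function(spec, candidates,
                       mode = c("additive", "additive_dominance"),
                       rounds = 100000L, burnin = 10000L,
                       reml_every = 1000L, prior_mean = 1,
                       update_conditioning = FALSE,
                       init = NULL, init_selection = c("greedy", "empty"),
                       predict_newdata = NULL,
                       predict_candidates = NULL, seed = NULL,
                       verbose = FALSE) {
  init_selection <- match.arg(init_selection)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(spec, "mm_spec"), rounds >= 1L, burnin >= 0L,
            prior_mean > 0)
  candidates <- as.matrix(candidates)
  ncand <- ncol(candidates)
  if (ncand == 0L) stop("empty candidate set")
  if (is.null(init)) init <- reml_fit(spec)
  theta <- if (inherits(init, "reml_fit")) unname(init$theta)
           else .theta_from(spec, init)
  base_fit <- if (inherits(init, "reml_fit")) init else NULL
  k_base <- length(spec$terms)
  p0 <- ncol(spec$X)
  cd <- .candidate_design(spec, candidates, mode)
  eng <- .profile_engine(spec, theta, cbind(spec$X, cd$Lam, cd$Del))
  do_predict <- !is.null(predict_newdata)
  if (do_predict) {
    rhs <- stats::delete.response(stats::terms(spec$formula))
    Xn <- stats::model.matrix(rhs,
            stats::model.frame(rhs, predict_newdata,
                               na.action = stats::na.pass))
    LamN <- as.matrix(predict_candidates)
    for (j in seq_len(ncol(LamN))) {
      mj <- is.na(LamN[, j])
      if (any(mj)) LamN[mj, j] <- mean(cd$Lam[, j])
    }
    DelN <- NULL
    if (!is.null(cd$Del)) {
      DelN <- (as.matrix(predict_candidates)[, cd$eligible, drop = FALSE] == 1L) * 1
      DelN[is.na(DelN)] <- 0.5
    }
    Tn <- cbind(Xn, LamN, DelN)
    yhat_fix_sum <- numeric(nrow(Tn))
    rand_parts <- list()
  }
  sel <- integer(0)
  cur <- .profile_ll(eng, .state_cols(sel, p0, cd))
  ## single-SNP evidence at the initial variances: drives the informed
  ## half of the add-proposal kernel (static weights, exact Hastings
  ## correction below, so the stationary distribution is untouched)
  dll1 <- vapply(seq_len(ncand), function(s) {
    pr <- .profile_ll(eng, .state_cols(s, p0, cd))
    if (is.null(pr)) -Inf else pr$ll - cur$ll
  }, numeric(1))
  w_inf <- exp(pmin(pmax(dll1, 0), 30))
  Wtot <- sum(w_inf)
  if (init_selection == "greedy") {
    repeat {
      k <- length(sel)
      if (k >= min(ncand, 25L)) break
      cand_idx <- setdiff(seq_len(ncand), sel)
      best <- NULL; best_ll <- -Inf
      for (s in cand_idx) {
        pr <- .profile_ll(eng, .state_cols(c(sel, s), p0, cd))
        if (!is.null(pr) && pr$ll > best_ll) { best <- s; best_ll <- pr$ll }
      }
      if (is.null(best) ||
          best_ll - cur$ll + log(prior_mean / (k + 1)) <= 0) break
      sel <- c(sel, best)
      cur <- .profile_ll(eng, .state_cols(sel, p0, cd))
    }
    if (length(sel)) {
      rf0 <- .refresh_fit(spec, cd, sel, theta, base_fit)
      theta <- unname(rf0$theta[c(names(spec$terms), "e")])
      eng <- .profile_engine(spec, theta, cbind(spec$X, cd$Lam, cd$Del))
      cur <- .profile_ll(eng, .state_cols(sel, p0, cd))
      while (is.null(cur) && length(sel)) {
        sel <- sel[-length(sel)]
        cur <- .profile_ll(eng, .state_cols(sel, p0, cd))
      }
    }
  }
  stored <- list()
  total <- burnin + rounds
  ll_tr <- numeric(total)
  nq_tr <- integer(total)
  mv_tr <- integer(total)
  ac_tr <- logical(total)
  ## per-round model id (bitmask over candidates) for small spaces
  track_state <- ncand <= 30L
  st_tr <- if (track_state) numeric(total) else NULL
  incl <- numeric(ncand)
  nq_of <- function(s) length(s) + if (mode == "additive_dominance")
    sum(!is.na(cd$dcol[s])) else 0L
  window_rounds <- 0L
  for (r in seq_len(total)) {
    mv <- sample.int(3L, 1L)
    accepted <- FALSE
    k <- length(sel)
    prop <- NULL
    if (mv == 1L && k < ncand) {                      # add
      unsel <- if (k == 0L) seq_len(ncand) else setdiff(seq_len(ncand), sel)
      Wu <- Wtot - sum(w_inf[sel])
      s <- if (stats::runif(1L) < 0.5) .resample(unsel, 1L)
           else unsel[sample.int(length(unsel), 1L, prob = w_inf[unsel])]
      q_add <- 0.5 / length(unsel) + 0.5 * w_inf[s] / Wu
      new_sel <- c(sel, s)
      prop <- .profile_ll(eng, .state_cols(new_sel, p0, cd))
      if (!is.null(prop)) {
        ## Poisson(prior_mean) prior on the SNP count, uniform over sets
        ## of a given size; reverse move is a uniform drop of one of
        ## k+1 SNPs (for a uniform add kernel this reduces to the
        ## familiar lambda/(k+1) factor)
        logacc <- (prop$ll - cur$ll) + log(prior_mean) -
          log(ncand - k) - log(k + 1) - log(q_add)
        if (log(stats::runif(1L)) < logacc) accepted <- TRUE
      }
    } else if (mv == 2L && k >= 1L) {                 # drop
      i <- sample.int(k, 1L)
      s <- sel[i]
      new_sel <- sel[-i]
      prop <- .profile_ll(eng, .state_cols(new_sel, p0, cd))
      if (!is.null(prop)) {
        ## reverse move re-adds s through the mixture add kernel
        unsel_rev <- ncand - k + 1L
        Wu_rev <- Wtot - sum(w_inf[new_sel])
        q_add_rev <- 0.5 / unsel_rev + 0.5 * w_inf[s] / Wu_rev
        logacc <- (prop$ll - cur$ll) + log(unsel_rev) - log(prior_mean) +
          log(q_add_rev) + log(k)
        if (log(stats::runif(1L)) < logacc) accepted <- TRUE
      }
    } else if (mv == 3L && k >= 1L && k < ncand) {    # swap
      i <- sample.int(k, 1L)
      s <- .resample(setdiff(seq_len(ncand), sel), 1L)
      new_sel <- c(sel[-i], s)
      prop <- .profile_ll(eng, .state_cols(new_sel, p0, cd))
      if (!is.null(prop)) {
        logacc <- prop$ll - cur$ll
        if (log(stats::runif(1L)) < logacc) accepted <- TRUE
      }
    }
    if (accepted) { sel <- new_sel; cur <- prop }
    ll_tr[r] <- cur$ll
    nq_tr[r] <- nq_of(sel)
    mv_tr[r] <- mv
    ac_tr[r] <- accepted
    if (track_state) st_tr[r] <- sum(2^(sel - 1L))
    post <- r > burnin
    if (post) {
      incl[sel] <- incl[sel] + 1
      window_rounds <- window_rounds + 1L
      if (do_predict)
        yhat_fix_sum <- yhat_fix_sum +
          drop(Tn[, .state_cols(sel, p0, cd), drop = FALSE] %*% cur$bhat)
    }
    if (r %% reml_every == 0L) {
      rf <- .refresh_fit(spec, cd, sel, theta, base_fit)
      if (update_conditioning) {
        theta <- unname(rf$theta[c(names(spec$terms), "e")])
        eng <- .profile_engine(spec, theta, cbind(spec$X, cd$Lam, cd$Del))
        cur <- .profile_ll(eng, .state_cols(sel, p0, cd))
        ## a state marginally valid under the old variances can turn
        ## collinear under the refreshed ones; shed SNPs until valid
        while (is.null(cur) && length(sel)) {
          sel <- sel[-length(sel)]
          cur <- .profile_ll(eng, .state_cols(sel, p0, cd))
        }
      }
      if (post) {
        stored[[length(stored) + 1L]] <- rf
        if (do_predict) {
          rand_parts[[length(rand_parts) + 1L]] <-
            list(w = window_rounds, v = .predict_base_random(rf, predict_newdata))
          window_rounds <- 0L
        }
      }
      if (verbose) message(sprintf("round %d  logL %.3f  n_q %d", r,
                                   cur$ll, nq_of(sel)))
    }
  }
  yhat <- NULL
  if (do_predict) {
    if (window_rounds > 0L || length(rand_parts) == 0L) {
      rf_last <- if (length(stored)) stored[[length(stored)]]
                 else base_fit %||% reml_fit(spec, start = stats::setNames(
                        theta, c(names(spec$terms), "e")), max_iter = 1L)
      rand_parts[[length(rand_parts) + 1L]] <-
        list(w = max(window_rounds, 1L),
             v = .predict_base_random(rf_last, predict_newdata))
    }
    wts <- vapply(rand_parts, `[[`, numeric(1), "w")
    rnd <- Reduce(`+`, Map(function(p) p$w * p$v, rand_parts)) / sum(wts)
    yhat <- yhat_fix_sum / rounds + rnd
  }
  structure(list(ll = ll_tr, nq = nq_tr, move = mv_tr, accepted = ac_tr,
                 state = st_tr,
                 burnin = burnin, rounds = rounds, mode = mode,
                 inclusion = incl / rounds, stored = stored,
                 k_base = k_base, prior_mean = prior_mean,
                 eligible = cd$eligible, yhat = yhat,
                 final_theta = theta),
            class = "rjmcmc")
}

## REML refresh: base terms plus common-variance design terms for the
## currently selected SNP effect columns
.refresh_fit <- function(spec, cd, sel, theta, base_fit) {
  nmB <- names(spec$terms)
  if (length(sel) == 0L) {
    start <- stats::setNames(theta, c(nmB, "e"))
    return(reml_fit(spec, start = start))
  }
  sp2 <- spec
  Z <- cd$Lam[, sel, drop = FALSE]
  sp2$terms$snp_add <- list(name = "snp_add", type = "design", Z = Z,
                            R = tcrossprod(Z),
                            scale = sum(apply(Z, 2L, stats::var)))
  dc <- cd$dcol[sel]; dc <- dc[!is.na(dc)]
  if (!is.null(cd$Del) && length(dc)) {
    Zd <- cd$Del[, dc, drop = FALSE]
    sp2$terms$snp_dom <- list(name = "snp_dom", type = "design", Z = Zd,
                              R = tcrossprod(Zd),
                              scale = sum(apply(Zd, 2L, stats::var)))
  }
  vary <- stats::var(spec$y)
  extra <- length(sp2$terms) - length(spec$terms)
  start <- c(theta[seq_along(nmB)], rep(0.05 * vary, extra),
             theta[length(theta)])
  reml_fit(sp2, start = stats::setNames(start, c(names(sp2$terms), "e")))
}

## family/cage/genomic prediction component of a refresh fit (design
## terms excluded: the per-round GLS effects already carry the QTL part)
.predict_base_random <- function(fit, newdata) {
  spec <- fit$spec
  out <- numeric(nrow(newdata))
  for (j in seq_along(spec$terms)) {
    tm <- spec$terms[[j]]
    u <- fit$ranef[[j]]
    if (tm$type == "factor") {
      add <- u[as.character(newdata[[tm$var]])]
      add[is.na(add)] <- 0
      out <- out + add
    } else if (tm$type == "relmat") {
      ids <- as.character(newdata[[tm$var]])
      if (any(!ids %in% names(u)))
        stop("prediction individuals absent from relationship matrix")
      out <- out + u[ids]
    }
  }
  unname(out)
}

#' Posterior summaries of an RJMCMC run
#'
#' Post-burn-in averages: mean profile log-likelihood, mean number of
#' fitted effect terms (additive and dominance counted separately,
#' reported to 2 decimals), `AIC = 2 * (n_base_components + avg_nq) -
#' 2 * avg_loglik`, posterior-mean variance ratios over the stored REML
#' refreshes, per-SNP posterior inclusion probabilities, acceptance
#' rates per move type, and averaged held-out predictions when
#' requested.
#'
#' @param trace an [run_rjmcmc()] result.
#' @export
posterior_summaries <- function(trace) {
  stopifnot(inherits(trace, "rjmcmc"))
  post <- seq.int(trace$burnin + 1L, trace$burnin + trace$rounds)
  avg_ll <- mean(trace$ll[post])
  avg_nq <- round(mean(trace$nq[post]), 2)
  ratios <- NULL
  if (length(trace$stored)) {
    tabs <- lapply(trace$stored, function(f)
      stats::setNames(f$varcomp$ratio, f$varcomp$component))
    comps <- unique(unlist(lapply(tabs, names)))
    ratios <- vapply(comps, function(cn)
      mean(vapply(tabs, function(tb) {
        v <- unname(tb[cn]); if (is.na(v)) 0 else v
      }, numeric(1))), numeric(1))
  }
  acc <- tapply(trace$accepted[post], trace$move[post], mean)
  list(avg_loglik = avg_ll, avg_nq = avg_nq,
       aic = aic(avg_ll, trace$k_base + avg_nq),
       ratios = ratios, inclusion = trace$inclusion,
       acceptance_rates = acc, yhat = trace$yhat)
}

#' @export
print.rjmcmc <- function(x, ...) {
  s <- posterior_summaries(x)
  cat("RJMCMC SNP selection (", x$mode, "): ", x$rounds, " rounds after ",
      x$burnin, " burn-in\n", sep = "")
  cat(sprintf("avg logL %.2f   avg n_q %.2f   AIC %.2f\n",
              s$avg_loglik, s$avg_nq, s$aic))
  if (!is.null(s$ratios)) {
    cat("posterior-mean variance ratios:\n")
    print(round(s$ratios, 3))
  }
  invisible(x)
}
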