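#' Estimation/validation split of phenotyped animals
#'
#' Two schemes mirroring the information available at prediction time:
#'
#' * `within_fullsib`: within every full-sib family about half of the
#'   members (randomly `floor(s/2)` or `ceiling(s/2)`) go to validation,
#'   so estimation and validation sets share families;
#' * `across_fullsib`: within every top-level family about half of its
#'   full-sib families are assigned wholesale to validation, so no
#'   full-sib family spans both sets.
#'
#' Animals without a full-sib family (founders) are split at random in
#' the within scheme and kept in the estimation set in the across scheme
#' (they belong to no nuclear family that could leak).
#'
#' @param phen phenotype data frame with columns `id`, `fullsib_family`,
#'   `family`.
#' @param scheme `"within_fullsib"` or `"across_fullsib"`.
#' @return List with `estimation` and `validation` id vectors and the
#'   scheme.
#' @export
make_split <- function(phen, scheme = c("within_fullsib", "across_fullsib")) {
  scheme <- match.arg(scheme)
  ids <- as.character(phen$id)
  fsf <- as.character(phen$fullsib_family)
  val <- character(0)
  if (scheme == "within_fullsib") {
    for (f in unique(stats::na.omit(fsf))) {
      mem <- ids[!is.na(fsf) & fsf == f]
      nv <- if (stats::runif(1L) < 0.5) floor(length(mem) / 2)
            else ceiling(length(mem) / 2)
      if (nv > 0L) val <- c(val, .resample(mem, nv))
    }
    loose <- ids[is.na(fsf)]
    if (length(loose) > 1L)
      val <- c(val, .resample(loose, floor(length(loose) / 2)))
  } else {
    fam <- as.character(phen$family)
    for (tf in unique(fam)) {
      fs <- unique(stats::na.omit(fsf[fam == tf]))
      if (length(fs) == 0L) next
      nv <- if (stats::runif(1L) < 0.5) floor(length(fs) / 2)
            else ceiling(length(fs) / 2)
      if (nv > 0L) {
        vf <- .resample(fs, nv)
        val <- c(val, ids[!is.na(fsf) & fsf %in% vf])
      }
    }
  }
  list(estimation = setdiff(ids, val), validation = val, scheme = scheme)
}

#' Prediction accuracy and bias
#'
#' Accuracy is the Pearson correlation between predicted and actual
#' phenotypes; the regression coefficient of actual on predicted
#' (`cov(actual, predicted)/var(predicted)`) indicates bias, with 1 =
#' unbiased.
#'
#' @param predicted,actual numeric vectors.
#' @return Named vector `c(accuracy, regression)`; `NA` with a warning
#'   when predictions have zero variance or fewer than 3 pairs are
#'   available.
#' @export
evaluate_prediction <- function(predicted, actual) {
  ok <- is.finite(predicted) & is.finite(actual)
  predicted <- predicted[ok]; actual <- actual[ok]
  if (length(predicted) < 3L || stats::var(predicted) == 0) {
    warning("prediction metrics undefined (zero variance or < 3 points)")
    return(c(accuracy = NA_real_, regression = NA_real_))
  }
  c(accuracy = stats::cor(predicted, actual),
    regression = stats::cov(actual, predicted) / stats::var(predicted))
}

#' Cross-validated phenotype prediction over the model ladder
#'
#' For each replicate and scheme, splits the phenotyped animals with
#' [make_split()], fits each requested model on the estimation records
#' only (relationship matrices keep spanning all animals — genotypes and
#' pedigree are not phenotypes), predicts the validation animals, and
#' computes accuracy and regression.  Models `"1"`, `"1-u"`, `"1-f"`,
#' `"2"` are REML fits predicted with [predict.reml_fit()]; models `"3"`
#' and `"4"` run [run_rjmcmc()] on the estimation set and use the
#' round-averaged predictions.  Non-converged replicates are flagged and
#' excluded from the summaries.
#'
#' @param phen phenotype data frame (columns `id`, trait, `cage`,
#'   `cage_density`, `fullsib_family`, `family`).
#' @param models subset of `c("1", "1-u", "1-f", "2", "3", "4")`.
#' @param schemes subset of `c("within_fullsib", "across_fullsib")`.
#' @param replicates number of replicates.
#' @param A,G relationship matrices as required by the models.
#' @param candidates candidate dosage matrix (rows aligned with `phen`)
#'   for models 3/4.
#' @param trait response column name.
#' @param mcmc list of RJMCMC settings for models 3/4 (`rounds`,
#'   `burnin`, `reml_every`, `prior_mean`).
#' @param seed optional master seed; replicate r uses `seed + r`.
#' @return List with `results` (per replicate x scheme x model metrics)
#'   and `summary` (mean and SD of accuracy and regression).
#' @export
cross_validate <- function(phen, models = c("1", "2"),
                           schemes = c("within_fullsib", "across_fullsib"),
                           replicates = 10L, A = NULL, G = NULL,
                           candidates = NULL, trait = "y",
                           mcmc = list(rounds = 20000L, burnin = 2000L,
                                       reml_every = 1000L, prior_mean = 1),
                           seed = NULL) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  rows <- list()
  for (r in seq_len(replicates)) {
    if (!is.null(seed)) set.seed(seed + r)
    for (sch in schemes) {
      split <- make_split(phen, sch)
      est <- phen[phen$id %in% split$estimation, , drop = FALSE]
      valp <- phen[phen$id %in% split$validation, , drop = FALSE]
      for (mo in models) {
        res <- tryCatch(
          suppressWarnings(.cv_one(mo, est, valp, A, G, candidates, phen,
                                   trait, mcmc)),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = r, scheme = sch, model = mo,
          accuracy = if (is.null(res)) NA_real_ else res[["accuracy"]],
          regression = if (is.null(res)) NA_real_ else res[["regression"]],
          converged = !is.null(res), stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(accuracy, regression) ~ scheme + model,
                          data = results[results$converged, , drop = FALSE],
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  summary_df <- data.frame(scheme = agg$scheme, model = agg$model,
                           acc_mean = agg$accuracy[, "mean"],
                           acc_sd = agg$accuracy[, "sd"],
                           reg_mean = agg$regression[, "mean"],
                           reg_sd = agg$regression[, "sd"],
                           stringsAsFactors = FALSE)
  list(results = results, summary = summary_df)
}

.cv_one <- function(mo, est, valp, A, G, candidates, phen, trait, mcmc) {
  if (mo %in% c("1", "1-u", "1-f", "2")) {
    fit <- fit_model(mo, est, A = A, G = G, trait = trait)
    if (!fit$converged) return(NULL)
    pred <- predict(fit, valp)
  } else {
    if (is.null(candidates)) stop("models 3/4 need a candidate matrix")
    f <- stats::as.formula(paste(trait, "~ cage_density"))
    spec <- mm_spec(f, est, list(f = ~fullsib_family, c = ~cage,
                                 g = vc_relmat(G, "id")))
    cand_est <- candidates[match(est$id, phen$id), , drop = FALSE]
    cand_val <- candidates[match(valp$id, phen$id), , drop = FALSE]
    tr <- run_rjmcmc(spec, cand_est,
                     mode = if (mo == "3") "additive" else "additive_dominance",
                     rounds = mcmc$rounds, burnin = mcmc$burnin,
                     reml_every = mcmc$reml_every,
                     prior_mean = mcmc$prior_mean,
                     predict_newdata = valp, predict_candidates = cand_val)
    pred <- tr$yhat
  }
  evaluate_prediction(pred, valp[[trait]])
}
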