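#' @title Posterior-probability filtering of prediction scores
#' @description Calibrates raw target-prediction context scores against the
#'   score distribution of empirically validated interactions and keeps
#'   predictions whose posterior probability of being a valid interaction
#'   exceeds a threshold (default 0.98).
#' @name prediction_filter
NULL

#' Fit a two-component score model
#'
#' Models the population of prediction context scores as a mixture of a
#' *valid* component (scores of genuinely functional miRNA-target pairs,
#' calibrated on the empirically validated subset) and a *background*
#' component (scores of spurious predictions). Both components are Gaussian.
#' The mixing weight `prior_valid` - the fraction of all predictions
#' attributable to the valid component - is estimated by a one-parameter EM
#' fixed-point on the pooled predicted scores with the component densities
#' held fixed. With `family = "gaussian_mixture"` a full two-component EM is
#' run on the pooled scores instead, with the component closer (in mean) to
#' the validated sample taken as the valid one; use this when no clean
#' validated score sample is available.
#'
#' @param validated_scores numeric; context scores of predictions whose pairs
#'   are empirically validated (>= 30 finite values required).
#' @param all_predicted_scores numeric; context scores of the whole predicted
#'   population (>= 30 finite values required). Scores equal to validated
#'   pairs are *not* removed here; pass the background-only sample if you
#'   have one, or leave the contamination to the mixture weight.
#' @param family `"gaussian"` (components anchored: valid from the validated
#'   sample, background from the predicted population after down-weighting)
#'   or `"gaussian_mixture"` (free two-component EM on the pooled scores).
#' @param threshold posterior probability above which a prediction is kept;
#'   default 0.98.
#' @param prior_valid optional fixed mixing weight overriding the estimate.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   mixing weight / parameters.
#' @return a `score_model` object with elements `valid` and `background`
#'   (each `list(mean, sd, family = "gaussian")`), `prior_valid`,
#'   `threshold`, `family`, `identifiable` (FALSE when the two components are
#'   indistinguishable, making the mixing weight unstable) and `n` (sample
#'   sizes used).
#' @export
fit_score_model <- function(validated_scores, all_predicted_scores,
                            family = c("gaussian", "gaussian_mixture"),
                            threshold = 0.98, prior_valid = NULL,
                            max_iter = 500L, tol = 1e-8) {
  family <- match.arg(family)
  clean <- function(x, what) {
    x <- as.numeric(x)
    bad <- !is.finite(x)
    if (any(bad)) warning(sum(bad), " non-finite ", what, " scores rejected")
    x[!bad]
  }
  v <- clean(validated_scores, "validated")
  p <- clean(all_predicted_scores, "predicted")
  if (length(v) < 30L || length(p) < 30L) {
    stop("need at least 30 finite scores in each sample")
  }
  if (stats::sd(v) == 0 || stats::sd(p) == 0) {
    stop("degenerate score sample: all values identical")
  }
  stopifnot(threshold > 0, threshold < 1)

  mle_norm <- function(x) list(mean = mean(x),
                               sd = sqrt(mean((x - mean(x))^2)),
                               family = "gaussian")

  if (family == "gaussian") {
    valid <- mle_norm(v)
    # background: EM on the pooled predicted scores with the valid component
    # fixed; the background parameters and mixing weight are re-estimated
    # from the responsibility-weighted sample.
    bg <- mle_norm(p)
    pi_v <- if (!is.null(prior_valid)) prior_valid else 0.1
    for (i in seq_len(max_iter)) {
      fv <- stats::dnorm(p, valid$mean, valid$sd)
      fb <- stats::dnorm(p, bg$mean, bg$sd)
      r <- pi_v * fv / (pi_v * fv + (1 - pi_v) * fb)
      r[!is.finite(r)] <- 0.5
      w <- 1 - r
      new_bg <- list(mean = sum(w * p) / sum(w),
                     sd = sqrt(sum(w * (p - sum(w * p) / sum(w))^2) / sum(w)),
                     family = "gaussian")
      new_pi <- if (!is.null(prior_valid)) prior_valid else mean(r)
      delta <- abs(new_pi - pi_v) + abs(new_bg$mean - bg$mean) +
        abs(new_bg$sd - bg$sd)
      bg <- new_bg
      pi_v <- new_pi
      if (delta < tol) break
    }
  } else {
    # free 2-component EM on pooled scores, initialized from the validated
    # sample and the pooled complement
    valid <- mle_norm(v)
    bg <- mle_norm(p)
    pi_v <- if (!is.null(prior_valid)) prior_valid else 0.5
    for (i in seq_len(max_iter)) {
      fv <- stats::dnorm(p, valid$mean, valid$sd)
      fb <- stats::dnorm(p, bg$mean, bg$sd)
      r <- pi_v * fv / (pi_v * fv + (1 - pi_v) * fb)
      r[!is.finite(r)] <- 0.5
      upd <- function(w) {
        mu <- sum(w * p) / sum(w)
        list(mean = mu, sd = sqrt(sum(w * (p - mu)^2) / sum(w)),
             family = "gaussian")
      }
      new_valid <- upd(r)
      new_bg <- upd(1 - r)
      new_pi <- if (!is.null(prior_valid)) prior_valid else mean(r)
      delta <- abs(new_pi - pi_v) + abs(new_valid$mean - valid$mean) +
        abs(new_bg$mean - bg$mean)
      valid <- new_valid
      bg <- new_bg
      pi_v <- new_pi
      if (delta < tol) break
    }
    # label the component nearer the validated sample mean as "valid"
    if (abs(valid$mean - mean(v)) > abs(bg$mean - mean(v))) {
      tmp <- valid; valid <- bg; bg <- tmp
      pi_v <- 1 - pi_v
    }
  }

  sep <- abs(valid$mean - bg$mean) /
    sqrt((valid$sd^2 + bg$sd^2) / 2)
  identifiable <- is.finite(sep) && sep > 0.5
  if (!identifiable) {
    warning("valid and background score distributions are nearly identical; ",
            "prior_valid estimate is not identifiable")
  }
  pi_v <- min(max(pi_v, 1e-6), 1 - 1e-6)
  structure(list(valid = valid, background = bg,
                 prior_valid = pi_v, threshold = threshold,
                 family = family, identifiable = identifiable,
                 n = c(validated = length(v), predicted = length(p))),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat("score_model (", x$family, ")\n", sep = "")
  cat(sprintf("  valid:      Normal(mean = %.4f, sd = %.4f)\n",
              x$valid$mean, x$valid$sd))
  cat(sprintf("  background: Normal(mean = %.4f, sd = %.4f)\n",
              x$background$mean, x$background$sd))
  cat(sprintf("  prior_valid = %.4f, posterior threshold = %.3f%s\n",
              x$prior_valid, x$threshold,
              if (!x$identifiable) "  [NOT identifiable]" else ""))
  invisible(x)
}

#' Posterior probability that a scored prediction is valid
#'
#' Bayes rule on the fitted two-component model:
#' `pi * f_valid(s) / (pi * f_valid(s) + (1 - pi) * f_background(s))`.
#'
#' @param score numeric vector of finite context scores.
#' @param model a fitted [fit_score_model()] object.
#' @return posterior probabilities in \[0, 1\], same length as `score`.
#' @export
posterior_validity <- function(score, model) {
  stopifnot(inherits(model, "score_model"))
  score <- as.numeric(score)
  if (any(!is.finite(score))) stop("non-finite score")
  # work on log densities to keep extreme tails stable
  lv <- stats::dnorm(score, model$valid$mean, model$valid$sd, log = TRUE) +
    log(model$prior_valid)
  lb <- stats::dnorm(score, model$background$mean, model$background$sd,
                     log = TRUE) + log(1 - model$prior_valid)
  1 / (1 + exp(lb - lv))
}

#' @export
predict.score_model <- function(object, newdata, ...) {
  posterior_validity(newdata, object)
}

#' Filter predictions by posterior validity
#'
#' Keeps predictions whose posterior probability of being valid exceeds the
#' model threshold, and reports the reduction in pairs, genes and miRNAs.
#'
#' @param predictions an [interaction_set()] carrying a `context_score`
#'   column (predicted dialect), or a data frame with columns `mirna`,
#'   `gene`, `context_score`.
#' @param model a fitted [fit_score_model()] object.
#' @param threshold optional override of `model$threshold`.
#' @return a list with `kept` (an [interaction_set()] of the retained pairs,
#'   with a `posterior` column), `posterior` (per input pair) and `report`
#'   (kept/dropped pair counts and distinct gene/miRNA counts before and
#'   after filtering).
#' @export
filter_predictions <- function(predictions, model, threshold = NULL) {
  stopifnot(inherits(model, "score_model"))
  if (!("context_score" %in% names(predictions))) {
    stop("predictions must carry a context_score column")
  }
  thr <- threshold %||% model$threshold
  post <- posterior_validity(predictions$context_score, model)
  keep <- post > thr
  kept <- interaction_set(predictions$mirna[keep], predictions$gene[keep],
                          source = "PREDICTED", evidence = "predicted",
                          score = predictions$context_score[keep],
                          name = "filtered_predictions")
  kept$posterior <- posterior_validity(kept$context_score, model)
  report <- list(
    threshold = thr,
    n_pairs_before = nrow(predictions), n_pairs_kept = sum(keep),
    n_genes_before = length(unique(predictions$gene)),
    n_genes_kept = length(unique(predictions$gene[keep])),
    n_mirnas_before = length(unique(predictions$mirna)),
    n_mirnas_kept = length(unique(predictions$mirna[keep])))
  list(kept = kept, posterior = post, report = report)
}

#' Serialize / restore a score model
#'
#' JSON round-trip of all model parameters at full double precision, so that
#' restored models reproduce posteriors bit-for-bit.
#'
#' @param model a `score_model`.
#' @param path file path.
#' @return `write_score_model()` returns `path` invisibly;
#'   `read_score_model()` returns the restored `score_model`.
#' @export
write_score_model <- function(model, path) {
  stopifnot(inherits(model, "score_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_score_model
#' @export
read_score_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$n <- unlist(x$n)
  structure(x, class = "score_model")
}
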