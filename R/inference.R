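#' Statistical layer: logistic intersection model, windowed odds ratios,
#' Welch comparison
#'
#' The probability that an hourly prenesting path segment interacts with a
#' nest-associated buffer is modelled as
#' `logit P(flag = 1) = b0 + b1 * day_before_laying`, pooled over females
#' within a subspecies (the segment is the unit of analysis; per-bird
#' clustering is deliberately unmodelled, with cluster-robust SEs available
#' behind a flag). Windowed contingency tables compare in-buffer odds between
#' days-before-laying windows with Woolf 95% intervals.
#'
#' @name inference
NULL

#' Fit the logistic intersection model
#'
#' Maximum-likelihood logistic regression of a region's 0/1 flag on the
#' days-before-laying index, via [stats::glm()]. Errors on degenerate
#' outcomes (all 0 or all 1) and on complete separation.
#'
#' @param records segment records (pooled across birds).
#' @param region region column name.
#' @param cluster_se also compute cluster-robust (by bird) standard errors
#'   via [sandwich::vcovCL()]; consecutive segments of one female are
#'   serially dependent, so the naive Wald interval understates uncertainty.
#' @return a `logistic_fit`: list with `region`, `coef` (b0, b1), `se`, `p`,
#'   `n`, `converged`, `grad_norm` (sup-norm of the score at the optimum),
#'   and the `glm` object; with `cluster_se`, also `se_cluster` and
#'   `df_cluster` (number of birds minus one, for t-based intervals).
#' @export
fit_intersection_model <- function(records, region, cluster_se = FALSE) {
  flag <- records[[region]]
  if (is.null(flag)) stop("no such region column: ", region, call. = FALSE)
  day <- records$day_before_laying
  if (length(unique(flag)) < 2) {
    stop("outcome is constant for region ", region, call. = FALSE)
  }
  # separation is re-checked explicitly below; glm.fit's own warnings about
  # fitted 0/1 probabilities would only duplicate that signal
  fit <- suppressWarnings(stats::glm(flag ~ day, family = stats::binomial()))
  mu <- stats::fitted(fit)
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    stop("complete separation in region ", region, call. = FALSE)
  }
  grad <- c(sum(flag - mu), sum((flag - mu) * day))
  co <- summary(fit)$coefficients
  out <- list(region = region,
              coef = c(b0 = unname(co[1, 1]), b1 = unname(co[2, 1])),
              se = c(b0 = unname(co[1, 2]), b1 = unname(co[2, 2])),
              p = c(b0 = unname(co[1, 4]), b1 = unname(co[2, 4])),
              n = length(flag),
              converged = fit$converged,
              grad_norm = max(abs(grad)),
              model = fit)
  if (cluster_se) {
    cl <- records$bird_id
    V <- sandwich::vcovCL(fit, cluster = cl)
    out$se_cluster <- c(b0 = sqrt(V[1, 1]), b1 = sqrt(V[2, 2]))
    out$df_cluster <- length(unique(cl)) - 1L
  }
  structure(out, class = "logistic_fit")
}

#' Predicted intersection probability
#'
#' @param fit a `logistic_fit`.
#' @param day days-before-laying value(s).
#' @return probability vector (inverse logit of the linear predictor).
#' @export
predict_probability <- function(fit, day) {
  stats::plogis(fit$coef[["b0"]] + fit$coef[["b1"]] * day)
}

#' Windowed contingency odds ratio
#'
#' Counts segments (or fixes) in-buffer vs not within two days-before-laying
#' windows, and reports `OR = (a*d)/(b*c)` with the Woolf log-interval
#' `exp(ln OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero,
#' the Haldane-Anscombe 0.5 is added to every cell (flagged).
#'
#' @param records segment records.
#' @param region region column name.
#' @param windowA,windowB inclusive `c(lo, hi)` days-before-laying ranges;
#'   the OR is the odds in A relative to B.
#' @return an `odds_ratio`: list with `counts` (a, b, c, d), `or`, `ci_low`,
#'   `ci_high`, `corrected`.
#' @export
window_odds_ratio <- function(records, region, windowA, windowB) {
  flag <- records[[region]]
  day <- records$day_before_laying
  inA <- day >= windowA[1] & day <= windowA[2]
  inB <- day >= windowB[1] & day <= windowB[2]
  if (!any(inA) || !any(inB)) {
    stop("a comparison window contains no segments", call. = FALSE)
  }
  a <- sum(flag[inA] == 1)
  b <- sum(flag[inA] == 0)
  cc <- sum(flag[inB] == 1)
  d <- sum(flag[inB] == 0)
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  structure(list(counts = c(a = a, b = b, c = cc, d = d),
                 or = or,
                 ci_low = exp(log(or) - 1.96 * se),
                 ci_high = exp(log(or) + 1.96 * se),
                 corrected = corrected),
            class = "odds_ratio")
}

#' Welch two-sample comparison
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value, via [stats::t.test()]. Two constant, equal groups
#' return `t = 0, p = 1`.
#'
#' @param groupA,groupB numeric vectors (meters), each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2) {
    stop("each group needs at least two values", call. = FALSE)
  }
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB)) {
      return(list(t = 0, df = length(groupA) + length(groupB) - 2, p = 1))
    }
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  tt <- stats::t.test(groupA, groupB, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}
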