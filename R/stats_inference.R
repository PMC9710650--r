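# Statistical kernels: ordinary and moderated t-tests, one-tailed Fisher
# exact test, Benjamini-Hochberg adjustment, Pearson correlation.

.insufficient_data <- function(msg) {
  stop(structure(class = c("insufficient_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Two-sample independent t-test
#'
#' Two-sided, pooled-variance (equal-variance) t-test on log2 intensities.
#' Missing values are removed per group; fewer than two observations in either
#' group raises a condition of class \code{insufficient_data_error} so callers
#' can skip the protein.
#'
#' @param a,b Numeric vectors of log2 intensities (NAs dropped).
#' @return List with elements \code{t}, \code{p}, \code{df}.
#' @export
independent_t_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    .insufficient_data("need >= 2 observations per group")
  }
  df <- length(a) + length(b) - 2L
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / df
  if (sp2 <= 0) {
    d <- mean(a) - mean(b)
    return(list(t = if (d == 0) 0 else sign(d) * Inf,
                p = if (d == 0) 1 else 0, df = df))
  }
  res <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Empirical-Bayes moderated two-group t-statistics
#'
#' For each protein the two group means, the log2 fold change (A minus B), the
#' pooled residual variance \eqn{s_g^2} and its degrees of freedom \eqn{d_g}
#' are computed on the non-missing values. A scaled inverse-chi-square prior
#' for the variances is then estimated by the method of moments on
#' \eqn{\log s_g^2} (prior degrees of freedom \eqn{d_0}, prior variance
#' \eqn{s_0^2}); with \code{trend = TRUE} the prior variance is a smooth
#' (lowess) function of the protein's average log2 intensity, correcting for
#' the intensity-variance relationship of MS data. The posterior variance
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' yields the moderated t-statistic with \eqn{d_0 + d_g} degrees of freedom.
#' As \eqn{d_0 \to 0} the moderated t reduces to the ordinary t; as
#' \eqn{d_0 \to \infty} every posterior variance equals the prior.
#'
#' @param group_a,group_b Numeric matrices (proteins x samples, same row
#'   names/order) of log2 intensities; \code{NA} = missing. Every protein
#'   needs at least two observations per group.
#' @param trend Model the prior variance as a function of average intensity?
#' @param prior_df Optional override of the estimated prior degrees of
#'   freedom (0 gives the ordinary t-test; \code{Inf} uses the prior variance
#'   alone). Used mainly for validation.
#' @param trend_span Lowess span for the variance trend (default 0.3).
#' @return A data.frame (one row per protein) with columns \code{protein},
#'   \code{mean_A}, \code{mean_B}, \code{log2_fc}, \code{s2}, \code{df_resid},
#'   \code{s2_prior}, \code{s2_post}, \code{t}, \code{p}, \code{df_total};
#'   attributes \code{prior_df} (\eqn{d_0}) and \code{trend}.
#' @export
moderated_t_fit <- function(group_a, group_b, trend = TRUE,
                            prior_df = NULL, trend_span = 0.3) {
  group_a <- as.matrix(group_a)
  group_b <- as.matrix(group_b)
  stopifnot(nrow(group_a) == nrow(group_b))
  n_a <- rowSums(!is.na(group_a))
  n_b <- rowSums(!is.na(group_b))
  if (any(n_a < 2L | n_b < 2L)) {
    stop(sum(n_a < 2L | n_b < 2L),
         " protein(s) have fewer than 2 observations in a group; ",
         "filter before fitting", call. = FALSE)
  }
  mean_a <- rowMeans(group_a, na.rm = TRUE)
  mean_b <- rowMeans(group_b, na.rm = TRUE)
  ss <- function(m, mu) rowSums((m - mu)^2, na.rm = TRUE)
  d <- n_a + n_b - 2L
  s2 <- (ss(group_a, mean_a) + ss(group_b, mean_b)) / d
  if (all(s2 == 0)) {
    stop("all proteins have zero residual variance; cannot fit prior",
         call. = FALSE)
  }
  abar <- (rowSums(group_a, na.rm = TRUE) + rowSums(group_b, na.rm = TRUE)) /
    (n_a + n_b)
  prior <- .fit_variance_prior(s2, d, if (trend) abar else NULL,
                               span = trend_span)
  d0 <- if (!is.null(prior_df)) prior_df else prior$d0
  s2_prior <- prior$s2_prior
  s2_post <- if (is.infinite(d0)) s2_prior
             else (d0 * s2_prior + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n_a + 1 / n_b))
  tstat <- (mean_a - mean_b) / se
  # the pooled information cannot exceed the total residual df of the fit
  df_total <- pmin(d0 + d, sum(d))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(protein = rownames(group_a) %||%
                      paste0("protein_", seq_along(s2)),
                    mean_A = mean_a, mean_B = mean_b,
                    log2_fc = mean_a - mean_b,
                    s2 = s2, df_resid = d,
                    s2_prior = s2_prior, s2_post = s2_post,
                    t = tstat, p = p, df_total = df_total,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior_df") <- d0
  attr(out, "trend") <- trend
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Method-of-moments fit of the scaled inverse-chi-square variance prior
# (Smyth-style): on z = log s2, e = z - digamma(d/2) + log(d/2) has mean
# log s0^2 + digamma(d0/2) - log(d0/2) and excess variance trigamma(d0/2)
# beyond trigamma(d/2). With a covariate, the mean is a lowess fit in the
# average intensity instead of a constant.
.fit_variance_prior <- function(s2, d, covariate = NULL, span = 0.3) {
  ok <- s2 > 0 & d > 0
  z <- log(s2[ok])
  dg <- d[ok]
  e <- z - digamma(dg / 2) + log(dg / 2)
  n <- length(e)
  if (n < 2L) {
    return(list(d0 = Inf, s2_prior = rep(mean(exp(e)), length(s2))))
  }
  if (!is.null(covariate)) {
    cv <- covariate[ok]
    lo <- stats::lowess(cv, e, f = span)
    efit_ok <- stats::approx(lo$x, lo$y, xout = cv, rule = 2, ties = mean)$y
    efit_all <- stats::approx(lo$x, lo$y, xout = covariate, rule = 2,
                              ties = mean)$y
  } else {
    efit_ok <- rep(mean(e), n)
    efit_all <- rep(mean(e), length(s2))
  }
  resid <- e - efit_ok
  evar <- sum(resid^2) / (n - 1) - mean(trigamma(dg / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s2_prior <- exp(efit_all + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond sampling noise: the variances are
    # exchangeable and the prior is their plain average (constant case)
    d0 <- Inf
    s2_prior <- if (is.null(covariate)) rep(mean(s2[ok]), length(s2))
                else exp(efit_all)
  }
  list(d0 = d0, s2_prior = s2_prior)
}

# Solve trigamma(y) = x by Newton iteration.
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in seq_len(50L)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with the monotone
#' envelope; output preserves length and order of the input.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, elementwise >= the input and <= 1.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' One-tailed Fisher exact test (enrichment direction)
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' number of detected in-term proteins, for the 2x2 table
#' (in term / not in term) x (detected / not detected).
#'
#' @param in_detected Proteins in the term and detected.
#' @param in_not Proteins in the term, not detected.
#' @param out_detected Proteins not in the term, detected.
#' @param out_not Proteins not in the term, not detected.
#' @return The one-tailed p-value.
#' @export
fisher_one_tailed <- function(in_detected, in_not, out_detected, out_not) {
  counts <- c(in_detected, in_not, out_detected, out_not)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  stats::phyper(in_detected - 1,
                m = in_detected + in_not,
                n = out_detected + out_not,
                k = in_detected + out_detected,
                lower.tail = FALSE)
}

#' Squared Pearson correlation on pairwise-complete observations
#'
#' @param x,y Numeric vectors of equal length; pairs with a missing value in
#'   either vector are dropped.
#' @return r-squared in [0, 1].
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2L) {
    .insufficient_data("need >= 2 complete pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop(structure(class = c("undefined_correlation_error", "error",
                             "condition"),
                   list(message = "zero variance: correlation undefined",
                        call = NULL)))
  }
  unname(stats::cor(x, y)^2)
}
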