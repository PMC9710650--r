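# Sigmoidal detection threshold and the four-scenario protein categorization.

#' Detection threshold policy
#'
#' Proteins in label-free MS data are frequently not detected at random, so a
#' protein must be detected (raw intensity > 0) in a sufficient number of
#' samples per group before it enters a group comparison. The required
#' fraction of detected samples follows a sigmoidal function of group size:
#' 100\% for groups of up to \code{n_full} samples, relaxing to 50\% for
#' groups of \code{n_half} or more samples, with a logistic interpolation
#' centered at \code{(n_full + n_half) / 2} in between.
#'
#' @param n_full Group size up to which every sample must show a detection
#'   (default 3).
#' @param n_half Group size from which half the samples suffice (default 12).
#' @param steepness Logistic rate of the interpolation, per sample
#'   (default 1).
#' @return An object of class \code{threshold_policy}.
#' @examples
#' pol <- threshold_policy()
#' required_fraction(pol, c(1, 3, 6, 12, 20))
#' required_count(pol, 12)
#' @export
threshold_policy <- function(n_full = 3, n_half = 12, steepness = 1.0) {
  stopifnot(n_full >= 1, n_half > n_full, steepness > 0)
  structure(list(n_full = n_full, n_half = n_half,
                 midpoint = (n_full + n_half) / 2,
                 steepness = steepness),
            class = "threshold_policy")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat("threshold_policy: 100% detection for n <= ", x$n_full,
      ", 50% for n >= ", x$n_half,
      ", logistic midpoint ", x$midpoint,
      ", steepness ", x$steepness, "/sample\n", sep = "")
  invisible(x)
}

#' Required detection fraction for a group size
#'
#' \code{required_fraction(policy, n)} is 1 for \code{n <= n_full}, 0.5 for
#' \code{n >= n_half}, and in between follows
#' \code{0.5 + 0.5 * plogis(-k * (n - midpoint))}: strictly decreasing,
#' always in [0.5, 1].
#'
#' @param policy A [threshold_policy()].
#' @param n Group size(s) in samples, \code{n >= 1}.
#' @return Numeric vector of required fractions in [0.5, 1].
#' @export
required_fraction <- function(policy, n) {
  stopifnot(inherits(policy, "threshold_policy"))
  if (any(is.na(n)) || any(n < 1)) {
    stop("group size must be >= 1", call. = FALSE)
  }
  f <- 0.5 + 0.5 * stats::plogis(-policy$steepness * (n - policy$midpoint))
  f[n <= policy$n_full] <- 1
  f[n >= policy$n_half] <- 0.5
  f
}

#' Minimum number of detections required in a group
#'
#' The ceiling of \code{required_fraction(policy, n) * n}, so the threshold
#' is never satisfied by fewer detections than the fraction implies.
#'
#' @inheritParams required_fraction
#' @return Integer vector of minimum detection counts, each \code{<= n}.
#' @export
required_count <- function(policy, n) {
  as.integer(ceiling(required_fraction(policy, n) * n - 1e-12))
}

#' Is a detection count above the group threshold?
#'
#' @param detections Number of samples (0..n) in which the protein was
#'   detected.
#' @inheritParams required_fraction
#' @return Logical vector.
#' @export
above_threshold <- function(detections, policy, n) {
  if (any(detections < 0) || any(detections > n)) {
    stop("detections must lie in [0, group size]", call. = FALSE)
  }
  detections >= required_count(policy, n)
}

#' Categorize a protein for a two-group comparison
#'
#' The four scenarios: the protein is \code{comparable} if it is detected
#' above threshold in both groups; \code{unique_in_A} if above threshold in A
#' and utterly absent (zero detections) in B, and symmetrically
#' \code{unique_in_B}; otherwise \code{not_considered} (below threshold in
#' both, or above threshold on one side with a below-threshold but nonzero
#' count on the other). The labels are mutually exclusive and exhaustive.
#'
#' @param det_a,det_b Detection counts in groups A and B (vectorized).
#' @param n_a,n_b Group sizes.
#' @param policy A [threshold_policy()].
#' @return Character vector with values in \code{c("comparable",
#'   "unique_in_A", "unique_in_B", "not_considered")}.
#' @export
categorize_detection <- function(det_a, n_a, det_b, n_b, policy) {
  above_a <- above_threshold(det_a, policy, n_a)
  above_b <- above_threshold(det_b, policy, n_b)
  out <- rep("not_considered", length(above_a))
  out[above_a & above_b] <- "comparable"
  out[above_a & !above_b & det_b == 0] <- "unique_in_A"
  out[above_b & !above_a & det_a == 0] <- "unique_in_B"
  out
}
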