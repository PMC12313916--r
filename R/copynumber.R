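# ddPCR Poisson copy-number estimation and the multi-copy reporter
# activation model, plus dose arithmetic.

#' Poisson mean occupancy from partition counts
#'
#' In digital PCR the fraction of positive partitions p underestimates the
#' mean copies per partition because multiply-occupied partitions score
#' once; the Poisson correction is \eqn{\lambda = -\ln(1 - p)}.
#'
#' @param n_positive Positive partitions.
#' @param n_partitions Total accepted partitions.
#' @return \eqn{\lambda \ge 0}.
#' @examples
#' poisson_lambda(10000, 20000)  # -log(0.5)
#' @export
poisson_lambda <- function(n_positive, n_partitions) {
  if (n_partitions <= 0) stop("n_partitions must be positive")
  if (n_positive < 0 || n_positive > n_partitions)
    stop("n_positive must lie in [0, n_partitions]")
  if (n_positive == n_partitions)
    stop("all partitions positive: lambda unbounded (saturated channel)")
  -log1p(-n_positive / n_partitions)
}

#' Copies per diploid genome from two-channel ddPCR counts
#'
#' Poisson-corrects each channel, forms the target:reference concentration
#' ratio (the partition volume cancels), and scales by the reference
#' gene's copies per diploid genome. The 95\% CI uses the Wilson score
#' interval on each channel's positive fraction, carried through the
#' monotone map \eqn{\lambda = -\ln(1-p)} and combined on the log-ratio
#' scale by the delta method.
#'
#' @param n_partitions Total accepted partitions (common to both channels).
#' @param n_positive_target,n_positive_reference Positive partitions per
#'   channel.
#' @param reference_copies_per_diploid Copies of the reference gene per
#'   diploid genome (default 2).
#' @return Object of class \code{copy_number_result}: \code{lambda_target},
#'   \code{lambda_reference}, \code{ratio}, \code{copies_per_diploid},
#'   \code{ci95_ratio}, \code{ci95_copies}.
#' @examples
#' copies_per_genome(20000, 11000, 4000)
#' @export
copies_per_genome <- function(n_partitions, n_positive_target,
                              n_positive_reference,
                              reference_copies_per_diploid = 2L) {
  lam_t <- poisson_lambda(n_positive_target, n_partitions)
  lam_r <- poisson_lambda(n_positive_reference, n_partitions)
  if (lam_r == 0) stop("no positive reference partitions: ratio undefined")
  ratio <- lam_t / lam_r

  se_log_lambda <- function(x, n) {
    p <- x / n
    lam <- -log1p(-p)
    ci <- stats::prop.test(x, n, correct = FALSE)$conf.int  # Wilson score
    lam_ci <- -log1p(-ci)
    list(se = (log(lam_ci[2]) - log(lam_ci[1])) / (2 * stats::qnorm(0.975)),
         lam = lam)
  }
  st <- se_log_lambda(n_positive_target, n_partitions)
  sr <- se_log_lambda(n_positive_reference, n_partitions)
  se_lr <- sqrt(st$se^2 + sr$se^2)
  z <- stats::qnorm(0.975)
  ci_ratio <- ratio * exp(c(-1, 1) * z * se_lr)

  structure(list(
    lambda_target = lam_t, lambda_reference = lam_r, ratio = ratio,
    copies_per_diploid = ratio * reference_copies_per_diploid,
    ci95_ratio = ci_ratio,
    ci95_copies = ci_ratio * reference_copies_per_diploid,
    n_partitions = n_partitions,
    reference_copies_per_diploid = reference_copies_per_diploid),
    class = "copy_number_result")
}

#' @export
print.copy_number_result <- function(x, ...) {
  cat(sprintf(
    "<copy_number_result> lambda T/R = %.4f/%.4f, ratio %.3f (95%% CI %.3f-%.3f), %.2f copies per diploid genome\n",
    x$lambda_target, x$lambda_reference, x$ratio, x$ci95_ratio[1],
    x$ci95_ratio[2], x$copies_per_diploid))
  invisible(x)
}

#' Fraction of reporter-positive cells from the per-copy edited fraction
#'
#' Under independent editing of the n copies within a cell, a cell lights
#' up when at least one copy is edited: \eqn{f = 1 - (1-q)^n}. Hence the
#' edited-allele fraction is generally lower than the positive-cell
#' fraction, with equality only for a single copy or q in \{0, 1\}.
#'
#' @param q Per-copy edited fraction in [0, 1].
#' @param n_copies Integer >= 1 (6 for the homozygous multi-copy
#'   reporter).
#' @return f in [0, 1].
#' @examples
#' cell_positive_fraction(0.1, 6)
#' @export
cell_positive_fraction <- function(q, n_copies) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  if (any(n_copies < 1)) stop("n_copies must be >= 1")
  -expm1(n_copies * log1p(-q))  # 1 - (1-q)^n without cancellation
}

#' Per-copy edited fraction from the positive-cell fraction
#'
#' Inverse of [cell_positive_fraction()]:
#' \eqn{q = 1 - (1-f)^{1/n}}.
#'
#' @param f Positive-cell fraction in [0, 1].
#' @param n_copies Integer >= 1.
#' @return q in [0, 1]; f = 1 returns exactly 1.
#' @export
allele_fraction_from_cells <- function(f, n_copies) {
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]")
  if (any(n_copies < 1)) stop("n_copies must be >= 1")
  ifelse(f == 1, 1, -expm1(log1p(-f) / n_copies))
}

#' Fold difference between two doses
#'
#' Doses given as vectors of vector-genome components are summed first.
#'
#' @param dose_a,dose_b Positive dose components (vector genomes).
#' @return List: \code{fold} (dose_a / dose_b), \code{fold_rounded},
#'   \code{total_a}, \code{total_b}.
#' @examples
#' dose_fold_difference(c(8e11, 1e11, 1e11), 2.7e10)
#' @export
dose_fold_difference <- function(dose_a, dose_b) {
  if (any(dose_a <= 0) || any(dose_b <= 0)) stop("doses must be positive")
  a <- sum(dose_a); b <- sum(dose_b)
  list(fold = a / b, fold_rounded = round(a / b), total_a = a, total_b = b)
}
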