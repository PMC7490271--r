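# Summary statistics of age-dependent allele replacement.  All member
# branches across all subtrees are pooled and the linear regression
#   s = a * length + b * age + c
# is fitted by OLS; (a, b) are the two ABC summary statistics.  A negative
# b indicates replacement rates falling with allele age (an entrenchment-
# like pattern), a positive b rising rates (senescence-like).

#' Pooled replacement-frequency regression
#'
#' Ordinary least squares of the per-branch loss indicator `s` on branch
#' length and allele age, with intercept.
#'
#' @param branches Data frame of pooled branch observations with columns
#'   `length`, `age`, `s` (e.g. the `branches` element of a `subtree_set`,
#'   or a matrix with these columns).
#' @return An object of class `summary_stats`: list with coefficients `a`
#'   (length), `b` (age), `c` (intercept) and `n_obs`.
#' @export
summary_regression <- function(branches) {
  branches <- as.data.frame(branches)
  stopifnot(all(c("length", "age", "s") %in% names(branches)))
  if (nrow(branches) < 3) stop("need at least 3 branch observations")
  X <- cbind(1, branches$length, branches$age)
  if (qr(X)$rank < 3)
    stop("design is rank-deficient (no variation in length or age); ",
         "pool more subtrees")
  fit <- lm.fit(X, branches$s)
  structure(list(a = unname(fit$coefficients[2]),
                 b = unname(fit$coefficients[3]),
                 c = unname(fit$coefficients[1]),
                 n_obs = nrow(branches)), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("Replacement regression (n = %d):\n  s = %.4f * length + %.4f * age + %.4f\n",
              x$n_obs, x$a, x$b, x$c))
  invisible(x)
}

as_stats_vector <- function(x) {
  if (inherits(x, "summary_stats")) c(a = x$a, b = x$b)
  else c(a = x[["a"]], b = x[["b"]])
}

#' Age-binned replacement-frequency profile
#'
#' Bins pooled branch observations into `n_bins` equal-count (quantile)
#' bins of allele age and reports the mean loss frequency per bin; the
#' weighted mean over bins equals the overall mean of `s`.
#'
#' @inheritParams summary_regression
#' @param n_bins Number of quantile bins (>= 2).
#' @return Data frame with `bin_lo`, `bin_hi`, `mean_age`, `mean_s`, `n`.
#' @export
age_profile <- function(branches, n_bins = 3) {
  branches <- as.data.frame(branches)
  stopifnot(n_bins >= 2)
  br <- quantile(branches$age, probs = seq(0, 1, length.out = n_bins + 1),
                 names = FALSE, type = 7)
  br[1] <- -Inf
  bin <- cut(branches$age, breaks = unique(c(br, Inf)), labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b,
               bin_lo = min(branches$age[sel]), bin_hi = max(branches$age[sel]),
               mean_age = mean(branches$age[sel]),
               mean_s = mean(branches$s[sel]), n = sum(sel))
  }))
  rownames(out) <- NULL
  out
}
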