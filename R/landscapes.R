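# Single-position fitness landscapes (SPFLs) and their dynamics.
#
# A landscape is a numeric vector of 20 log-fitness values, one per amino
# acid in the order of AMINO_ACIDS.  Selection coefficients are differences
# of log fitness.

#' Specify the shape family of a single-position fitness landscape
#'
#' Three families are supported: `"flat"` (all 20 alleles equally fit, every
#' substitution neutral), `"rugged"` (one allele has log fitness
#' `peak_height`, the rest 0), and `"gamma"` (the 20 log-fitness values are
#' i.i.d. draws from a gamma distribution with shape and rate both equal to
#' `alpha`, so the mean log fitness is always 1 and smaller `alpha` means a
#' more rugged landscape).
#'
#' @param shape One of `"flat"`, `"rugged"`, `"gamma"`.
#' @param peak_height Log fitness of the preferred allele (rugged only).
#' @param alpha Shared shape and rate parameter of the gamma distribution of
#'   log fitness (gamma only); must be positive.
#' @return An object of class `landscape_spec`.
#' @examples
#' draw_landscape(landscape_spec("rugged", peak_height = 10))
#' @export
landscape_spec <- function(shape = c("flat", "rugged", "gamma"),
                           peak_height = 10, alpha = 1) {
  shape <- match.arg(shape)
  if (shape == "gamma" && (!is.finite(alpha) || alpha <= 0))
    stop("alpha must be a positive number for the gamma landscape")
  structure(list(shape = shape, peak_height = peak_height, alpha = alpha),
            class = "landscape_spec")
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat("SPFL spec:", x$shape)
  if (x$shape == "rugged") cat(" (peak height ", x$peak_height, ")", sep = "")
  if (x$shape == "gamma") cat(" (alpha ", x$alpha, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Specify how a fitness landscape changes over time
#'
#' `"static"`: the landscape never changes.  `"random"`: the landscape is hit
#' by a Poisson process of rate `lambda` (events per dS); at each event the
#' log-fitness values are reshuffled between alleles (flat/rugged family) or
#' redrawn from the same gamma distribution.  `"allele_linear"`: the log
#' fitness of the resident allele changes linearly at rate `k` per dS,
#' applied in discrete steps of `dt`; positive `k` is entrenchment, negative
#' `k` senescence.  When a substitution occurs the replaced allele's fitness
#' freezes and the new resident starts to change at rate `k`.
#'
#' @param mode One of `"static"`, `"random"`, `"allele_linear"`.
#' @param lambda Poisson rate of landscape changes per dS (random mode).
#' @param k Rate of change of the resident allele's log fitness per dS.
#' @param dt Discretization step in dS for the linear drift (default 0.01).
#' @return An object of class `change_process`.
#' @export
change_process <- function(mode = c("static", "random", "allele_linear"),
                           lambda = 0, k = 0, dt = 0.01) {
  mode <- match.arg(mode)
  if (lambda < 0) stop("lambda must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (mode == "static" && (lambda != 0 || k != 0))
    stop("static mode requires lambda = 0 and k = 0")
  structure(list(mode = mode, lambda = lambda, k = k, dt = dt),
            class = "change_process")
}

#' @export
print.change_process <- function(x, ...) {
  cat("SPFL change process:", x$mode)
  if (x$mode == "random") cat(" (lambda ", x$lambda, " per dS)", sep = "")
  if (x$mode == "allele_linear")
    cat(" (k ", x$k, " per dS, dt ", x$dt, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Draw a fitness landscape from a shape family
#'
#' @param spec A [landscape_spec()].
#' @return A named numeric vector of 20 log-fitness values.
#' @export
draw_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  logf <- switch(spec$shape,
    flat = rep(0, 20),
    rugged = {
      v <- rep(0, 20)
      v[sample.int(20, 1)] <- spec$peak_height
      v
    },
    gamma = rgamma(20, shape = spec$alpha, rate = spec$alpha))
  names(logf) <- AMINO_ACIDS
  logf
}

#' Apply one random landscape-change event
#'
#' Flat and rugged landscapes are reshuffled (a uniformly random permutation
#' of the current values); gamma landscapes are redrawn i.i.d. from the same
#' distribution.  The input vector is not modified.
#'
#' @param logf Current log-fitness vector (length 20).
#' @param spec A [landscape_spec()].
#' @return A new log-fitness vector.
#' @export
change_landscape <- function(logf, spec) {
  stopifnot(inherits(spec, "landscape_spec"), length(logf) == 20)
  out <- if (spec$shape == "gamma")
    rgamma(20, shape = spec$alpha, rate = spec$alpha)
  else
    logf[sample.int(20)]
  names(out) <- AMINO_ACIDS
  out
}

#' Apply one step of linear fitness drift to the resident allele
#'
#' Increments the resident allele's log fitness by `k * dt` and leaves all
#' other values unchanged.
#'
#' @param logf Log-fitness vector (length 20).
#' @param resident One-letter amino acid code or index of the resident allele.
#' @param k Drift rate per dS.
#' @param dt Time step in dS.
#' @return The updated log-fitness vector.
#' @export
apply_drift <- function(logf, resident, k, dt) {
  stopifnot(length(logf) == 20)
  i <- if (is.character(resident)) aa_index(resident) else as.integer(resident)
  stopifnot(i >= 1, i <= 20)
  logf[i] <- logf[i] + k * dt
  logf
}
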