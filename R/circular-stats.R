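## Circular descriptive statistics and the von Mises likelihood-ratio
## circular analysis of variance used to compare track-orientation
## distributions between genotypes.

KAPPA_MAX <- 1e4

#' Ratio of modified Bessel functions A(kappa) = I1(kappa)/I0(kappa)
#'
#' Links the von Mises concentration kappa to the expected mean resultant
#' length. Computed with exponent-scaled Bessel functions so that large
#' kappa does not overflow.
#'
#' @param kappa Non-negative numeric vector.
#' @return A(kappa) in \[0, 1).
#' @export
bessel_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
}

## log I0(kappa), overflow-safe
log_bessel_i0 <- function(kappa) {
  kappa + log(besselI(kappa, 0, expon.scaled = TRUE))
}

#' Invert A(kappa) = rbar for the von Mises concentration
#'
#' Bracketed root-finding on \[0, 1e4\]; closed-form approximations are not
#' used as the answer. `rbar` values beyond `A(1e4)` (numerically
#' degenerate concentration) are capped at kappa = 1e4 with a warning.
#'
#' @param rbar Mean resultant length in \[0, 1\].
#' @param tol Root tolerance passed to [stats::uniroot()].
#' @return Estimated kappa >= 0.
#' @export
kappa_from_rbar <- function(rbar, tol = 1e-12) {
  if (rbar < 0 || rbar > 1) stop("'rbar' must be in [0, 1]")
  if (rbar < 1e-12) return(0)
  if (rbar >= bessel_ratio(KAPPA_MAX)) {
    warning("rbar = ", format(rbar),
            " implies a degenerate concentration; kappa capped at ", KAPPA_MAX)
    return(KAPPA_MAX)
  }
  stats::uniroot(function(k) bessel_ratio(k) - rbar,
                 lower = 1e-12, upper = KAPPA_MAX, tol = tol)$root
}

#' Wrap angles to (-pi, pi]
#' @param theta Numeric vector of angles in radians.
#' @return Angles wrapped into (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Angles with group labels
#'
#' The substrate of rose plots and the circular ANOVA: track-orientation
#' angles in radians within (-pi, pi] with a parallel group label (e.g.
#' genotype).
#'
#' @param angles Numeric vector of radians in (-pi, pi]. Values outside
#'   the range are an error, never silently wrapped; use [wrap_angle()]
#'   first if needed.
#' @param groups Parallel vector of group labels.
#' @return An object of class `circular_sample`.
#' @export
circular_sample <- function(angles, groups) {
  angles <- as.numeric(angles)
  if (anyNA(angles)) stop("angles must be finite (drop undefined angles first)")
  if (any(angles <= -pi - 1e-12 | angles > pi + 1e-12))
    stop("angles must lie in (-pi, pi]")
  groups <- as.character(groups)
  if (length(groups) != length(angles))
    stop("'groups' must be parallel to 'angles'")
  structure(list(angles = angles, groups = groups),
            class = "circular_sample")
}

#' Fit a von Mises distribution by maximum likelihood
#'
#' The mean direction mu is the direction of the resultant vector; the
#' concentration kappa solves A(kappa) = rbar by bracketed root-finding,
#' where rbar is the mean resultant length.
#'
#' @param angles Numeric vector of radians (n >= 2).
#' @return An object of class `von_mises`: list with `mu` (radians),
#'   `kappa`, `rbar`, `n` and `loglik`.
#' @export
fit_von_mises <- function(angles) {
  angles <- as.numeric(angles)
  n <- length(angles)
  if (n < 2L) stop("need at least 2 angles to fit a von Mises distribution")
  C <- sum(cos(angles)); S <- sum(sin(angles))
  R <- sqrt(C^2 + S^2)
  rbar <- R / n
  mu <- if (R < 1e-12) 0 else atan2(S, C)
  kappa <- kappa_from_rbar(rbar)
  loglik <- kappa * sum(cos(angles - mu)) - n * (log(2 * pi) + log_bessel_i0(kappa))
  structure(list(mu = mu, kappa = kappa, rbar = rbar, n = n, loglik = loglik),
            class = "von_mises")
}

#' @export
print.von_mises <- function(x, ...) {
  cat(sprintf("von Mises fit: mu = %.4f rad (%.1f deg), kappa = %.4g, rbar = %.4f, n = %d, logLik = %.3f\n",
              x$mu, x$mu * 180 / pi, x$kappa, x$rbar, x$n, x$loglik))
  invisible(x)
}

#' Likelihood-ratio circular analysis of variance
#'
#' Tests equality of mean directions across groups under a von Mises
#' working model with a common concentration (the classical mean-direction
#' likelihood-ratio ANOVA). Under H0 all groups share one mean direction
#' and kappa is estimated from the pooled resultant; under H1 each group
#' has its own mean direction and the shared kappa is estimated from the
#' sum of within-group resultant lengths. The statistic is twice the
#' log-likelihood-ratio, floored at zero, referred to a chi-squared
#' distribution with (number of groups - 1) degrees of freedom.
#'
#' @param sample A [circular_sample()] with >= 2 groups, each of size >= 2.
#' @return An object of class `circ_anova`: `statistic`, `df`, `p_value`,
#'   `group_fits` (per-group [fit_von_mises()] results), `pooled_fit`, and
#'   `kappa_model = "common kappa, re-estimated under H0 and H1"`.
#' @export
circ_anova_lrt <- function(sample) {
  stopifnot(inherits(sample, "circular_sample"))
  by_group <- split(sample$angles, sample$groups)
  if (length(by_group) < 2L) stop("circular ANOVA needs at least 2 groups")
  small <- names(by_group)[lengths(by_group) < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 angles: ", paste(small, collapse = ", "))
  n <- length(sample$angles)
  resultant <- function(a) {
    C <- sum(cos(a)); S <- sum(sin(a)); sqrt(C^2 + S^2)
  }
  R_pooled <- resultant(sample$angles)
  R_within <- sum(vapply(by_group, resultant, 0))
  degenerate <- FALSE
  withCallingHandlers({
    kappa0 <- kappa_from_rbar(R_pooled / n)
    kappa1 <- kappa_from_rbar(R_within / n)
  }, warning = function(w) {
    degenerate <<- TRUE
    invokeRestart("muffleWarning")
  })
  ll0 <- kappa0 * R_pooled - n * (log(2 * pi) + log_bessel_i0(kappa0))
  ll1 <- kappa1 * R_within - n * (log(2 * pi) + log_bessel_i0(kappa1))
  stat <- max(0, 2 * (ll1 - ll0))
  if (degenerate) {
    warning("degenerate (fully concentrated) angles; statistic set by the ",
            "capped-kappa likelihoods")
    if (abs(R_within - R_pooled) < 1e-9 * n) stat <- 0
  }
  df <- length(by_group) - 1L
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  group_fits <- suppressWarnings(lapply(by_group, fit_von_mises))
  pooled_fit <- suppressWarnings(fit_von_mises(sample$angles))
  structure(list(statistic = stat, df = df, p_value = p,
                 group_fits = group_fits, pooled_fit = pooled_fit,
                 kappa_shared = kappa1, n = n,
                 kappa_model = "common kappa, re-estimated under H0 and H1"),
            class = "circ_anova")
}

#' @export
print.circ_anova <- function(x, ...) {
  cat("\tCircular analysis of variance (von Mises likelihood-ratio test)\n\n")
  cat(sprintf("LRT statistic = %.4f, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  mus <- vapply(x$group_fits, `[[`, 0, "mu") * 180 / pi
  ns <- vapply(x$group_fits, `[[`, 0L, "n")
  cat("group mean directions (deg):",
      paste(sprintf("%s = %.1f (n=%d)", names(mus), mus, ns), collapse = ", "),
      "\n")
  cat(sprintf("shared kappa = %.4g   [%s]\n", x$kappa_shared, x$kappa_model))
  invisible(x)
}

#' Directional histogram for rose plots
#'
#' Equal-width bins partitioning (-pi, pi], right-closed: an angle exactly
#' at a bin edge belongs to the bin whose right edge it is.
#'
#' @param angles Numeric vector of radians in (-pi, pi] (may be empty).
#' @param n_bins Number of bins (>= 2).
#' @return An object of class `rose_histogram`: data frame with
#'   `bin_start`, `bin_end` (radians) and `count`.
#' @export
rose_histogram <- function(angles, n_bins) {
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  edges <- seq(-pi, pi, length.out = n_bins + 1L)
  counts <- integer(n_bins)
  if (length(angles)) {
    angles <- as.numeric(angles)
    if (any(angles <= -pi - 1e-12 | angles > pi + 1e-12))
      stop("angles must lie in (-pi, pi]")
    ## right-closed bins (edges[i], edges[i+1]]
    bin <- ceiling((angles - (-pi)) / (2 * pi / n_bins))
    bin[bin < 1L] <- 1L
    bin[bin > n_bins] <- n_bins
    ## snap angles sitting exactly on an edge to the bin they right-close
    on_edge <- which(abs(angles - edges[bin]) < 1e-12)
    bin[on_edge] <- pmax(1L, bin[on_edge] - 1L)
    tb <- tabulate(bin, nbins = n_bins)
    counts <- tb
  }
  structure(data.frame(bin_start = edges[-(n_bins + 1L)],
                       bin_end = edges[-1L], count = counts),
            class = c("rose_histogram", "data.frame"))
}

#' Draw random angles from a von Mises distribution
#'
#' Best–Fisher rejection sampler; kappa = 0 returns uniform angles.
#' Uses the current RNG state (seed with [set.seed()]).
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration (>= 0).
#' @return Numeric vector of angles in (-pi, pi].
#' @export
r_von_mises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("'kappa' must be >= 0")
  if (kappa == 0) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      theta <- sign(u3 - 0.5) * acos(f)
      out[i] <- theta + mu
      i <- i + 1L
    }
  }
  wrap_angle(out)
}
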