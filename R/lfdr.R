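# Local false discovery rate over a z-score ensemble, following Efron's
# empirical-null recipe: the marginal density f is a Poisson regression of
# binned counts on a polynomial basis; the null f0 is a normal fitted by
# maximum likelihood to the central portion of the scores (where passengers
# dominate); lfdr(z) = min(1, pi0 * f0(z) / f(z)).

#' Fit the local false discovery rate over a score ensemble
#'
#' The marginal log-density is fitted by Poisson regression of histogram
#' counts (120 equal-width bins spanning the score range) on a degree-7
#' orthogonal polynomial of the bin centers.  The empirical null N(mean, sd)
#' and the null proportion pi0 (capped at 1) are estimated by truncated-normal
#' maximum likelihood on the central 50% of the scores.  With fewer than
#' `min_regions` scores the empirical null is unstable, so the theoretical
#' N(0, 1) null with pi0 = 1 is used instead (with a warning).  lfdr values
#' are clipped to [0, 1].
#'
#' @param z Numeric vector of finite scores (at least two distinct values).
#' @param min_regions Minimum ensemble size for empirical-null estimation
#'   (default 200).
#' @param n_bins Number of histogram bins (default 120).
#' @param df Polynomial degree for the log-density fit (default 7).
#' @param central Fraction of central scores used for the null fit
#'   (default 0.5).
#' @return An `lfdr_fit` object: list with `z`, `lfdr` (parallel to `z`),
#'   `bins` (tibble `center`, `count`, `fitted`), `null_mean`, `null_sd`,
#'   `pi0`, `null_type` (`"empirical"` or `"theoretical"`), `n`,
#'   `bin_width`.
#' @export
fit_local_fdr <- function(z, min_regions = 200, n_bins = 120, df = 7,
                          central = 0.5) {
  if (!all(is.finite(z))) stop("z scores must be finite", call. = FALSE)
  n <- length(z)
  if (n < 2 || diff(range(z)) < sqrt(.Machine$double.eps)) {
    stop("degenerate z ensemble: need at least two distinct scores",
         call. = FALSE)
  }
  breaks <- seq(min(z), max(z), length.out = n_bins + 1)
  h <- graphics::hist(z, breaks = breaks, plot = FALSE)
  dat <- data.frame(count = h$counts, center = h$mids)
  w <- breaks[2] - breaks[1]
  dfit <- suppressWarnings(
    glm(count ~ poly(center, degree = df), data = dat, family = poisson())
  )
  f_at <- function(x) {
    mu <- suppressWarnings(predict(dfit, newdata = data.frame(center = x),
                                   type = "response"))
    pmax(mu / (n * w), .Machine$double.xmin)
  }
  if (n >= min_regions) {
    null <- fit_empirical_null(z, central = central)
  } else {
    warning("fewer than ", min_regions,
            " scores: using theoretical N(0,1) null", call. = FALSE)
    null <- list(mean = 0, sd = 1, pi0 = 1, type = "theoretical")
  }
  f <- f_at(z)
  f0 <- dnorm(z, null$mean, null$sd)
  lfdr <- pmin(1, pmax(0, null$pi0 * f0 / f))
  structure(
    list(z = z, lfdr = lfdr,
         bins = tibble::tibble(center = dat$center, count = dat$count,
                               fitted = unname(predict(dfit, type = "response"))),
         null_mean = null$mean, null_sd = null$sd, pi0 = null$pi0,
         null_type = null$type, n = n, bin_width = w),
    class = "lfdr_fit"
  )
}

# truncated-normal ML on the central quantile band; falls back to the
# theoretical null when the optimizer degenerates
fit_empirical_null <- function(z, central = 0.5) {
  lo <- unname(quantile(z, (1 - central) / 2))
  hi <- unname(quantile(z, 1 - (1 - central) / 2))
  zc <- z[z >= lo & z <= hi]
  fallback <- list(mean = 0, sd = 1, pi0 = 1, type = "theoretical")
  if (length(zc) < 10 || sd(zc) == 0 || hi <= lo) {
    warning("central band degenerate: using theoretical N(0,1) null",
            call. = FALSE)
    return(fallback)
  }
  nll <- function(par) {
    m <- par[1]; s <- exp(par[2])
    mass <- pnorm(hi, m, s) - pnorm(lo, m, s)
    if (!is.finite(mass) || mass <= 0) return(1e10)
    -sum(dnorm(zc, m, s, log = TRUE)) + length(zc) * log(mass)
  }
  opt <- tryCatch(
    optim(c(mean(zc), log(sd(zc))), nll),
    error = function(e) NULL
  )
  if (is.null(opt) || opt$convergence != 0 || !all(is.finite(opt$par))) {
    warning("empirical-null fit failed: using theoretical N(0,1) null",
            call. = FALSE)
    return(fallback)
  }
  m <- opt$par[1]; s <- exp(opt$par[2])
  mass <- pnorm(hi, m, s) - pnorm(lo, m, s)
  pi0 <- min(1, (length(zc) / length(z)) / mass)
  list(mean = m, sd = s, pi0 = pi0, type = "empirical")
}

#' @export
print.lfdr_fit <- function(x, ...) {
  cat("<lfdr_fit> n = ", x$n, ", ", x$null_type, " null N(",
      signif(x$null_mean, 3), ", ", signif(x$null_sd, 3), "^2), pi0 = ",
      signif(x$pi0, 3), "\n", sep = "")
  invisible(x)
}

#' Export lfdr diagnostics (binned counts and fitted curve) as TSV
#'
#' @param fit An `lfdr_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lfdr_diagnostics <- function(fit, path) {
  stopifnot(inherits(fit, "lfdr_fit"))
  readr::write_tsv(fit$bins, path)
  invisible(path)
}
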