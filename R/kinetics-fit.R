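#' @include AllClasses.R
NULL

#' Average a transient spectrum over the surrounding delay points
#'
#' Reconstructs the difference absorption spectrum at delay \code{t} as the
#' unweighted mean of the 10 delay columns surrounding the nearest grid
#' point (5 before, 5 after, the centre column excluded), the averaging
#' used when assembling spectra from kinetic traces.
#'
#' @param ts a [SpectralTimeSeries-class]
#' @param t delay, seconds; must have at least 5 grid points on each side
#' @return named numeric vector over wavelengths (delta-A units)
#' @export
averageWindow <- function(ts, t) {
  stopifnot(is(ts, "SpectralTimeSeries"))
  d <- ts@delays
  i <- which.min(abs(d - t))
  nBefore <- i - 1L
  nAfter <- length(d) - i
  if (nBefore < 5L || nAfter < 5L)
    stop(sprintf(
      "t = %g s too close to the grid edge: %d point(s) before and %d after the nearest delay; 5 required on each side",
      t, nBefore, nAfter))
  cols <- setdiff((i - 5L):(i + 5L), i)
  out <- rowMeans(ts@deltaA[, cols, drop = FALSE])
  names(out) <- ts@wavelengths
  out
}

# Variable projection: for trial taus, solve the per-wavelength linear DAS
# subproblem in closed form and return the projected residual matrix.
varproParts <- function(Y, delays, taus) {
  E <- exp(outer(delays, -1 / taus))              # n_t x k
  EtE <- crossprod(E)
  B <- Y %*% E                                    # n_wl x k
  D <- t(solve(EtE, t(B)))                        # DAS, n_wl x k
  list(E = E, das = D, resid = Y - D %*% t(E))
}

defaultTauStarts <- function(delays, k, nStarts) {
  lo <- log10(min(delays)); hi <- log10(max(delays))
  base <- seq(lo, hi, length.out = k + 2)[2:(k + 1)]
  lapply(seq_len(nStarts), function(j) {
    10^(base + (j - (nStarts + 1) / 2) * 0.2)
  })
}

#' Global multi-exponential fit with decay-associated spectra
#'
#' Fits \eqn{\Delta A(\lambda,t) = \sum_i DAS_i(\lambda) e^{-t/\tau_i}}
#' to all kinetic traces simultaneously by variable projection: for trial
#' time constants the per-wavelength amplitudes (DAS) are solved in closed
#' form by linear least squares, and the time constants are refined with
#' the Levenberg-Marquardt minimizer ([minpack.lm::nls.lm()]) on the
#' projected residual, in log-tau coordinates. Unless initial values are
#' supplied, a multi-start over log-spaced tau grids spanning the delay
#' range is performed and the best chi-square kept. Standard errors come
#' from the curvature matrix of the projected functional at the optimum.
#'
#' @param ts a [SpectralTimeSeries-class]
#' @param nComponents number of exponential components (>= 1)
#' @param initTaus optional sorted initial time constants (s); suppresses
#'   the multi-start
#' @param bounds optional 2-vector or 2-column matrix of per-component
#'   (lower, upper) tau bounds (s)
#' @param nStarts number of multi-start grids (default 8)
#' @param maxIter Levenberg-Marquardt iteration cap (default 500)
#' @param ftol relative chi-square convergence tolerance (default 1e-10)
#' @return a [GlobalFitResult-class], components sorted by ascending tau.
#'   Non-convergence is flagged in \code{converged}, never silent; taus
#'   closer than a ratio of 1.05 raise a warning and set
#'   \code{degenerate}.
#' @examples
#' grid <- defaultAcquisitionGrid(thin = 200)
#' ts <- simulateTransientSpectra(buildReferenceScheme("H2O"), grid,
#'                                sigma = 0)
#' fitGlobal(ts, 3)
#' @export
fitGlobal <- function(ts, nComponents, initTaus = NULL, bounds = NULL,
                      nStarts = 8L, maxIter = 500L, ftol = 1e-10) {
  stopifnot(is(ts, "SpectralTimeSeries"), nComponents >= 1)
  Y <- ts@deltaA
  delays <- ts@delays
  if (length(delays) < nComponents + 1)
    stop("need at least nComponents + 1 delay points")
  if (is.null(bounds)) {
    bounds <- cbind(rep(min(delays) / 100, nComponents),
                    rep(max(delays) * 100, nComponents))
  } else if (is.null(dim(bounds))) {
    bounds <- matrix(bounds, nComponents, 2, byrow = TRUE)
  }
  starts <- if (is.null(initTaus)) {
    defaultTauStarts(delays, nComponents, nStarts)
  } else {
    stopifnot(length(initTaus) == nComponents, !is.unsorted(initTaus))
    if (any(initTaus < bounds[, 1]) || any(initTaus > bounds[, 2]))
      stop("initTaus must lie inside bounds")
    list(initTaus)
  }
  residFun <- function(logTau) {
    as.vector(varproParts(Y, delays, exp(logTau))$resid)
  }
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, bounds[, 1]), bounds[, 2])
    fit <- try(minpack.lm::nls.lm(
      par = log(st), fn = residFun,
      lower = log(bounds[, 1]), upper = log(bounds[, 2]),
      control = minpack.lm::nls.lm.control(
        maxiter = as.integer(maxIter), ftol = ftol, ptol = 1e-12)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all optimizer starts failed")
  tau <- exp(best$par)
  ord <- order(tau)
  tau <- tau[ord]
  parts <- varproParts(Y, delays, tau)
  # curvature-matrix stderr of the projected functional, delta method from
  # log-tau; dof counts the eliminated linear DAS parameters too
  dof <- length(Y) - nComponents * (1 + nrow(Y))
  s2 <- best$deviance / max(dof, 1)
  covLog <- try(solve(best$hessian), silent = TRUE)
  stderr <- if (inherits(covLog, "try-error")) {
    rep(NA_real_, nComponents)
  } else {
    (sqrt(pmax(diag(covLog), 0)) * exp(best$par) * sqrt(s2))[ord]
  }
  degenerate <- nComponents > 1 &&
    any(tau[-1] / tau[-nComponents] < 1.05)
  if (degenerate)
    warning("degenerate time constants: adjacent tau ratio < 1.05")
  isConv <- best$info %in% 1:4
  if (!isConv)
    warning("global fit did not converge: ", best$message)
  new("GlobalFitResult", taus = tau, tauStderr = stderr,
      das = parts$das, residuals = parts$resid,
      chi2 = sum(parts$resid^2), converged = isConv,
      nIterations = as.integer(best$niter),
      wavelengths = ts@wavelengths, delays = delays,
      degenerate = degenerate, message = best$message)
}

#' Model reconstruction from a global fit
#'
#' @param fit a [GlobalFitResult-class]
#' @return matrix of fitted values, wavelengths by delays
#' @export
reconstruct <- function(fit) {
  stopifnot(is(fit, "GlobalFitResult"))
  fit@das %*% t(exp(outer(fit@delays, -1 / fit@taus)))
}

#' Residual-structure diagnostics of a global fit
#'
#' Per-wavelength lag-1 autocorrelation and Wald-Wolfowitz runs-test z
#' statistics of the residual traces. Values only, no verdict: structure
#' in the residuals (large |lag-1| or |z|) indicates model misfit.
#' All-zero residual traces are reported as NA and flagged.
#'
#' @param fit a converged [GlobalFitResult-class]
#' @return data.frame with columns \code{wavelength}, \code{lag1},
#'   \code{runsZ}, \code{degenerate}
#' @export
residualDiagnostics <- function(fit) {
  stopifnot(is(fit, "GlobalFitResult"))
  if (!fit@converged) stop("fit did not converge")
  res <- fit@residuals
  out <- t(apply(res, 1, function(e) {
    n <- length(e)
    if (all(e == 0)) return(c(NA_real_, NA_real_, 1))
    lag1 <- sum(e[-n] * e[-1]) / sum(e^2)
    sgn <- sign(e - stats::median(e))
    sgn <- sgn[sgn != 0]
    np <- sum(sgn > 0); nm <- sum(sgn < 0); nn <- np + nm
    if (np == 0 || nm == 0) return(c(lag1, NA_real_, 1))
    runs <- 1 + sum(diff(sgn) != 0)
    mu <- 2 * np * nm / nn + 1
    sd <- sqrt(2 * np * nm * (2 * np * nm - nn) / (nn^2 * (nn - 1)))
    c(lag1, (runs - mu) / sd, 0)
  }))
  data.frame(wavelength = fit@wavelengths, lag1 = out[, 1],
             runsZ = out[, 2], degenerate = out[, 3] == 1)
}

#' Residual-shuffling bootstrap of a global fit
#'
#' Builds replicate datasets as best-fit reconstruction plus a residual
#' matrix in which a uniformly chosen fraction of the entries has been
#' permuted among themselves (values conserved, remainder untouched), and
#' refits the model to each replicate starting from the best-fit time
#' constants. With \code{resample = TRUE} the selected entries are instead
#' drawn with replacement from the whole residual pool.
#'
#' @param ts the fitted [SpectralTimeSeries-class]
#' @param best a converged [GlobalFitResult-class] for \code{ts}
#' @param nReplicates number of replicates (default 1000)
#' @param shuffleFraction fraction of residual entries shuffled
#'   (default 0.25)
#' @param seed integer seed; the whole bootstrap is reproducible under it
#' @param resample logical, use resampling-with-replacement instead of
#'   permutation for the selected entries (default FALSE)
#' @return a [BootstrapResult-class]; replicates whose refit does not
#'   converge are excluded and counted in \code{nFailed}
#' @export
bootstrapFit <- function(ts, best, nReplicates = 1000L,
                         shuffleFraction = 0.25, seed = 1L,
                         resample = FALSE) {
  stopifnot(is(ts, "SpectralTimeSeries"), is(best, "GlobalFitResult"))
  if (!best@converged) stop("best fit did not converge")
  if (shuffleFraction < 0 || shuffleFraction > 1)
    stop("shuffleFraction must lie in [0,1]")
  recon <- reconstruct(best)
  res <- as.vector(best@residuals)
  nCells <- length(res)
  nShuffle <- round(shuffleFraction * nCells)
  k <- length(best@taus)
  set.seed(as.integer(seed))
  repTaus <- matrix(NA_real_, nReplicates, k)
  nFailed <- 0L
  for (r in seq_len(nReplicates)) {
    resB <- res
    if (nShuffle > 0) {
      idx <- sample.int(nCells, nShuffle)
      resB[idx] <- if (resample) res[sample.int(nCells, nShuffle,
                                                replace = TRUE)]
                   else res[idx][sample.int(nShuffle)]
    }
    tsB <- new("SpectralTimeSeries", wavelengths = ts@wavelengths,
               delays = ts@delays,
               deltaA = recon + matrix(resB, nrow = nrow(recon)),
               condition = ts@condition)
    fitB <- try(suppressWarnings(
      fitGlobal(tsB, k, initTaus = best@taus)), silent = TRUE)
    if (inherits(fitB, "try-error") || !fitB@converged) {
      nFailed <- nFailed + 1L
    } else {
      repTaus[r, ] <- fitB@taus
    }
  }
  ok <- stats::complete.cases(repTaus)
  kept <- repTaus[ok, , drop = FALSE]
  if (!nrow(kept)) stop("no bootstrap replicate converged")
  # sd undefined for a single surviving replicate
  sds <- if (nrow(kept) > 1L) apply(kept, 2, stats::sd)
         else rep(NA_real_, k)
  new("BootstrapResult", replicateTaus = kept,
      means = colMeans(kept), sds = sds,
      shuffleFraction = shuffleFraction,
      nReplicates = as.integer(nReplicates), nFailed = nFailed,
      seed = as.integer(seed))
}

#' Kinetic isotope effect from two matched global fits
#'
#' Matches components by ascending-tau rank and reports
#' \eqn{\tau_{D,i}/\tau_{H,i}}, which equals the kinetic isotope effect
#' \eqn{k_H/k_D} since \eqn{k = 1/\tau}. Ratios are displayed at 3
#' significant digits.
#'
#' @param fitH,fitD converged [GlobalFitResult-class] objects (or bare
#'   numeric tau vectors in seconds) for the H2O and D2O conditions
#' @return an [IsotopeComparison-class]
#' @examples
#' ratios(isotopeRatios(c(5.57, 36.1, 824.8) * 1e-6,
#'                      c(5.16, 88.4, 2041.1) * 1e-6))
#' @export
isotopeRatios <- function(fitH, fitD) {
  getTaus <- function(f, nm) {
    if (is(f, "GlobalFitResult")) {
      if (!f@converged) stop(nm, " fit did not converge")
      f@taus
    } else if (is.numeric(f) && all(f > 0)) {
      sort(f)
    } else stop(nm, " must be a GlobalFitResult or positive numeric taus")
  }
  tH <- getTaus(fitH, "fitH")
  tD <- getTaus(fitD, "fitD")
  if (length(tH) != length(tD))
    stop("component counts differ: ", length(tH), " vs ", length(tD))
  new("IsotopeComparison", ratios = tD / tH, tausH = tH, tausD = tD)
}
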