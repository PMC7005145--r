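#' @include AllClasses.R structure-factors.R
NULL

# Align two reflection sets on hkl; error when the sets differ.
alignReflections <- function(a, b, what = c("on", "off")) {
  ra <- a@records; rb <- b@records
  key <- function(r) paste(r$h, r$k, r$l)
  m <- match(key(ra), key(rb))
  if (anyNA(m) || nrow(ra) != nrow(rb))
    stop("reflection sets '", what[1], "' and '", what[2],
         "' do not share the same hkl set")
  rb <- rb[m, , drop = FALSE]
  list(a = ra, b = rb)
}

#' Bayesian q-weights for difference structure-factor amplitudes
#'
#' Per-reflection shrinkage weights that damp difference amplitudes whose
#' uncertainty is large compared to the difference signal. In resolution
#' bins (equal-count, on 1/d), the signal variance is estimated as
#' \eqn{V_s = \max(0, \langle\Delta F^2\rangle -
#' \langle\sigma^2_{\Delta F}\rangle)} with
#' \eqn{\sigma^2_{\Delta F} = \sigma^2_{on} + \sigma^2_{off}}, and each
#' reflection receives \eqn{q_h = V_s / (V_s + \sigma^2_{\Delta F,h})},
#' floored at \code{floor}. This is a binned shrinkage estimator standing
#' in for the cited q-weighting scheme, whose exact formula the source
#' does not reproduce. Reflections with zero sigma get weight 1 (noiseless
#' limit).
#'
#' @param on,off matched [ReflectionSet-class] objects with sigmas
#' @param nBins number of resolution bins (default 10; reduced when fewer
#'   reflections are available, so no bin is empty)
#' @param floor lower clamp for the weights (default 0.01)
#' @return a [QWeightSet-class] aligned with the records of \code{on}
#' @export
qWeights <- function(on, off, nBins = 10L, floor = 0.01) {
  al <- alignReflections(on, off)
  if (anyNA(al$a$sigma) || anyNA(al$b$sigma))
    stop("q-weighting requires sigmas on both reflection sets")
  dF <- al$a$amp - al$b$amp
  s2 <- al$a$sigma^2 + al$b$sigma^2
  geom <- cellGeometry(on@cell)
  invd <- invResolution(as.matrix(al$a[, c("h", "k", "l")]), geom)
  n <- length(dF)
  nBins <- max(1L, min(as.integer(nBins), n))
  breaks <- unique(stats::quantile(invd, probs = seq(0, 1,
                                                     length.out = nBins + 1)))
  bin <- cut(invd, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  q <- numeric(n)
  for (b in unique(bin)) {
    i <- bin == b
    vs <- max(0, mean(dF[i]^2) - mean(s2[i]))
    q[i] <- ifelse(s2[i] == 0, 1, pmax(floor, vs / (vs + s2[i])))
  }
  new("QWeightSet", q = q, qMean = mean(q))
}

unitWeights <- function(n) new("QWeightSet", q = rep(1, n), qMean = 1)

# FFT grid divisions: odd enough to hold the hemisphere (>= 2*hmax + 1)
# and fine enough for dmin/3 spacing, rounded up to an FFT-friendly size.
defaultGridDivisions <- function(cell, dmin) {
  hmax <- ceiling(cell[1:3] / dmin)
  vapply(seq_len(3), function(i) {
    stats::nextn(max(2L * hmax[i] + 1L, ceiling(3 * cell[i] / dmin)),
                 factors = c(2, 3, 5))
  }, integer(1))
}

# Fourier synthesis of a real P1 map from hemisphere coefficients:
# rho(x) = (1/V) sum_h c_h exp(-2 pi i h.x), Friedel completion enforced.
synthesizeMap <- function(cell, hkl, coeff, grid) {
  stopifnot(all(grid >= 2 * apply(abs(hkl), 2, max) + 1))
  C <- array(0 + 0i, dim = grid)
  idx <- function(m) cbind(m[, 1] %% grid[1], m[, 2] %% grid[2],
                           m[, 3] %% grid[3]) + 1L
  C[idx(hkl)] <- coeff
  C[idx(-hkl)] <- Conj(coeff)
  vol <- cellGeometry(cell)$volume
  Re(stats::fft(C)) / vol
}

#' q-weighted difference Fourier map
#'
#' Synthesizes the difference electron-density map with coefficients
#' \eqn{(q_h/\langle q\rangle)\,(F_{on,h} - F_{off,h})\,
#' e^{i\varphi_{calc,h}}}, phases taken from a reference (laser_off)
#' structure, with Friedel completion so the map is real. The map is
#' returned in sigma units (values divided by the grid rms).
#'
#' @param on,off matched observed [ReflectionSet-class] amplitude sets
#' @param phases [ReflectionSet-class] carrying calculated phases for the
#'   same hkl (e.g. from [structureFactors()] of the off model)
#' @param weights a [QWeightSet-class] aligned with \code{on} (defaults to
#'   [qWeights()] of the pair); pass \code{NULL} explicitly for unweighted
#'   synthesis
#' @param grid integer grid divisions per axis (default from the cell and
#'   \code{dmin}: spacing at most dmin/3)
#' @return a [DensityMap-class]
#' @export
differenceMap <- function(on, off, phases, weights = qWeights(on, off),
                          grid = defaultGridDivisions(on@cell, on@dmin)) {
  al <- alignReflections(on, off)
  ph <- alignReflections(on, phases, c("on", "phases"))$b
  if (anyNA(ph$phase))
    stop("phase missing for one or more reflections")
  if (is.null(weights)) weights <- unitWeights(nrow(al$a))
  if (length(weights@q) != nrow(al$a))
    stop("weights length does not match reflection count")
  dF <- (weights@q / weights@qMean) * (al$a$amp - al$b$amp)
  coeff <- dF * exp(1i * ph$phase * pi / 180)
  rho <- synthesizeMap(on@cell, as.matrix(al$a[, c("h", "k", "l")]),
                       coeff, as.integer(grid))
  rms <- sqrt(mean(rho^2))
  new("DensityMap", cell = on@cell,
      values = if (rms > 0) rho / rms else rho, rms = rms)
}

#' Integrate density peaks around sites
#'
#' Sums \code{|value|} over all grid points lying within \code{radius} of
#' any site (minimum-image distance in the periodic cell) where
#' \code{|value| >= threshold} sigma. Matches the contour-level logic of
#' difference-map inspection: only density beyond the display contour
#' counts.
#'
#' @param map a [DensityMap-class] (values in sigma units)
#' @param sites matrix (or list of vectors) of fractional coordinates
#' @param radius integration radius, Angstrom (default 2.0)
#' @param threshold sigma cutoff (default 3, the usual contour level)
#' @param mask optional precomputed logical selection array (grid-sized);
#'   when given, \code{sites} and \code{radius} are ignored
#' @return numeric, the integrated absolute density (0 when nothing
#'   survives the cutoff)
#' @export
integratePeaks <- function(map, sites, radius = 2.0, threshold = 3,
                           mask = NULL) {
  stopifnot(is(map, "DensityMap"), radius > 0)
  if (is.null(mask)) {
    if (is.list(sites)) sites <- do.call(rbind, sites)
    sites <- matrix(sites, ncol = 3)
    if (!nrow(sites)) stop("sites must be non-empty")
    mask <- siteMask(map@cell, dim(map@values), sites, radius)
  }
  v <- map@values[mask]
  sum(abs(v)[abs(v) >= threshold])
}

# Logical array marking grid points within radius of any site
# (periodic minimum image, cartesian distance).
siteMask <- function(cell, grid, sites, radius) {
  ortho <- cellGeometry(cell)$ortho
  fr <- as.matrix(expand.grid(x = (seq_len(grid[1]) - 1) / grid[1],
                              y = (seq_len(grid[2]) - 1) / grid[2],
                              z = (seq_len(grid[3]) - 1) / grid[3]))
  sel <- rep(FALSE, nrow(fr))
  for (i in seq_len(nrow(sites))) {
    d <- fr - matrix(sites[i, ], nrow(fr), 3, byrow = TRUE)
    d <- d - round(d)
    cart <- d %*% t(ortho)
    sel <- sel | rowSums(cart^2) <= radius^2
  }
  array(sel, dim = grid)
}
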