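#' @include AllClasses.R
NULL

# Cromer-Mann 4-Gaussian + constant X-ray form factors (neutral atoms).
# f(s) = sum_i a_i exp(-b_i (s/2)^2) + c with s = 1/d in 1/Angstrom.
# Toy-scale scope: C, N, O, S only.
.formFactors <- list(
  C = list(a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512), c = 0.215600),
  N = list(a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600), c = -11.5290),
  O = list(a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089), c = 0.250800),
  S = list(a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720), c = 0.866900)
)

#' Atomic scattering factor
#'
#' Evaluates the tabulated 4-Gaussian form factor for C, N, O or S at
#' scattering vector length \code{s = 1/d}.
#'
#' @param element element symbol
#' @param s numeric, 1/d in 1/Angstrom
#' @return numeric, electrons
#' @export
formFactor <- function(element, s) {
  ff <- .formFactors[[element]]
  if (is.null(ff)) stop("unknown element: ", element,
                        " (supported: C, N, O, S)")
  x <- (s / 2)^2
  Reduce(`+`, lapply(seq_along(ff$a),
                     function(i) ff$a[i] * exp(-ff$b[i] * x)), ff$c)
}

# Direct-space metric tensor and derived geometry for a triclinic cell.
cellGeometry <- function(cell) {
  a <- cell[1]; b <- cell[2]; cc <- cell[3]
  ang <- cell[4:6] * pi / 180
  ca <- cos(ang[1]); cb <- cos(ang[2]); cg <- cos(ang[3]); sg <- sin(ang[3])
  G <- matrix(c(a * a, a * b * cg, a * cc * cb,
                a * b * cg, b * b, b * cc * ca,
                a * cc * cb, b * cc * ca, cc * cc), 3, 3)
  vol <- sqrt(det(G))
  # fractional -> cartesian (standard PDB orthogonalization)
  ortho <- matrix(c(a, b * cg, cc * cb,
                    0, b * sg, cc * (ca - cb * cg) / sg,
                    0, 0, vol / (a * b * sg)), 3, 3, byrow = TRUE)
  list(G = G, Ginv = solve(G), volume = vol, ortho = ortho)
}

# 1/d for rows of an integer hkl matrix.
invResolution <- function(hkl, geom) {
  sqrt(rowSums((hkl %*% geom$Ginv) * hkl))
}

# Unique hemisphere of hkl to dmin: l > 0, or l = 0 & k > 0, or
# l = k = 0 & h > 0. (000) excluded.
hemisphereHKL <- function(cell, dmin) {
  geom <- cellGeometry(cell)
  hmax <- ceiling(cell[1:3] / dmin)
  g <- expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                   l = 0:hmax[3])
  m <- as.matrix(g)
  keep <- m[, 3] > 0 | (m[, 3] == 0 & m[, 2] > 0) |
          (m[, 3] == 0 & m[, 2] == 0 & m[, 1] > 0)
  m <- m[keep, , drop = FALSE]
  s <- invResolution(m, geom)
  m <- m[s <= 1 / dmin, , drop = FALSE]
  m[order(m[, 3], m[, 2], m[, 1]), , drop = FALSE]
}

# Complex kinematic structure factors of a ToyCrystal for given hkl rows:
# F(h) = sum_j occ_j f_j(s) exp(-B_j s^2 / 4) exp(2 pi i h.x_j)
complexStructureFactors <- function(model, hkl) {
  geom <- cellGeometry(model@cell)
  s <- invResolution(hkl, geom)
  at <- model@atoms
  xyz <- t(as.matrix(at[, c("x", "y", "z")]))     # 3 x natoms
  phase <- 2 * pi * (hkl %*% xyz)                 # nrefl x natoms
  w <- vapply(seq_len(nrow(at)), function(j) {
    at$occ[j] * formFactor(at$element[j], s) * exp(-at$b[j] * s^2 / 4)
  }, numeric(length(s)))                          # nrefl x natoms
  as.vector((w * exp(1i * phase)) %*% rep(1, nrow(at)))
}

#' Kinematic structure factors of a toy model
#'
#' Computes \eqn{F(h) = \sum_j occ_j f_j(s) e^{-B_j s^2/4} e^{2\pi i h
#' \cdot x_j}} with \eqn{s = 1/d(h)} over the complete unique hemisphere of
#' reflections to \code{dmin}, using tabulated Gaussian form factors for
#' C/N/O/S. Amplitudes and phases are returned; sigmas are zero (the
#' calculation is exact).
#'
#' @param model a [ToyCrystal-class]
#' @param dmin high-resolution cutoff, Angstrom (> 0)
#' @return a [ReflectionSet-class] with phases (degrees)
#' @examples
#' xtl <- buildToyPair(seed = 1)$off
#' structureFactors(xtl, dmin = 2.5)
#' @export
structureFactors <- function(model, dmin) {
  stopifnot(is(model, "ToyCrystal"))
  if (dmin <= 0) stop("dmin must be positive")
  hkl <- hemisphereHKL(model@cell, dmin)
  f <- complexStructureFactors(model, hkl)
  new("ReflectionSet", cell = model@cell, dmin = dmin,
      records = data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                           amp = Mod(f), sigma = 0,
                           phase = Arg(f) * 180 / pi))
}
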