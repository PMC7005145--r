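#' @include AllClasses.R
NULL

#' Read and write transient-absorption matrices as TSV
#'
#' The on-disk layout is one row per delay: first column the delay in
#' seconds (named \code{delay_s}), remaining columns one per wavelength,
#' header giving the wavelength in nm; cells are delta-A values.
#'
#' @param path file path
#' @param ts a [SpectralTimeSeries-class]
#' @param condition label attached on reading (default "unknown")
#' @return \code{readSpectraTSV} returns a [SpectralTimeSeries-class];
#'   \code{writeSpectraTSV} returns \code{path} invisibly
#' @export
writeSpectraTSV <- function(ts, path) {
  stopifnot(is(ts, "SpectralTimeSeries"))
  df <- data.frame(delay_s = ts@delays, t(ts@deltaA), check.names = FALSE)
  names(df)[-1] <- as.character(ts@wavelengths)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectraTSV
#' @export
readSpectraTSV <- function(path, condition = "unknown") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  if (names(df)[1] != "delay_s")
    stop("first column must be 'delay_s'")
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  dimnames(m) <- NULL
  new("SpectralTimeSeries",
      wavelengths = as.numeric(names(df)[-1]),
      delays = df$delay_s, deltaA = m, condition = condition)
}

#' Read and write reflection tables as TSV
#'
#' Columns \code{h k l amp sigma} with optional \code{phase_deg}; the cell
#' and resolution cutoff travel in \code{# cell ...} / \code{# dmin ...}
#' header comments.
#'
#' @param rs a [ReflectionSet-class]
#' @param path file path
#' @return \code{readReflectionTSV} returns a [ReflectionSet-class];
#'   \code{writeReflectionTSV} returns \code{path} invisibly
#' @export
writeReflectionTSV <- function(rs, path) {
  stopifnot(is(rs, "ReflectionSet"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# cell", paste(rs@cell, collapse = " ")),
               paste("# dmin", rs@dmin)), con)
  r <- rs@records
  hasPhase <- !all(is.na(r$phase))
  if (!hasPhase) r$phase <- NULL else names(r)[names(r) == "phase"] <-
    "phase_deg"
  utils::write.table(r, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReflectionTSV
#' @export
readReflectionTSV <- function(path) {
  hdr <- readLines(path, n = 10)
  cellLine <- grep("^# cell ", hdr, value = TRUE)
  dminLine <- grep("^# dmin ", hdr, value = TRUE)
  if (!length(cellLine) || !length(dminLine))
    stop("missing '# cell' / '# dmin' header lines")
  cell <- as.numeric(strsplit(sub("^# cell ", "", cellLine[1]), " ")[[1]])
  dmin <- as.numeric(sub("^# dmin ", "", dminLine[1]))
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  if (!"phase_deg" %in% names(df)) df$phase_deg <- NA_real_
  new("ReflectionSet", cell = cell, dmin = dmin,
      records = data.frame(h = as.integer(df$h), k = as.integer(df$k),
                           l = as.integer(df$l), amp = df$amp,
                           sigma = df$sigma, phase = df$phase_deg))
}

#' Write and read toy models as PDB
#'
#' Standard fixed-width CRYST1 + ATOM records; coordinates are converted
#' between the fractional representation of [ToyCrystal-class] and the
#' cartesian Angstrom of PDB. Occupancy and B columns round-trip. Reading
#' uses \pkg{bio3d}; the CRYST1 line is parsed directly.
#'
#' @param xtl a [ToyCrystal-class]
#' @param path file path
#' @return \code{readToyPDB} returns a [ToyCrystal-class];
#'   \code{writeToyPDB} returns \code{path} invisibly
#' @export
writeToyPDB <- function(xtl, path) {
  stopifnot(is(xtl, "ToyCrystal"))
  geom <- cellGeometry(xtl@cell)
  at <- xtl@atoms
  cart <- as.matrix(at[, c("x", "y", "z")]) %*% t(geom$ortho)
  lines <- sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
    xtl@cell[1], xtl@cell[2], xtl@cell[3],
    xtl@cell[4], xtl@cell[5], xtl@cell[6])
  for (i in seq_len(nrow(at))) {
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s LIG A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      i, paste0(at$element[i], i), 1,
      cart[i, 1], cart[i, 2], cart[i, 3], at$occ[i], at$b[i],
      at$element[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname writeToyPDB
#' @export
readToyPDB <- function(path) {
  cr <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cr)) stop("no CRYST1 record in ", path)
  cell <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                       substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                       substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  frac <- as.matrix(at[, c("x", "y", "z")]) %*%
    t(solve(cellGeometry(cell)$ortho))
  frac <- frac - floor(frac)
  new("ToyCrystal", cell = cell,
      atoms = data.frame(element = at$elesy, x = frac[, 1], y = frac[, 2],
                         z = frac[, 3], b = at$b, occ = at$o))
}
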