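test_that("toy pairs are reproducible with matched atom counts and real displacements", {
  p1 <- buildToyPair(seed = 0)
  p2 <- buildToyPair(seed = 0)
  expect_identical(p1, p2)
  expect_equal(nrow(atoms(p1$off)), nrow(atoms(p1$intermediate)))

  cell <- cellParams(p1$off)
  fr <- as.matrix(atoms(p1$off)[, c("x", "y", "z")])
  expect_true(all(fr >= 0 & fr < 1))

  # displaced atoms move by at least 1 A (direct coordinate comparison)
  for (i in p1$displaced) {
    d <- fracDist(cell,
                  unlist(atoms(p1$off)[i, c("x", "y", "z")]),
                  unlist(atoms(p1$intermediate)[i, c("x", "y", "z")]))
    expect_gte(d, 1)
    expect_lte(d, 2 + 1e-9)
  }
  still <- setdiff(seq_len(nrow(atoms(p1$off))), p1$displaced)
  expect_identical(atoms(p1$off)[still, ], atoms(p1$intermediate)[still, ])
})

test_that("observed pairs hit the no-activation and full-conversion limits", {
  pair <- buildToyPair(seed = 1)
  o0 <- simulateObservedPair(pair$off, pair$intermediate, fraction = 0,
                             dmin = 2, noiseFrac = 0, seed = 1)
  expect_equal(reflections(o0$laser_on)$amp, reflections(o0$laser_off)$amp)

  o1 <- simulateObservedPair(pair$off, pair$intermediate, fraction = 1,
                             dmin = 2, noiseFrac = 0, seed = 1)
  fInt <- structureFactors(pair$intermediate, dmin = 2)
  expect_equal(reflections(o1$laser_on)$amp, reflections(fInt)$amp,
               tolerance = 1e-12)

  expect_error(simulateObservedPair(pair$off, pair$intermediate,
                                    fraction = 1.2, dmin = 2), "fraction")
})

test_that("complex mixing precedes the modulus and common atoms cancel in the difference", {
  cell <- c(20, 20, 20, 90, 90, 90)
  shared <- data.frame(element = "C", x = 0.5, y = 0.5, z = 0.5,
                       b = 10, occ = 1)
  off <- new("ToyCrystal", cell = cell,
             atoms = rbind(shared,
                           data.frame(element = "O", x = 0.3, y = 0.4,
                                      z = 0.35, b = 12, occ = 1)))
  inter <- new("ToyCrystal", cell = cell,
               atoms = rbind(shared,
                             data.frame(element = "O", x = 0.42, y = 0.55,
                                        z = 0.3, b = 12, occ = 1)))
  obs <- simulateObservedPair(off, inter, fraction = 0.5, dmin = 2,
                              noiseFrac = 0, seed = 1)
  r <- reflections(obs$laser_on)
  pick <- match(c("1 0 2", "2 1 0", "3 2 1"), paste(r$h, r$k, r$l))
  expect_false(anyNA(pick))
  hkl <- as.matrix(r[pick, c("h", "k", "l")])

  # hand-computed complex mixture on three reflections
  fOff <- oracleComplexF(off, hkl)
  fInt <- oracleComplexF(inter, hkl)
  expect_equal(r$amp[pick], Mod(0.5 * fOff + 0.5 * fInt),
               tolerance = 1e-10)

  # the shared atom cancels in the complex difference: F_int - F_off equals
  # the two-O difference alone
  onlyO <- Mod(fInt - fOff)
  oOff <- oracleComplexF(new("ToyCrystal", cell = cell,
                             atoms = off@atoms[2, , drop = FALSE]), hkl)
  oInt <- oracleComplexF(new("ToyCrystal", cell = cell,
                             atoms = inter@atoms[2, , drop = FALSE]), hkl)
  expect_equal(onlyO, Mod(oInt - oOff), tolerance = 1e-10)
})

test_that("the complex light-induced difference grows monotonically with the fraction", {
  # the mixing model is linear in complex structure-factor space, so the
  # modulus of the complex difference must scale exactly with f wherever
  # the two states differ
  pair <- buildToyPair(seed = 6)
  rs <- reflections(structureFactors(pair$off, dmin = 2.5))
  hkl <- as.matrix(rs[, c("h", "k", "l")])
  fOff <- oracleComplexF(pair$off, hkl)
  fInt <- oracleComplexF(pair$intermediate, hkl)
  changed <- Mod(fInt - fOff) > 1e-6
  fs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  d <- sapply(fs, function(f) Mod((1 - f) * fOff + f * fInt - fOff))
  deltas <- apply(d[changed, ], 1, diff)
  expect_true(all(deltas >= -1e-9))
  expect_equal(d[changed, 3], 0.5 * Mod(fInt - fOff)[changed],
               tolerance = 1e-12)
  # and the generator realizes exactly this mixture
  o <- simulateObservedPair(pair$off, pair$intermediate, fraction = 0.5,
                            dmin = 2.5, noiseFrac = 0, seed = 1)
  expect_equal(reflections(o$laser_on)$amp, Mod(0.5 * fOff + 0.5 * fInt),
               tolerance = 1e-9)
})

test_that("observed sigmas follow the fractional-noise model and seeds reproduce", {
  pair <- buildToyPair(seed = 2)
  a <- simulateObservedPair(pair$off, pair$intermediate, 0.5, dmin = 2,
                            noiseFrac = 0.05, seed = 9)
  b <- simulateObservedPair(pair$off, pair$intermediate, 0.5, dmin = 2,
                            noiseFrac = 0.05, seed = 9)
  expect_identical(reflections(a$laser_on), reflections(b$laser_on))
  r <- reflections(a$laser_off)
  expect_equal(r$sigma, 0.05 * r$amp)
})
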