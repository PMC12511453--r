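# a small forearm grid shared by the solver tests
small_tissue <- function() tissue_model(size_mm = c(120, 85), depth_mm = 35,
                                        dx_mm = 5, n_muscle = 6)
small_setup <- function(...) electrode_setup(
  centers_mm = rbind(c(-25, -20), c(25, -20), c(-25, 20), c(25, 20)), ...)

solved_pair <- function(p) {
  memo(paste0("vc_small_", p),
       solve_pair(small_tissue(), small_setup(), p))
}

test_that("prescribed electrode currents are reproduced", {
  s1 <- solved_pair(1)
  inj <- Re(s1$injected_A) * 1e3
  expect_equal(inj[1], 5, tolerance = 1e-3)
  expect_equal(inj[2], -5, tolerance = 1e-3)
  expect_lt(max(abs(inj[3:4])), 5e-3)
  expect_lt(abs(sum(Re(s1$injected_A))), 1e-9)   # global conservation
  expect_lt(s1$residual, 1e-10)
})

test_that("the discrete operator is linear in the injected currents", {
  s1 <- solved_pair(1)
  s2 <- solved_pair(2)
  sb <- memo("vc_small_both", solve_pair(small_tissue(), small_setup(), "both"))
  err <- max(Mod(sb$v - s1$v - s2$v)) / max(Mod(sb$v))
  expect_lt(err, 1e-10)
  # scaling the current scales the solution
  s1d <- solve_pair(small_tissue(), small_setup(i1_mA = 10), 1)
  errs <- max(Mod(s1d$v - 2 * s1$v)) / max(Mod(s1d$v))
  expect_lt(errs, 1e-10)
})

test_that("activating amplitudes recover closed-form second derivatives", {
  s1 <- solved_pair(1)
  g <- s1$grid
  fake <- s1
  # quadratic potential V = a x^2 -> |d2V/dx2| = 2a everywhere
  a <- 3.7
  vq <- array(0, dim = c(g$nx, g$ny, g$nz))
  for (k in seq_len(g$nz)) vq[, , k] <- outer(a * g$xc^2, rep(1, g$ny))
  fake$v <- vq
  aq <- activating_amplitude(fake)
  expect_equal(max(abs(aq - 2 * a), na.rm = TRUE), 0, tolerance = 1e-6)
  # linear ramp -> zero activating function
  vl <- array(0, dim = c(g$nx, g$ny, g$nz))
  for (k in seq_len(g$nz)) vl[, , k] <- outer(5 * g$xc, rep(1, g$ny))
  fake$v <- vl
  al <- activating_amplitude(fake)
  expect_lt(max(al, na.rm = TRUE), 1e-8)
  expect_error(activating_amplitude(fake, nerve_depth_mm = 200), "outside")
})

test_that("nerve midline sees balanced amplitudes; steering makes it tonic", {
  s1 <- solved_pair(1)
  s2 <- solved_pair(2)
  a1 <- activating_amplitude(s1)
  a2 <- activating_amplitude(s2)
  mid <- which.min(abs(s1$grid$yc))
  # by montage symmetry the two pairs contribute equally on the midline
  expect_equal(max(a1[, mid], na.rm = TRUE), max(a2[, mid], na.rm = TRUE),
               tolerance = 1e-6)

  # per-mA amplitude fields (linearity lets us rescale without resolving)
  a1u <- a1 / 5; a2u <- a2 / 5
  nerve1 <- max(a1u[, mid], na.rm = TRUE)
  # equal currents chosen so the midline summed amplitude is 1.5 x A_T:
  # phasic at the nerve, tonic next to the electrodes
  at <- 1000
  i_eq <- 1.5 * at / (2 * nerve1)
  tm <- tot_map(i_eq * a1u, i_eq * a2u, at)
  expect_true(any(tm$region == "tonic", na.rm = TRUE))
  mid_tot <- tm$tot[which.max(i_eq * a1u[, mid] + i_eq * a2u[, mid]), mid]
  expect_gt(mid_tot, 0)
  expect_lt(mid_tot, 1)

  # strongly asymmetric steering (1:9 of the same total) drives the
  # nerve point tonic: the unmodulated floor exceeds the threshold
  i1 <- 0.2 * i_eq; i2 <- 1.8 * i_eq
  tm2 <- tot_map(i1 * a1u, i2 * a2u, at)
  expect_identical(tm2$region[which.max(a1u[, mid]), mid], "tonic")

  # currents far below threshold leave the whole map unstimulated
  tm0 <- tot_map(1e-3 * a1u, 1e-3 * a2u, at)
  expect_true(all(tm0$tot[is.finite(tm0$tot)] == 0))

  expect_error(tot_map(a1[1:4, 1:4], a2, at), "co-registered")
})

test_that("tissue and montage constructors validate their inputs", {
  expect_error(tissue_model(sigma_muscle_along = 0.3,
                            sigma_muscle_across = 0.35), "muscle")
  expect_error(tissue_model(nerve_depth_mm = 3), "nerve_depth_mm")
  expect_error(electrode_setup(polarity = c(1, 1, 1, -1)), "anode")
  expect_error(electrode_setup(centers_mm = rbind(c(0, 0), c(5, 5),
                                                  c(-30, 25), c(30, 25))),
               "overlap")
  expect_error(electrode_setup(alpha = 1.2))
})
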