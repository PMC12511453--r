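#' Layered forearm tissue model
#'
#' A three-layer (skin, fat, muscle) slab on a structured cell-centred
#' grid. Skin and fat are isotropic; muscle conductivity and permittivity
#' are transversely anisotropic with the fibre (and nerve) direction along
#' x. Default material values are the standard literature parameters at
#' kHz frequencies: muscle 0.6 S/m & 1.5e5 (along fibre), 0.35 S/m & 1e5
#' (across); fat 0.0243 S/m & 3000; skin 0.0015 S/m & 40000.
#'
#' @param skin_mm,fat_mm Layer thicknesses in mm. Defaults 1.5 and 5.
#' @param size_mm Lateral domain extents `c(x, y)` in mm.
#'   Default `c(160, 125)` (odd y cell count keeps the nerve midline on-grid).
#' @param depth_mm Total slab depth in mm. Default 40.
#' @param dx_mm Lateral grid spacing in mm. Default 5.
#' @param n_skin,n_fat,n_muscle Cells across each layer (>= 2).
#'   Defaults 2, 4, 8 (muscle cells geometrically graded with depth).
#' @param sigma_muscle_along,sigma_muscle_across,sigma_fat,sigma_skin
#'   Conductivities in S/m.
#' @param epsr_muscle_along,epsr_muscle_across,epsr_fat,epsr_skin
#'   Relative permittivities.
#' @param nerve_depth_mm Depth of the nerve plane below the skin surface
#'   (must lie in muscle). Default 10.
#' @param frequency_hz Operating carrier frequency. Default 2500.
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(skin_mm = 1.5, fat_mm = 5, size_mm = c(160, 125),
                         depth_mm = 40, dx_mm = 5, n_skin = 2, n_fat = 4,
                         n_muscle = 8, sigma_muscle_along = 0.6,
                         sigma_muscle_across = 0.35, sigma_fat = 0.0243,
                         sigma_skin = 0.0015, epsr_muscle_along = 1.5e5,
                         epsr_muscle_across = 1e5, epsr_fat = 3000,
                         epsr_skin = 40000, nerve_depth_mm = 10,
                         frequency_hz = 2500) {
  stopifnot(skin_mm > 0, fat_mm > 0, depth_mm > skin_mm + fat_mm,
            n_skin >= 2, n_fat >= 2, n_muscle >= 2,
            sigma_muscle_along > 0, sigma_muscle_across > 0,
            sigma_muscle_along / sigma_muscle_across > 1,
            sigma_fat > 0, sigma_skin > 0, frequency_hz > 0,
            nerve_depth_mm > skin_mm + fat_mm, nerve_depth_mm < depth_mm)
  # z cell thicknesses: uniform within skin/fat, geometric in muscle
  dz_skin <- rep(skin_mm / n_skin, n_skin)
  dz_fat <- rep(fat_mm / n_fat, n_fat)
  hm <- depth_mm - skin_mm - fat_mm
  r <- 1.3
  w <- r^(seq_len(n_muscle) - 1)
  dz_mus <- hm * w / sum(w)
  structure(list(skin_mm = skin_mm, fat_mm = fat_mm, size_mm = size_mm,
                 depth_mm = depth_mm, dx_mm = dx_mm,
                 dz_mm = c(dz_skin, dz_fat, dz_mus),
                 layer = rep(c("skin", "fat", "muscle"),
                             c(n_skin, n_fat, n_muscle)),
                 sigma = list(muscle_along = sigma_muscle_along,
                              muscle_across = sigma_muscle_across,
                              fat = sigma_fat, skin = sigma_skin),
                 epsr = list(muscle_along = epsr_muscle_along,
                             muscle_across = epsr_muscle_across,
                             fat = epsr_fat, skin = epsr_skin),
                 nerve_depth_mm = nerve_depth_mm,
                 frequency_hz = frequency_hz),
            class = "tissue_model")
}

#' Electrode montage with electrode-skin interface impedance
#'
#' Square gel electrode patches on the skin surface, each belonging to one
#' of two stimulation pairs. The electrode-skin interface is a distributed
#' constant phase element, admittance per area `(j w)^alpha / K`, in
#' parallel with a charge-transfer resistance `Rp`; each electrode's gel
#' is a single equipotential node carrying a prescribed total current.
#'
#' @param centers_mm A 4 x 2 matrix (or data frame) of patch centre
#'   coordinates (x, y) in mm. Default: pair 1 at y = -25 and pair 2 at
#'   y = +25, each with electrodes at x = -30 (anode) and x = +30
#'   (cathode), so the nerve midline y = 0 lies midway between the pairs.
#' @param size_mm Patch side length in mm. Default 20.
#' @param pair Pair id per patch. Default `c(1, 1, 2, 2)`.
#' @param polarity +1 / -1 per patch; each pair needs exactly one of each.
#'   Default `c(1, -1, 1, -1)`.
#' @param K_Mohm_cm2 CPE magnitude K in MOhm s^-alpha cm^2. Default 35.
#' @param alpha CPE exponent in (0, 1]. Default 0.9.
#' @param Rp_Mohm_cm2 Charge-transfer resistance in MOhm cm^2.
#'   Default 4.7.
#' @param i1_mA,i2_mA Pair current amplitudes in mA. Defaults 5 and 5.
#' @param f1_hz,f2_hz Carrier frequencies of the two pairs; both pairs are
#'   solved at `f1_hz` (for beat offsets of a few Hz the per-pair transfer
#'   functions are indistinguishable). Defaults 2500 and 2510.
#' @return An object of class `electrode_setup`.
#' @export
electrode_setup <- function(centers_mm = NULL, size_mm = 20,
                            pair = c(1, 1, 2, 2),
                            polarity = c(1, -1, 1, -1),
                            K_Mohm_cm2 = 35, alpha = 0.9,
                            Rp_Mohm_cm2 = 4.7, i1_mA = 5, i2_mA = 5,
                            f1_hz = 2500, f2_hz = 2510) {
  if (is.null(centers_mm))
    centers_mm <- rbind(c(-30, -25), c(30, -25), c(-30, 25), c(30, 25))
  centers_mm <- as.matrix(centers_mm)
  np <- nrow(centers_mm)
  stopifnot(ncol(centers_mm) == 2, length(pair) == np,
            length(polarity) == np, all(polarity %in% c(-1, 1)),
            size_mm > 0, K_Mohm_cm2 > 0, alpha > 0, alpha <= 1,
            Rp_Mohm_cm2 > 0)
  for (p in unique(pair)) {
    pol <- polarity[pair == p]
    if (sum(pol == 1) != 1 || sum(pol == -1) != 1)
      stop("each pair must have exactly one anode and one cathode")
  }
  # overlap check (axis-aligned squares)
  if (np > 1) {
    for (i in 1:(np - 1)) for (j in (i + 1):np) {
      if (all(abs(centers_mm[i, ] - centers_mm[j, ]) < size_mm))
        stop("electrode patches overlap")
    }
  }
  structure(list(centers_mm = centers_mm, size_mm = size_mm, pair = pair,
                 polarity = polarity, K_Mohm_cm2 = K_Mohm_cm2,
                 alpha = alpha, Rp_Mohm_cm2 = Rp_Mohm_cm2,
                 i_mA = c(i1_mA, i2_mA), f1_hz = f1_hz, f2_hz = f2_hz),
            class = "electrode_setup")
}

# complex admittivity (S/m) per cell and direction
.cell_admittivity <- function(tissue, direction) {
  eps0 <- 8.8541878128e-12
  w <- 2 * pi * tissue$frequency_hz
  lay <- tissue$layer
  sig <- tissue$sigma; epr <- tissue$epsr
  kap <- complex(length(lay))
  for (i in seq_along(lay)) {
    l <- lay[i]
    if (l == "muscle") {
      if (direction == "x") {
        s <- sig$muscle_along; e <- epr$muscle_along
      } else {
        s <- sig$muscle_across; e <- epr$muscle_across
      }
    } else {
      s <- sig[[l]]; e <- epr[[l]]
    }
    kap[i] <- complex(real = s, imaginary = w * eps0 * e)
  }
  kap
}

# grid geometry helper: cell centres and thicknesses in meters
.vc_grid <- function(tissue) {
  dx <- tissue$dx_mm * 1e-3
  nx <- round(tissue$size_mm[1] / tissue$dx_mm)
  ny <- round(tissue$size_mm[2] / tissue$dx_mm)
  xc <- (seq_len(nx) - (nx + 1) / 2) * dx
  yc <- (seq_len(ny) - (ny + 1) / 2) * dx
  dz <- tissue$dz_mm * 1e-3
  zf <- cumsum(c(0, dz))
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  list(nx = nx, ny = ny, nz = length(dz), dx = dx, xc = xc, yc = yc,
       zc = zc, dz = dz)
}

# Solve (R + iS) v = b, with R SPD and S symmetric PSD (both real
# sparse), by BiCGSTAB preconditioned with the CHOLMOD Cholesky
# factorization of R + S. For quasi-static tissue operators the
# preconditioned iteration converges in a few tens of steps.
.cocg_solve <- function(Rm, Sm, b, tol = 1e-12, maxit = 500) {
  P <- Matrix::forceSymmetric(Rm + Sm)
  ch <- Matrix::Cholesky(P, LDL = FALSE, perm = TRUE)
  minv <- function(z) {
    u <- Matrix::solve(ch, cbind(Re(z), Im(z)), system = "A")
    complex(real = u[, 1], imaginary = u[, 2])
  }
  amul <- function(z) {
    zr <- Re(z); zi <- Im(z)
    complex(real = as.numeric(Rm %*% zr - Sm %*% zi),
            imaginary = as.numeric(Sm %*% zr + Rm %*% zi))
  }
  cdot <- function(a, b2) sum(Conj(a) * b2)
  n <- length(b)
  x <- minv(b)
  r <- b - amul(x)
  bnorm <- sqrt(Re(cdot(b, b)))
  if (bnorm == 0) return(complex(n))
  rhat <- r
  rho <- alpha <- omega <- complex(real = 1)
  vv <- p <- complex(n)
  for (it in seq_len(maxit)) {
    rho1 <- cdot(rhat, r)
    if (Mod(rho1) < 1e-300) break
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * vv)
    phat <- minv(p)
    vv <- amul(phat)
    alpha <- rho / cdot(rhat, vv)
    s <- r - alpha * vv
    shat <- minv(s)
    t2 <- amul(shat)
    omega <- cdot(t2, s) / cdot(t2, t2)
    x <- x + alpha * phat + omega * shat
    r <- s - omega * t2
    if (sqrt(Re(cdot(r, r))) / bnorm < tol) return(x)
  }
  if (sqrt(Re(cdot(r, r))) / bnorm > 1e-8)
    stop(sprintf("iterative solve stalled: relative residual %.3g after %d iterations",
                 sqrt(Re(cdot(r, r))) / bnorm, maxit))
  x
}

# Assemble and solve the complex system for given per-pair current
# amplitudes (amps, length = number of pairs). Returns complex potentials.
.vc_solve <- function(tissue, setup, pair_amps_A) {
  g <- .vc_grid(tissue)
  nx <- g$nx; ny <- g$ny; nz <- g$nz
  N <- nx * ny * nz
  ne <- nrow(setup$centers_mm)
  idx <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nx * ny

  kap_x <- .cell_admittivity(tissue, "x")   # per z-layer
  kap_t <- .cell_admittivity(tissue, "t")

  ii <- integer(0); jj <- integer(0); xx <- complex(0)

  dx <- g$dx; dz <- g$dz
  # x- and y-direction face conductances (uniform lateral spacing);
  # within a z-layer the admittivity is constant laterally
  for (k in seq_len(nz)) {
    a_yz <- dx * dz[k]      # face area for x-neighbours
    Gx <- kap_x[k] * a_yz / dx
    Gy <- kap_t[k] * a_yz / dx
    base <- (k - 1) * nx * ny
    # x faces
    i1 <- rep(seq_len(nx - 1), ny) + rep((seq_len(ny) - 1) * nx, each = nx - 1) + base
    i2 <- i1 + 1
    ii <- c(ii, i1, i2, i1, i2); jj <- c(jj, i1, i2, i2, i1)
    xx <- c(xx, rep(Gx, 2 * length(i1)), rep(-Gx, 2 * length(i1)))
    # y faces
    j1 <- rep(seq_len(nx), ny - 1) + rep((seq_len(ny - 1) - 1) * nx, each = nx) + base
    j2 <- j1 + nx
    ii <- c(ii, j1, j2, j1, j2); jj <- c(jj, j1, j2, j2, j1)
    xx <- c(xx, rep(Gy, 2 * length(j1)), rep(-Gy, 2 * length(j1)))
  }
  # z faces: series of the two half cells (handles layer interfaces)
  a_xy <- dx * dx
  for (k in seq_len(nz - 1)) {
    Gz <- a_xy / (dz[k] / (2 * kap_t[k]) + dz[k + 1] / (2 * kap_t[k + 1]))
    k1 <- seq_len(nx * ny) + (k - 1) * nx * ny
    k2 <- k1 + nx * ny
    ii <- c(ii, k1, k2, k1, k2); jj <- c(jj, k1, k2, k2, k1)
    xx <- c(xx, rep(Gz, 2 * length(k1)), rep(-Gz, 2 * length(k1)))
  }

  # electrode-skin interface: CPE || Rp in series with the top half-cell
  w <- 2 * pi * setup$f1_hz
  Rp <- setup$Rp_Mohm_cm2 * 1e6 * 1e-4          # Ohm m^2
  K <- setup$K_Mohm_cm2 * 1e6 * 1e-4            # Ohm m^2 s^-alpha
  y_esi <- 1 / Rp + (complex(imaginary = w))^setup$alpha / K  # S/m^2
  b <- complex(N + ne)
  gel_rows <- vector("list", ne)
  half <- setup$size_mm / 2
  for (e in seq_len(ne)) {
    cx <- setup$centers_mm[e, 1] * 1e-3
    cy <- setup$centers_mm[e, 2] * 1e-3
    selx <- which(abs(g$xc - cx) <= half * 1e-3 + 1e-9)
    sely <- which(abs(g$yc - cy) <= half * 1e-3 + 1e-9)
    if (!length(selx) || !length(sely))
      stop("electrode patch covers no surface cells")
    cells <- as.vector(outer(selx, (sely - 1) * nx, `+`))  # k = 1 layer
    # series: ESI admittance over the face area, then half of the top cell
    g_esi <- y_esi * a_xy
    g_half <- kap_t[1] * a_xy / (dz[1] / 2)
    g_eff <- 1 / (1 / g_esi + 1 / g_half)
    ge <- N + e
    nc <- length(cells)
    ii <- c(ii, cells, rep(ge, nc), cells, rep(ge, nc))
    jj <- c(jj, cells, rep(ge, nc), rep(ge, nc), cells)
    xx <- c(xx, rep(g_eff, 2 * nc), rep(-g_eff, 2 * nc))
    gel_rows[[e]] <- cells
    p <- setup$pair[e]
    b[ge] <- setup$polarity[e] * pair_amps_A[p]
  }

  Ntot <- N + ne
  # original (unpinned) operator for residual/conservation checks
  Ar0 <- Matrix::sparseMatrix(i = ii, j = jj, x = Re(xx), dims = c(Ntot, Ntot))
  Ai0 <- Matrix::sparseMatrix(i = ii, j = jj, x = Im(xx), dims = c(Ntot, Ntot))

  # The pure-Neumann operator has a constant nullspace; pin one deep
  # corner cell to 0 V. Dropping the pinned row AND column is exact
  # (V_pin = 0) and keeps the operator symmetric: the complex system
  # A = R + iS then has SPD real part and PSD imaginary part.
  pin <- idx(1, 1, nz)
  keep <- ii != pin & jj != pin
  iiS <- c(ii[keep], pin); jjS <- c(jj[keep], pin)
  xxS <- c(xx[keep], complex(real = 1))
  Rm <- Matrix::sparseMatrix(i = iiS, j = jjS, x = Re(xxS),
                             dims = c(Ntot, Ntot))
  Sm <- Matrix::sparseMatrix(i = iiS, j = jjS, x = Im(xxS),
                             dims = c(Ntot, Ntot))
  bs <- b
  bs[pin] <- 0
  v <- .cocg_solve(Rm, Sm, bs)

  vre <- Re(v); vim <- Im(v)
  rr <- as.numeric(Ar0 %*% vre - Ai0 %*% vim) - Re(b)
  ri <- as.numeric(Ai0 %*% vre + Ar0 %*% vim) - Im(b)
  bnorm <- max(sqrt(sum(Mod(b)^2)), 1e-300)
  resid <- sqrt(sum(rr^2 + ri^2)) / bnorm

  # injected current per electrode (for the conservation contract)
  g_esi <- y_esi * a_xy
  g_half <- kap_t[1] * a_xy / (dz[1] / 2)
  g_eff <- 1 / (1 / g_esi + 1 / g_half)
  inj <- vapply(seq_len(ne), function(e)
    sum(g_eff * (v[N + e] - v[gel_rows[[e]]])), complex(1))
  list(v = array(v[seq_len(N)], dim = c(nx, ny, nz)),
       gel = v[N + seq_len(ne)], grid = g, residual = as.numeric(resid),
       injected_A = inj)
}

#' Solve the volume conductor for one (or both) electrode pairs
#'
#' Solves the frequency-domain current continuity equation
#' `div((sigma + j w eps0 epsr) grad V) = 0` on the structured grid with
#' insulating outer boundaries, gel-equipotential electrodes coupled
#' through the CPE electrode-skin interface, and prescribed total current
#' on the active pair (zero net current on the inactive pair, which
#' remains present and can shunt current through its interface).
#'
#' @param tissue A [tissue_model()].
#' @param setup An [electrode_setup()].
#' @param pair Which pair to drive: 1, 2, or `"both"`.
#' @return An object of class `field_solution` with the complex potential
#'   array `v` (V), grid coordinates, gel potentials, solver residual, and
#'   injected per-electrode currents.
#' @export
solve_pair <- function(tissue, setup, pair = 1) {
  stopifnot(inherits(tissue, "tissue_model"),
            inherits(setup, "electrode_setup"))
  # every layer must be resolved by at least 2 cells (constructor default)
  for (l in unique(tissue$layer))
    if (sum(tissue$layer == l) < 2)
      stop("each tissue layer needs at least 2 grid cells in depth")
  amps <- setup$i_mA * 1e-3
  sel <- if (identical(pair, "both")) c(1, 2)
         else if (pair %in% c(1, 2)) pair
         else stop("pair must be 1, 2 or 'both'")
  pa <- c(0, 0)
  pa[sel] <- amps[sel]
  out <- .vc_solve(tissue, setup, pa)
  if (out$residual > 1e-8)
    stop(sprintf("linear solve did not converge: residual %g", out$residual))
  structure(list(v = out$v, grid = out$grid, gel_V = out$gel,
                 residual = out$residual, injected_A = out$injected_A,
                 pair = pair, tissue = tissue, setup = setup),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  g <- x$grid
  cat(sprintf("<field_solution> pair %s: %d x %d x %d cells, residual %.2e\n",
              paste(x$pair, collapse = "+"), g$nx, g$ny, g$nz, x$residual))
  invisible(x)
}

#' Activating-function amplitude on the nerve plane
#'
#' The modulus of the second central difference of the complex potential
#' along the fibre direction x, evaluated on the horizontal plane at the
#' nerve depth: `A = |d2V/dx2|` in V/m^2.
#'
#' @param solution A `field_solution`.
#' @param nerve_depth_mm Depth of the nerve plane in mm; defaults to the
#'   tissue model's value. Must lie inside the grid.
#' @return A matrix (x along rows, y along columns) of activating
#'   amplitudes; the two boundary rows are NA.
#' @export
activating_amplitude <- function(solution, nerve_depth_mm = NULL) {
  stopifnot(inherits(solution, "field_solution"))
  g <- solution$grid
  if (is.null(nerve_depth_mm))
    nerve_depth_mm <- solution$tissue$nerve_depth_mm
  zt <- nerve_depth_mm * 1e-3
  if (zt < min(g$zc) || zt > max(g$zc))
    stop("nerve plane lies outside the grid")
  k <- which.min(abs(g$zc - zt))
  vpl <- solution$v[, , k]
  nx <- g$nx
  a <- matrix(NA_real_, nx, g$ny)
  d2 <- (vpl[1:(nx - 2), ] - 2 * vpl[2:(nx - 1), ] + vpl[3:nx, ]) / g$dx^2
  a[2:(nx - 1), ] <- Mod(d2)
  a
}

#' Time-over-threshold map from two activating-amplitude fields
#'
#' Applies the closed-form time-over-threshold statistic elementwise to
#' co-registered per-pair activating amplitude fields and labels each
#' point subthreshold / phasic / tonic. Also returns the combined maps
#' `a_max = a1 + a2` (beat envelope maximum) and `a_min = |a1 - a2|`
#' (unmodulated floor).
#'
#' @param a1,a2 Per-pair activating amplitude matrices (same dimensions).
#' @param a_threshold Activation threshold in V/m^2. Default 1000.
#' @return A list with matrices `tot`, `region`, `a_max`, `a_min`.
#' @export
tot_map <- function(a1, a2, a_threshold = 1000) {
  if (!all(dim(a1) == dim(a2)))
    stop("activating amplitude fields are not co-registered")
  ok <- is.finite(a1) & is.finite(a2)
  tot <- matrix(NA_real_, nrow(a1), ncol(a1))
  tot[ok] <- tot_closed_form(activating_pair(a1[ok], a2[ok], a_threshold))
  region <- matrix(NA_character_, nrow(a1), ncol(a1))
  region[ok] <- classify_region(tot[ok])
  list(tot = tot, region = region, a_max = a1 + a2, a_min = abs(a1 - a2),
       a_threshold = a_threshold)
}

#' Export a field map as CSV
#'
#' Writes a long-format CSV (`x_mm`, `y_mm`, `value`) for a nerve-plane
#' map as produced by [activating_amplitude()] or [tot_map()].
#'
#' @param map A matrix over the lateral grid.
#' @param solution The `field_solution` the map came from (for
#'   coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, solution, path) {
  g <- solution$grid
  df <- expand.grid(x_mm = g$xc * 1e3, y_mm = g$yc * 1e3)
  df$value <- as.vector(map)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
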