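# Synthetic 1-D carbon-beam transport surrogate: a Bragg-Kleeman
# range-energy relation with Gaussian range straggling (deterministic
# Gauss-Hermite quadrature over the range distribution) and optional
# exponential primary attenuation, producing per-slice deposition records
# with the HIBMC-like water-phantom geometry.

#' Water-phantom slab geometry
#'
#' A lateral `lateral_cm` x `lateral_cm` water box split along the beam axis
#' into `n_slices` slices of `slice_mm` each. Defaults reproduce the
#' HIBMC-style setup: 15 x 15 cm^2, 250 slices of 1 mm (250 mm depth).
#'
#' @param lateral_cm Lateral side, cm.
#' @param n_slices Number of depth slices.
#' @param slice_mm Slice thickness, mm.
#' @return Object of class `phantom_geometry` with derived `depth_mm`,
#'   slice-center `depth_grid` and `voxel_volume_mm3`.
#' @export
phantom_geometry <- function(lateral_cm = 15, n_slices = 250L, slice_mm = 1) {
  stopifnot(lateral_cm > 0, n_slices >= 1L, slice_mm > 0)
  n_slices <- as.integer(n_slices)
  structure(list(lateral_cm = lateral_cm, n_slices = n_slices,
                 slice_mm = slice_mm,
                 depth_mm = n_slices * slice_mm,
                 depth_grid = (seq_len(n_slices) - 0.5) * slice_mm,
                 voxel_volume_mm3 = (lateral_cm * 10)^2 * slice_mm),
            class = "phantom_geometry")
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf("<phantom_geometry> %g x %g cm^2, %d slices of %g mm (%g mm depth)\n",
              x$lateral_cm, x$lateral_cm, x$n_slices, x$slice_mm, x$depth_mm))
  invisible(x)
}

# Bragg-Kleeman exponent and carbon anchor: a is calibrated once so that a
# 320 MeV/n carbon beam ranges 220 mm in water; other species scale with
# A/Z^2 relative to carbon.
.BK_EXPONENT <- 1.75
.BK_COEFF_CARBON <- 220 / 320^1.75   # mm / (MeV/n)^1.75

#' Beam configuration for the 1-D transport surrogate
#'
#' @param ion Ion species (default carbon).
#' @param energy Initial kinetic energy per nucleon, MeV/n, in (0, 430].
#' @param fluence Number of primaries (scales all deposits linearly).
#' @param straggling_sigma Gaussian range-straggling sigma, mm; `NULL` means
#'   the default 0.012 x range; 0 disables straggling.
#' @param attenuation_length Exponential primary-attenuation length, cm;
#'   `Inf` (default) disables attenuation.
#' @param fragment_fraction Fraction of the residual energy of attenuated
#'   primaries re-deposited locally as a helium tail. This is a crude,
#'   deliberately non-physical plumbing knob (no real fragment spectra);
#'   default 0 (off).
#' @param range_coeff,range_exponent Bragg-Kleeman parameters for carbon
#'   (other ions scale as A/Z^2).
#' @param straggling_nodes Gauss-Hermite quadrature nodes for the range
#'   distribution (transport accuracy; 61 resolves the straggled peak shape
#'   to well below the slice width).
#' @param seed Retained for API symmetry with stochastic generators; the
#'   bundled transport is fully deterministic.
#' @return Object of class `beam_config`.
#' @export
beam_config <- function(ion = "carbon", energy = 320, fluence = 1,
                        straggling_sigma = NULL, attenuation_length = Inf,
                        fragment_fraction = 0,
                        range_coeff = .BK_COEFF_CARBON,
                        range_exponent = .BK_EXPONENT,
                        straggling_nodes = 61L,
                        seed = 12345L) {
  ion <- ion_species(ion)
  stopifnot(energy > 0, energy <= 430, fluence > 0,
            attenuation_length > 0, fragment_fraction >= 0,
            fragment_fraction <= 1, range_coeff > 0, range_exponent > 0)
  if (!is.null(straggling_sigma)) stopifnot(straggling_sigma >= 0)
  structure(list(ion = ion, energy = energy, fluence = fluence,
                 straggling_sigma = straggling_sigma,
                 attenuation_length = attenuation_length,
                 fragment_fraction = fragment_fraction,
                 range_coeff = range_coeff,
                 range_exponent = range_exponent,
                 straggling_nodes = as.integer(straggling_nodes),
                 seed = as.integer(seed)),
            class = "beam_config")
}

.bk_coeff <- function(ion, config) {
  ion <- ion_species(ion)
  config$range_coeff * (ion$A / ion$Z^2) / (12 / 36)
}

#' Bragg-Kleeman range-energy relation
#'
#' `range_energy` gives the residual range R = a E0^p in mm of water;
#' `energy_at_depth` inverts it, E(z) = ((R - z)/a)^(1/p) for z < R and 0
#' beyond. The carbon coefficient is calibrated so a 320 MeV/n beam ranges
#' 220 mm.
#'
#' @param ion Ion species.
#' @param E0 Initial kinetic energy per nucleon, MeV/n.
#' @param depth Depth in water, mm (vectorized), >= 0.
#' @param config A [beam_config()] carrying the Bragg-Kleeman parameters.
#' @return Range in mm, or energy in MeV/n.
#' @examples
#' range_energy("carbon", 320)  # ~ 220 mm
#' @export
range_energy <- function(ion, E0, config = beam_config(ion = ion, energy = E0)) {
  if (any(E0 <= 0) || any(E0 > 430)) stop("E0 must be in (0, 430] MeV/n")
  .bk_coeff(ion, config) * E0^config$range_exponent
}

#' @rdname range_energy
#' @export
energy_at_depth <- function(ion, E0, depth,
                            config = beam_config(ion = ion, energy = E0)) {
  if (any(depth < 0)) stop("depth must be non-negative")
  a <- .bk_coeff(ion, config)
  R <- a * E0^config$range_exponent
  res <- pmax(R - depth, 0)
  (res / a)^(1 / config$range_exponent)
}

# Gauss-Hermite nodes/weights for integral over N(mu, sigma), probabilist
# convention: int f(x) dN(x) ~ sum w_i f(mu + sqrt(2) sigma t_i) / sqrt(pi)
.gauss_hermite <- function(n = 15L) {
  gh <- pracma::gaussHermite(n)
  w <- gh$w / sqrt(pi)
  keep <- w > 0   # extreme-node weights can underflow to exact zero
  list(x = gh$x[keep], w = w[keep])
}

#' Generate a pristine Bragg curve and its deposition records
#'
#' Transports the beam slice by slice: each range-distribution quadrature
#' node deposits, in slice i, `fluence * w * A * (E(z_i) - E(z_{i+1}))` MeV
#' (all electronic losses local, emulating transport without secondary
#' electron generation), optionally thinned by exponential primary
#' attenuation; attenuated primaries can re-deposit a fraction of their
#' residual energy locally as a helium-tagged tail. Range straggling is
#' integrated deterministically with Gauss-Hermite quadrature over the
#' Gaussian range distribution (`straggling_nodes` nodes), so identical
#' inputs give identical records.
#'
#' @param config A [beam_config()].
#' @param geom A [phantom_geometry()].
#' @return List of class `pristine_beam`: `curve` (a `depth_dose_curve`:
#'   `depth` mm at slice centers, `dose` Gy), `records` (data.frame with
#'   columns `voxel` (0-based slice), `ion`, `E` MeV/n at slice entrance,
#'   `edep` MeV), `config`, `geom`.
#' @export
pristine_beam <- function(config = beam_config(), geom = phantom_geometry()) {
  stopifnot(inherits(config, "beam_config"), inherits(geom, "phantom_geometry"))
  ion <- config$ion
  R0 <- range_energy(ion, config$energy, config)
  if (R0 > geom$depth_mm)
    warning(sprintf("beam range %.1f mm exceeds phantom depth %g mm; records truncated",
                    R0, geom$depth_mm))
  sig <- if (is.null(config$straggling_sigma)) 0.012 * R0
         else config$straggling_sigma
  ngh <- if (is.null(config$straggling_nodes)) 61L else config$straggling_nodes
  nodes <- if (sig > 0) .gauss_hermite(ngh) else list(x = 0, w = 1)
  a <- .bk_coeff(ion, config)
  p <- config$range_exponent
  edges <- seq(0, geom$depth_mm, by = geom$slice_mm)
  zlo <- edges[-length(edges)]; zhi <- edges[-1L]
  lam <- config$attenuation_length * 10  # cm -> mm
  surv <- if (is.finite(lam)) exp(-zlo / lam) else rep(1, length(zlo))
  dsurv <- if (is.finite(lam)) surv * (1 - exp(-(zhi - zlo) / lam))
           else rep(0, length(zlo))

  rec <- list(); k <- 0L
  for (j in seq_along(nodes$x)) {
    Rj <- R0 + sqrt(2) * sig * nodes$x[j]
    if (Rj <= 0) next
    wj <- nodes$w[j] * config$fluence
    Ein  <- (pmax(Rj - zlo, 0) / a)^(1 / p)
    Eout <- (pmax(Rj - zhi, 0) / a)^(1 / p)
    dE <- Ein - Eout
    hit <- which(dE > 0)
    if (!length(hit)) next
    k <- k + 1L
    rec[[k]] <- data.frame(voxel = hit - 1L, ion = ion$name,
                           E = Ein[hit],
                           edep = wj * surv[hit] * ion$A * dE[hit],
                           stringsAsFactors = FALSE)
    if (config$fragment_fraction > 0 && is.finite(lam)) {
      # residual energy of primaries removed in each slice, re-tagged helium
      Eres <- Eout[hit]
      tail_e <- wj * dsurv[hit] * ion$A * Eres * config$fragment_fraction
      keep <- tail_e > 0
      if (any(keep)) {
        k <- k + 1L
        rec[[k]] <- data.frame(voxel = hit[keep] - 1L, ion = "helium",
                               E = pmax(Eres[keep], 1e-6),
                               edep = tail_e[keep],
                               stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, rec)
  if (is.null(records))
    records <- data.frame(voxel = integer(), ion = character(),
                          E = numeric(), edep = numeric())
  records <- records[records$edep > 0, ]   # guard against underflow
  records <- records[order(records$voxel, records$ion, records$E), ]
  rownames(records) <- NULL
  dose_mev <- rep(0, geom$n_slices)
  agg <- rowsum(records$edep, records$voxel)
  dose_mev[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  curve <- depth_dose_curve(geom$depth_grid,
                            edep_to_dose(dose_mev, geom$voxel_volume_mm3))
  structure(list(curve = curve, records = records, config = config,
                 geom = geom),
            class = "pristine_beam")
}

#' Depth-dose curve
#'
#' @param depth Depth grid, mm.
#' @param dose Dose per depth, Gy (>= 0).
#' @return Object of class `depth_dose_curve`.
#' @export
depth_dose_curve <- function(depth, dose) {
  stopifnot(length(depth) == length(dose), all(dose >= 0),
            all(diff(depth) > 0))
  structure(list(depth = depth, dose = dose), class = "depth_dose_curve")
}

#' @export
print.depth_dose_curve <- function(x, ...) {
  i <- which.max(x$dose)
  cat(sprintf("<depth_dose_curve> %d points, peak %.4g Gy at %.1f mm\n",
              length(x$depth), x$dose[i], x$depth[i]))
  invisible(x)
}

#' Peak depth of a depth-dose curve
#'
#' @param curve A `depth_dose_curve`.
#' @return Depth of maximum dose, mm.
#' @export
peak_depth <- function(curve) curve$depth[which.max(curve$dose)]

#' Apply a water-equivalent range shifter
#'
#' Degrades the beam so its residual range drops by exactly `thickness` mm,
#' by lowering the initial energy through the Bragg-Kleeman inverse. Zero
#' thickness is the identity.
#'
#' @param config A [beam_config()].
#' @param thickness Water-equivalent thickness, mm (>= 0); must be smaller
#'   than the beam range.
#' @return A modified [beam_config()]; run [pristine_beam()] on it for the
#'   shifted curve/records.
#' @export
apply_range_shifter <- function(config, thickness) {
  stopifnot(inherits(config, "beam_config"), thickness >= 0)
  if (thickness == 0) return(config)
  R <- range_energy(config$ion, config$energy, config)
  if (thickness >= R)
    stop(sprintf("shifter thickness %g mm >= beam range %.1f mm: degenerate beam",
                 thickness, R))
  a <- .bk_coeff(config$ion, config)
  config$energy <- ((R - thickness) / a)^(1 / config$range_exponent)
  # keep absolute straggling width of the unshifted beam unless fixed by user
  if (is.null(config$straggling_sigma)) config$straggling_sigma <- 0.012 * R
  config
}

#' Convert per-voxel deposited energy to dose
#'
#' @param edep_mev Deposited energy, MeV.
#' @param volume_mm3 Voxel volume, mm^3.
#' @param density Density, g/cm^3.
#' @return Dose in Gy.
#' @export
edep_to_dose <- function(edep_mev, volume_mm3, density = 1.0) {
  if (any(volume_mm3 <= 0) || density <= 0)
    stop("volume and density must be positive")
  mass_kg <- density * volume_mm3 * 1e-6   # mm^3 * g/cm^3 -> kg
  edep_mev * 1.602176634e-13 / mass_kg
}

#' Normalize a beam to a prescription dose at a depth
#'
#' Scales curve and records so the physical dose at `depth_mm` (nearest
#' slice center) equals `dose_gy`.
#'
#' @param beam A `pristine_beam` (or any list with `curve` and `records`).
#' @param dose_gy Prescription dose, Gy.
#' @param depth_mm Depth of the prescription point (isocenter), mm.
#' @return The beam with scaled `curve$dose` and `records$edep`, plus the
#'   applied `scale`.
#' @export
normalize_to_prescription <- function(beam, dose_gy = 2.4, depth_mm) {
  i <- which.min(abs(beam$curve$depth - depth_mm))
  d0 <- beam$curve$dose[i]
  if (d0 <= 0) stop("zero dose at the prescription depth; cannot normalize")
  s <- dose_gy / d0
  beam$curve$dose <- beam$curve$dose * s
  beam$records$edep <- beam$records$edep * s
  beam$scale <- if (is.null(beam$scale)) s else beam$scale * s
  beam
}

#' Export deposition records / depth-dose curves as ASCII
#'
#' @param records Records data.frame (`voxel`, `ion`, `E`, `edep`).
#' @param curve A `depth_dose_curve`.
#' @param path Output file.
#' @export
write_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: voxel ion E_MeV_per_n edep_MeV", con)
  writeLines(sprintf("%d %s %.12g %.12g", records$voxel, records$ion,
                     records$E, records$edep), con)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("voxel", "ion", "E", "edep"),
                          stringsAsFactors = FALSE)
  if (any(df$edep <= 0)) stop("records must have positive deposited energy")
  df
}

#' @rdname write_records
#' @export
write_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# columns: depth_mm dose_Gy", con)
  writeLines(sprintf("%.12g %.12g", curve$depth, curve$dose), con)
  invisible(path)
}
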