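# LET (stopping power) layer: the track model treats LET as given and only
# needs it for normalization. A water stopping-power table per ion, generated
# once from the Bethe formula with Barkas effective charge, is shipped as a
# plain-text fixture and interpolated log-log.

# Bethe electronic stopping constants for liquid water
.K_BETHE  <- 0.307075   # MeV cm^2 / g (4 pi N_A r_e^2 m_e c^2 / A)
.ZA_WATER <- 0.55509    # Z/A of water
.I_WATER  <- 78e-6      # mean excitation energy, MeV (ICRU 90)
.ME_C2    <- 0.5109989  # electron rest energy, MeV

#' Electronic stopping power of water (Bethe formula)
#'
#' Unrestricted electronic LET of an ion in liquid water from the Bethe
#' formula with the Barkas effective charge, valid down to ~0.05 MeV/n for
#' light ions. Used once to generate the bundled LET fixture tables; runtime
#' lookups go through [let_water()].
#'
#' @param ion An [ion_species()].
#' @param E Kinetic energy per nucleon, MeV/n (vectorized).
#' @param density Medium density, g/cm^3.
#' @return LET in keV/um.
#' @export
stopping_power_water <- function(ion, E, density = 1.0) {
  ion <- ion_species(ion)
  if (any(E <= 0)) stop("kinetic energy must be positive")
  gamma <- 1 + E / .M_NUCLEON
  beta2 <- 1 - 1 / gamma^2
  zeff  <- effective_charge(ion, E)
  Lterm <- log(2 * .ME_C2 * beta2 * gamma^2 / .I_WATER) - beta2
  if (any(Lterm <= 0))
    stop("Bethe stopping number non-positive; energy below model validity")
  S <- .K_BETHE * .ZA_WATER * zeff^2 / beta2 * Lterm  # MeV cm^2/g
  S * density * 0.1                                    # keV/um
}

.let_cache <- new.env(parent = emptyenv())

#' Read a bundled (or external) LET table
#'
#' Two-column whitespace-separated ASCII (energy MeV/n, LET keV/um) with `#`
#' comment headers naming the ion and medium.
#'
#' @param path File path; defaults to the bundled water table for `ion`.
#' @param ion Ion species (used only to locate the bundled file).
#' @return data.frame with columns `energy` and `let`, energies strictly
#'   increasing.
#' @export
read_let_table <- function(path = NULL, ion = NULL) {
  if (is.null(path)) {
    ion <- ion_species(ion)
    path <- system.file("extdata", "let",
                        paste0(ion$name, "_water.txt"),
                        package = "hadrondose", mustWork = TRUE)
  }
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("energy", "let"))
  if (nrow(tab) < 2L || any(diff(tab$energy) <= 0) || any(tab$let <= 0))
    stop("malformed LET table: ", path)
  tab
}

#' LET of an ion in water
#'
#' Log-log linear interpolation of the bundled stopping-power fixture table.
#' Queries outside the tabulated energy range are an error.
#'
#' @inheritParams stopping_power_water
#' @return LET in keV/um (vectorized over `E`).
#' @examples
#' let_water("carbon", c(1, 10, 100))
#' @export
let_water <- function(ion, E) {
  ion <- ion_species(ion)
  if (any(E <= 0)) stop("kinetic energy must be positive")
  key <- ion$name
  if (is.null(.let_cache[[key]])) {
    .let_cache[[key]] <- if (key %in% supported_ions())
      read_let_table(ion = ion)
    else  # species without a bundled table: evaluate the generator directly
      NULL
  }
  tab <- .let_cache[[key]]
  if (is.null(tab)) return(stopping_power_water(ion, E))
  if (any(E < min(tab$energy)) || any(E > max(tab$energy)))
    stop("energy outside tabulated LET range [",
         min(tab$energy), ", ", max(tab$energy), "] MeV/n")
  exp(stats::approx(log(tab$energy), log(tab$let), xout = log(E))$y)
}
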