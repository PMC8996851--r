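#' Ion species
#'
#' Construct the identity of a beam particle: element name, charge number Z
#' and mass number A. The package ships microdosimetry support for the four
#' therapy-relevant species: hydrogen (1,1), helium (2,4), carbon (6,12) and
#' oxygen (8,16); arbitrary (Z, A) pairs are accepted for the generic
#' kinematics helpers.
#'
#' @param name Species name or element symbol ("hydrogen"/"H", "helium"/"He",
#'   "carbon"/"C", "oxygen"/"O"), or an `ion_species` object (returned as is).
#' @param Z,A Optional charge and mass number for species outside the
#'   built-in set; both must be given together and satisfy `A >= Z >= 1`.
#'
#' @return An object of class `ion_species` with fields `name`, `symbol`,
#'   `Z` and `A`.
#' @examples
#' ion_species("carbon")
#' ion_species("X", Z = 3, A = 7)
#' @export
ion_species <- function(name, Z = NULL, A = NULL) {
  if (inherits(name, "ion_species")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  if (is.null(Z) != is.null(A))
    stop("Z and A must be supplied together")
  if (is.null(Z)) {
    key <- tolower(name)
    reg <- .ion_registry()
    hit <- match(key, c(tolower(reg$name), tolower(reg$symbol)))
    if (is.na(hit))
      stop("unsupported ion species: '", name, "' (supported: ",
           paste(reg$name, collapse = ", "),
           "); give Z and A explicitly for other species")
    hit <- (hit - 1L) %% nrow(reg) + 1L
    out <- list(name = reg$name[hit], symbol = reg$symbol[hit],
                Z = reg$Z[hit], A = reg$A[hit])
  } else {
    Z <- as.integer(Z); A <- as.integer(A)
    if (Z < 1L || A < Z) stop("require Z >= 1 and A >= Z")
    out <- list(name = name, symbol = name, Z = Z, A = A)
  }
  class(out) <- "ion_species"
  out
}

.ion_registry <- function() {
  data.frame(
    name   = c("hydrogen", "helium", "carbon", "oxygen"),
    symbol = c("H", "He", "C", "O"),
    Z      = c(1L, 2L, 6L, 8L),
    A      = c(1L, 4L, 12L, 16L),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s (%s), Z = %d, A = %d\n",
              x$name, x$symbol, x$Z, x$A))
  invisible(x)
}

#' Names of the ion species with bundled LET tables
#'
#' @return Character vector of species names.
#' @export
supported_ions <- function() .ion_registry()$name

# nucleon rest mass energy, MeV (average; relativistic kinematics helper)
.M_NUCLEON <- 931.494

#' Relativistic speed from kinetic energy per nucleon
#'
#' @param E Kinetic energy per nucleon, MeV/n.
#' @return beta = v/c (dimensionless, in (0, 1)).
#' @keywords internal
ion_beta <- function(E) {
  if (any(E <= 0)) stop("kinetic energy must be positive")
  gamma <- 1 + E / .M_NUCLEON
  sqrt(1 - 1 / gamma^2)
}

#' Effective charge of a slow ion (Barkas rule)
#'
#' Electron capture at low velocity reduces the net charge an ion presents to
#' the medium. The Barkas parameterization
#' \deqn{Z_{eff} = Z (1 - e^{-125 \beta Z^{-2/3}})}
#' is continuous in energy, so downstream microdosimetric quantities inherit
#' no quantization discontinuities.
#'
#' @param ion An [ion_species()] (or name accepted by it).
#' @param E Kinetic energy per nucleon, MeV/n (vectorized); must be > 0.
#' @return Effective charge in (0, Z]; tends to Z at high energy and is
#'   non-decreasing in E.
#' @examples
#' effective_charge("carbon", 400)  # ~ 6
#' effective_charge("carbon", 1)    # < 6
#' @export
effective_charge <- function(ion, E) {
  ion <- ion_species(ion)
  if (any(!is.finite(E)) || any(E <= 0))
    stop("kinetic energy must be positive and finite")
  b <- ion_beta(E)
  ion$Z * (1 - exp(-125 * b * ion$Z^(-2 / 3)))
}
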