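#' Spherical (Hertzian) contact configuration
#'
#' @param bead_radius radius of the spherical indenter tip (m, > 0).
#' @param poisson_ratio Poisson's ratio of the sample, in `[0, 0.5]`;
#'   0.5 for roughly incompressible soft biological tissue.
#' @return object of class `contact_config`.
#' @export
contact_config <- function(bead_radius = 150e-6, poisson_ratio = 0.5) {
  if (!is.numeric(bead_radius) || length(bead_radius) != 1L || bead_radius <= 0)
    stop("contact_config: 'bead_radius' must be a single value > 0", call. = FALSE)
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      poisson_ratio < 0 || poisson_ratio > 0.5)
    stop("contact_config: 'poisson_ratio' must lie in [0, 0.5]", call. = FALSE)
  structure(list(bead_radius = bead_radius, poisson_ratio = poisson_ratio),
            class = "contact_config")
}

# reduced (effective) indentation modulus E/(1 - nu^2) from the shear modulus:
# E = 2 G (1 + nu)  =>  E_eff = 2 G / (1 - nu)
effective_modulus <- function(shear_modulus, poisson_ratio) {
  2 * shear_modulus / (1 - poisson_ratio)
}

#' Hertzian force-depth law for a spherical indenter
#'
#' `F = (4/3) E_eff sqrt(R) h^(3/2)` with `E_eff = E / (1 - nu^2)` and
#' `E = 2 G (1 + nu)`. Valid for indentation depths much smaller than the
#' bead radius; no adhesion.
#'
#' @param depth indentation depth h (m, >= 0); vectorized.
#' @param contact a [contact_config()].
#' @param shear_modulus sample shear modulus G (Pa, >= 0).
#' @return force in N.
#' @export
hertz_force <- function(depth, contact, shear_modulus) {
  stopifnot(inherits(contact, "contact_config"))
  if (any(depth < 0))
    stop("hertz_force: negative depth (no adhesion model)", call. = FALSE)
  e_eff <- effective_modulus(shear_modulus, contact$poisson_ratio)
  (4 / 3) * e_eff * sqrt(contact$bead_radius) * depth^1.5
}

#' Dynamic contact stiffness about a static depth
#'
#' The linearization of the Hertzian force about the static operating
#' depth: `S = dF/dh |_{h0} = 2 E_eff sqrt(R h0)`. This is the quantity
#' that links small oscillation amplitudes to the complex modulus.
#'
#' @param static_depth operating depth h0 (m, > 0).
#' @param contact a [contact_config()].
#' @param effective_modulus reduced modulus `E_eff = E/(1-nu^2)` (Pa).
#' @return stiffness in N/m.
#' @export
dynamic_stiffness <- function(static_depth, contact, effective_modulus) {
  stopifnot(inherits(contact, "contact_config"))
  if (any(static_depth <= 0))
    stop("dynamic_stiffness: 'static_depth' must be > 0", call. = FALSE)
  2 * effective_modulus * sqrt(contact$bead_radius * static_depth)
}

#' Shear modulus from compression modulus via Poisson's ratio
#'
#' `G = E / (2 (1 + nu))`; with `nu = 0.5` (incompressible) this is
#' exactly `G = E / 3`.
#'
#' @param E compression (Young's) modulus, Pa, >= 0.
#' @param poisson_ratio Poisson's ratio, in `(-1, 0.5]`.
#' @return shear modulus G in Pa.
#' @export
shear_from_compression <- function(E, poisson_ratio) {
  if (!is.numeric(poisson_ratio) || any(poisson_ratio <= -1) ||
      any(poisson_ratio > 0.5))
    stop("shear_from_compression: 'poisson_ratio' must lie in (-1, 0.5]",
         call. = FALSE)
  if (any(E < 0))
    stop("shear_from_compression: 'E' must be >= 0", call. = FALSE)
  E / (2 * (1 + poisson_ratio))
}

#' Complex shear moduli from an oscillatory indentation observation
#'
#' Inverts the linearized oscillatory Hertzian solution: with force
#' amplitude `F1`, indentation amplitude `h1`, phase lag `phi` of the
#' indentation behind the load, and static depth `h0`,
#' \deqn{G' = (1-\nu) F_1 \cos\phi / (4 h_1 \sqrt{R h_0}), \quad
#'       G'' = (1-\nu) F_1 \sin\phi / (4 h_1 \sqrt{R h_0}).}
#' This is algebraically the complex dynamic stiffness
#' `E* = (1-nu^2) (F1/h1) e^{i phi} / (2 sqrt(R h0))` followed by the
#' conversion `G = E / (2 (1 + nu))`.
#'
#' Rows violating quality bounds are flagged, not dropped:
#' `linearity` if `h1/h0` exceeds `linearity_bound`, `geometry` if
#' `h0/R` exceeds `geometry_bound`, `phase_range` if `phi` falls outside
#' `[0, pi/2)` (a passive sample cannot produce it; the row is unreliable).
#'
#' @param observation list or data frame with elements/columns
#'   `frequency` (Hz), `F1` (N), `h1` (m), `phase` (rad), `h0` (m).
#' @param contact a [contact_config()].
#' @param linearity_bound maximum `h1/h0` for the linearization (default 0.05).
#' @param geometry_bound maximum `h0/R` (default 0.4).
#' @return data frame with columns `frequency`, `storage`, `loss`,
#'   `qc_flags` (comma-joined, empty string when clean).
#' @export
moduli_from_oscillation <- function(observation, contact,
                                    linearity_bound = 0.05,
                                    geometry_bound = 0.4) {
  stopifnot(inherits(contact, "contact_config"))
  obs <- as.data.frame(observation)
  need <- c("frequency", "F1", "h1", "phase", "h0")
  if (!all(need %in% names(obs)))
    stop("moduli_from_oscillation: observation needs fields ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(obs$F1 <= 0) || any(obs$h1 <= 0) || any(obs$h0 <= 0))
    stop("moduli_from_oscillation: F1, h1, h0 must be > 0", call. = FALSE)
  nu <- contact$poisson_ratio
  R <- contact$bead_radius
  scale <- (1 - nu) * obs$F1 / (4 * obs$h1 * sqrt(R * obs$h0))
  storage <- scale * cos(obs$phase)
  loss <- scale * sin(obs$phase)
  flags <- lapply(seq_len(nrow(obs)), function(i) {
    f <- character(0)
    if (obs$h1[i] / obs$h0[i] > linearity_bound) f <- c(f, "linearity")
    if (obs$h0[i] / R > geometry_bound) f <- c(f, "geometry")
    if (obs$phase[i] < 0 || obs$phase[i] >= pi / 2) f <- c(f, "phase_range")
    f
  })
  data.frame(frequency = obs$frequency, storage = storage, loss = loss,
             qc_flags = vapply(flags, paste, "", collapse = ","),
             stringsAsFactors = FALSE)
}
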