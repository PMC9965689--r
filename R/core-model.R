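# Forward physics of the impedance probe: equivalent-circuit impedance of the
# branch dielectric mixture and the reflection-voltage transfer function on
# the coaxial line, plus the resistive inverse used for round-trip testing.

#' Vacuum permittivity (F/m)
#'
#' Fixed physical constant used throughout the dielectric model.
#' @keywords internal
EPS0 <- 8.85e-12

#' Equivalent RC circuit of branch tissue
#'
#' Branch tissue is modelled as a porous dielectric mixture of gas, liquid and
#' solid phases, each contributing a parallel resistance and a capacitance.
#'
#' @param Rg,Rl,Rs Resistance (Ohm) of the gas, liquid and solid phases; all
#'   must be strictly positive (use a very large value for an absent phase).
#' @param Cg,Cl,Cs Capacitance (F) of the three phases; all must be >= 0.
#' @return An object of class `equivalent_circuit`.
#' @examples
#' equivalent_circuit(Rg = 1e9, Rl = 100, Rs = 1e6, Cg = 0, Cl = 1e-12, Cs = 0)
#' @export
equivalent_circuit <- function(Rg, Rl, Rs, Cg = 0, Cl = 0, Cs = 0) {
  r <- c(Rg = Rg, Rl = Rl, Rs = Rs)
  if (any(!is.finite(r) & !is.infinite(r)) || any(r <= 0)) {
    stop("all phase resistances must be > 0 (got ",
         paste(sprintf("%s=%g", names(r), r), collapse = ", "), ")",
         call. = FALSE)
  }
  cc <- c(Cg = Cg, Cl = Cl, Cs = Cs)
  if (any(cc < 0)) {
    stop("all phase capacitances must be >= 0", call. = FALSE)
  }
  structure(list(Rg = Rg, Rl = Rl, Rs = Rs, Cg = Cg, Cl = Cl, Cs = Cs),
            class = "equivalent_circuit")
}

#' Three-phase volumetric composition of a branch
#'
#' Volumes of the gas, liquid and solid phases within a total branch volume,
#' together with the relative permittivity of each phase. Liquid water has
#' permittivity ~81, ice and woody solids ~3, which is why the liquid volume
#' dominates the imaginary impedance and makes the measurement possible.
#'
#' @param V Total branch volume (m^3).
#' @param Vg,Vl,Vs Gas / liquid / solid volumes (m^3); each >= 0 and their sum
#'   must not exceed `V`.
#' @param eps_g,eps_l,eps_s Relative permittivities (dimensionless); defaults
#'   1 (gas), 81 (liquid water), 3 (solids/ice).
#' @return An object of class `phase_composition`.
#' @export
phase_composition <- function(V, Vg = 0, Vl = 0, Vs = 0,
                              eps_g = 1, eps_l = 81, eps_s = 3) {
  if (V <= 0) stop("total volume V must be > 0", call. = FALSE)
  if (any(c(Vg, Vl, Vs) < 0)) stop("phase volumes must be >= 0", call. = FALSE)
  if (Vg + Vl + Vs > V * (1 + 1e-12)) {
    stop("phase volumes exceed total branch volume (Vg + Vl + Vs > V)",
         call. = FALSE)
  }
  if (eps_l < 1 || eps_s < 1 || eps_g < 1 - 1e-12) {
    stop("relative permittivities must be >= 1", call. = FALSE)
  }
  structure(list(V = V, Vg = Vg, Vl = Vl, Vs = Vs,
                 eps_g = eps_g, eps_l = eps_l, eps_s = eps_s),
            class = "phase_composition")
}

#' Probe and measurement-circuit constants
#'
#' Physical constants of the probe and the reflection measurement circuit:
#' electrode geometry factor, operating angular frequency, coaxial line
#' impedance, amplification and excitation amplitude.
#'
#' @param frequency_hz Excitation frequency (Hz); default 1e8 (100 MHz, the
#'   frequency at which inter-species variability is minimised and branch
#'   reactance remains capacitive).
#' @param z_line_ohm Coaxial transmission line impedance (Ohm), default 50.
#' @param beta0 Signal amplification (dimensionless), > 0.
#' @param amplitude_v Excitation source amplitude (V), > 0.
#' @param k_geo_m Electrode geometry factor (m). Determined by electrode
#'   geometry; default 1e-3 is a documented config constant.
#' @param eps_g,eps_l,eps_s Default phase permittivities carried along for
#'   mixture calculations.
#' @return An object of class `probe_physics` with fields `w` (angular
#'   frequency, rad/s) and `eps0` (vacuum permittivity, fixed).
#' @seealso [default_probe_physics()] for the calibrated default amplification.
#' @export
probe_physics <- function(frequency_hz = 1e8, z_line_ohm = 50, beta0 = 1,
                          amplitude_v = 1, k_geo_m = 1e-3,
                          eps_g = 1, eps_l = 81, eps_s = 3) {
  if (frequency_hz <= 0) stop("frequency_hz must be > 0", call. = FALSE)
  if (z_line_ohm <= 0) stop("z_line_ohm must be > 0", call. = FALSE)
  if (beta0 <= 0) stop("beta0 must be > 0", call. = FALSE)
  if (amplitude_v <= 0) stop("amplitude_v must be > 0", call. = FALSE)
  if (k_geo_m <= 0) stop("k_geo_m must be > 0", call. = FALSE)
  structure(list(frequency_hz = frequency_hz,
                 w = 2 * pi * frequency_hz,
                 ZL = z_line_ohm,
                 beta0 = beta0,
                 A = amplitude_v,
                 k_geo = k_geo_m,
                 eps0 = EPS0,
                 eps_g = eps_g, eps_l = eps_l, eps_s = eps_s),
            class = "probe_physics")
}

#' Default probe physics with span-calibrated amplification
#'
#' Returns [probe_physics()] defaults with `beta0` solved so that sweeping the
#' liquid fraction from 0 to 100% of the branch volume (the all-ice to
#' all-water extremes) spans `target_span_v` volts of output, the full-scale
#' voltage change observed when a water sample freezes completely (1.574 V).
#' The output is linear in `beta0`, so the solve is closed-form.
#'
#' @param target_span_v Full-scale output span (V), default 1.574.
#' @param r_total_ohm Mixture parallel resistance assumed during the sweep
#'   (Ohm); default 10, within the 0-20 Ohm band observed at 100 MHz.
#' @param ... Passed to [probe_physics()] (everything except `beta0`).
#' @return A `probe_physics` object.
#' @export
default_probe_physics <- function(target_span_v = 1.574, r_total_ohm = 10,
                                  ...) {
  ph1 <- probe_physics(beta0 = 1, ...)
  u_at <- function(frac) {
    comp <- phase_composition(V = 1, Vl = frac, eps_l = ph1$eps_l)
    probe_voltage(mixture_impedance(comp, r_total_ohm, ph1,
                                    mode = "simplified"), ph1)
  }
  span1 <- u_at(1) - u_at(0)
  probe_physics(beta0 = target_span_v / span1, ...)
}

#' Complex impedance as resistance + reactance
#'
#' @param resistance Real part (Ohm); >= 0 for physical branches.
#' @param reactance Imaginary part (Ohm); sign free.
#' @return An object of class `complex_impedance`; coerce with
#'   `as.complex()`.
#' @export
complex_impedance <- function(resistance, reactance = 0) {
  if (any(resistance < 0)) {
    stop("resistance (real part) must be >= 0 for a physical branch",
         call. = FALSE)
  }
  structure(list(resistance = resistance, reactance = reactance),
            class = "complex_impedance")
}

#' @export
as.complex.complex_impedance <- function(x, ...) {
  complex(real = x$resistance, imaginary = x$reactance)
}

#' @export
print.complex_impedance <- function(x, ...) {
  sgn <- ifelse(x$reactance < 0, "-", "+")
  cat(sprintf("<impedance> %g %s %gj Ohm\n",
              x$resistance, sgn, abs(x$reactance)))
  invisible(x)
}

as_impedance <- function(z) {
  if (inherits(z, "complex_impedance")) return(z)
  if (is.complex(z)) return(complex_impedance(Re(z), Im(z)))
  if (is.numeric(z)) return(complex_impedance(z, 0))
  stop("cannot interpret object of class ", class(z)[1], " as an impedance",
       call. = FALSE)
}

#' Total parallel resistance of the three-phase circuit
#'
#' Harmonic combination `Rg // Rl // Rs` of the phase resistances.
#'
#' @param circuit An [equivalent_circuit()].
#' @return Total parallel resistance (Ohm), always below the smallest branch.
#' @examples
#' parallel_resistance(equivalent_circuit(10, 20, 40)) # 40/7
#' @export
parallel_resistance <- function(circuit) {
  stopifnot(inherits(circuit, "equivalent_circuit"))
  1 / (1 / circuit$Rg + 1 / circuit$Rl + 1 / circuit$Rs)
}

#' Total impedance of the equivalent circuit
#'
#' Real part is the parallel resistance; imaginary part is
#' `w * (Cg + Cl + Cs)`, the printed form of the lumped model.
#'
#' @param circuit An [equivalent_circuit()].
#' @param physics A [probe_physics()] supplying the angular frequency.
#' @return A [complex_impedance()].
#' @export
circuit_impedance <- function(circuit, physics) {
  stopifnot(inherits(physics, "probe_physics"))
  complex_impedance(parallel_resistance(circuit),
                    physics$w * (circuit$Cg + circuit$Cl + circuit$Cs))
}

#' Relative permittivity from capacitance (and back)
#'
#' For a probe with geometry factor `k_geo`, `eps_r = C / (k_geo * eps0)`.
#' `capacitance_from_permittivity()` is the exact inverse.
#'
#' @param C Capacitance (F), >= 0.
#' @param physics A [probe_physics()] (uses `k_geo`, `eps0`).
#' @return Relative permittivity (dimensionless).
#' @export
permittivity_from_capacitance <- function(C, physics) {
  stopifnot(inherits(physics, "probe_physics"))
  if (any(C < 0)) stop("capacitance must be >= 0", call. = FALSE)
  if (physics$k_geo <= 0) stop("k_geo must be > 0", call. = FALSE)
  C / (physics$k_geo * physics$eps0)
}

#' @rdname permittivity_from_capacitance
#' @param eps_r Relative permittivity (dimensionless), >= 1 or 0 for vacuum
#'   bookkeeping.
#' @export
capacitance_from_permittivity <- function(eps_r, physics) {
  stopifnot(inherits(physics, "probe_physics"))
  eps_r * physics$k_geo * physics$eps0
}

#' Impedance of a three-phase dielectric mixture
#'
#' Replaces the lumped capacitances with the volume-weighted permittivity sum
#' over the gas, liquid and solid phases. In `"simplified"` mode only the
#' liquid term is kept: gas permittivity is ~1 with a small volume share and
#' solid/ice permittivity is ~3 and changes slowly, so the liquid water volume
#' dominates the imaginary part. That dominance is the physical basis of the
#' measurement: the imaginary part is strictly increasing in the liquid
#' volume.
#'
#' @param comp A [phase_composition()].
#' @param R_total Total parallel resistance of the mixture (Ohm), > 0.
#' @param physics A [probe_physics()].
#' @param mode `"full"` (all three phase terms) or `"simplified"` (liquid
#'   only).
#' @return A [complex_impedance()].
#' @export
mixture_impedance <- function(comp, R_total, physics,
                              mode = c("full", "simplified")) {
  stopifnot(inherits(comp, "phase_composition"),
            inherits(physics, "probe_physics"))
  mode <- match.arg(mode)
  if (R_total <= 0) stop("R_total must be > 0", call. = FALSE)
  if (comp$Vl > comp$V) stop("liquid volume exceeds branch volume",
                             call. = FALSE)
  wsum <- comp$Vl / comp$V * comp$eps_l
  if (mode == "full") {
    wsum <- wsum + comp$Vg / comp$V * comp$eps_g + comp$Vs / comp$V * comp$eps_s
  }
  complex_impedance(R_total, physics$w * physics$k_geo * physics$eps0 * wsum)
}

#' Amplified reflection voltage at the probe
#'
#' The high-frequency wave reflected at the probe/line interface produces a
#' potential difference across the coaxial line that is amplified to an
#' analog DC level: `U = 2 * beta0 * A * Re((ZP - ZL) / (ZP + ZL))`, the
#' signed real projection of the complex reflection expression. For passive
#' loads (`Re(ZP) >= 0`) the reflection coefficient magnitude is at most 1,
#' so `|U| <= 2 * beta0 * A`; `U = 0` exactly for a matched load `ZP = ZL`.
#'
#' @param ZP Probe impedance: a [complex_impedance()], complex, or numeric
#'   (purely resistive) value.
#' @param physics A [probe_physics()].
#' @return Output voltage (V), scalar or vector following `ZP`.
#' @examples
#' ph <- probe_physics(beta0 = 1, amplitude_v = 1)
#' probe_voltage(150, ph) # reflection 0.5 -> 1 V
#' @export
probe_voltage <- function(ZP, physics) {
  stopifnot(inherits(physics, "probe_physics"))
  # accept any load here (no physicality check): the reflection expression
  # itself is defined for all ZP != -ZL
  z <- if (inherits(ZP, "complex_impedance")) as.complex(ZP) else
    as.complex(ZP)
  if (any(abs(z + physics$ZL) == 0)) {
    stop("ZP = -ZL: reflection expression is singular", call. = FALSE)
  }
  2 * physics$beta0 * physics$A * Re((z - physics$ZL) / (z + physics$ZL))
}

#' Resistive probe impedance from an output voltage
#'
#' Inverse of [probe_voltage()] restricted to purely resistive loads, used to
#' close simulator round trips. With `g = U / (2 * beta0 * A)` the unique
#' passive resistive solution is `ZP = ZL * (1 + g) / (1 - g)`, defined for
#' `|g| < 1`.
#'
#' @param U Output voltage (V) with `|U| < 2 * beta0 * A`.
#' @param physics A [probe_physics()].
#' @return A [complex_impedance()] with zero reactance.
#' @export
impedance_from_voltage <- function(U, physics) {
  stopifnot(inherits(physics, "probe_physics"))
  g <- U / (2 * physics$beta0 * physics$A)
  if (any(abs(g) >= 1)) {
    stop("|U| >= 2*beta0*A: no passive resistive load produces this voltage",
         call. = FALSE)
  }
  complex_impedance(physics$ZL * (1 + g) / (1 - g), 0)
}

#' Read probe/circuit constants from a config file
#'
#' Accepts either JSON (`.json`) or plain `key = value` text. Recognised keys:
#' `frequency_hz`, `z_line_ohm`, `beta0`, `amplitude_v`, `k_geo_m`, `eps_l`,
#' `eps_s`, `eps_g`. Unknown keys are rejected; missing keys fall back to the
#' [probe_physics()] defaults.
#'
#' @param path Path to the config file.
#' @return A `probe_physics` object.
#' @export
read_probe_config <- function(path) {
  if (!file.exists(path)) {
    stop("probe config file not found: ", path, call. = FALSE)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- strsplit(lines, "[=:]")
    bad <- vapply(kv, length, 1L) != 2L
    if (any(bad)) {
      stop("malformed config line: '", lines[which(bad)[1]], "'",
           call. = FALSE)
    }
    vals <- lapply(kv, function(p) as.numeric(trimws(p[2])))
    names(vals) <- vapply(kv, function(p) trimws(p[1]), "")
  }
  allowed <- c("frequency_hz", "z_line_ohm", "beta0", "amplitude_v",
               "k_geo_m", "eps_l", "eps_s", "eps_g")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0) {
    stop("unknown probe config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- lapply(vals, as.numeric)
  if (any(vapply(vals, function(v) length(v) != 1 || is.na(v), TRUE))) {
    stop("all probe config values must be single numbers", call. = FALSE)
  }
  do.call(probe_physics, vals)
}
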