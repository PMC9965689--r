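# Forward physics: parallel resistance, circuit/mixture impedance,
# reflection voltage and its resistive inverse.

test_that("parallel_resistance matches the harmonic-sum oracle", {
  # independent oracle: explicit harmonic sum
  harm <- function(r) 1 / sum(1 / r)
  expect_equal(parallel_resistance(equivalent_circuit(30, 30, 30)), 10)
  expect_equal(parallel_resistance(equivalent_circuit(Inf, 100, Inf)), 100)
  expect_equal(parallel_resistance(equivalent_circuit(10, 20, 40)),
               harm(c(10, 20, 40)))
  expect_equal(parallel_resistance(equivalent_circuit(10, 20, 40)), 40 / 7)
  set.seed(7)
  for (i in 1:25) {
    r <- stats::runif(3, 1, 1e4)
    circ <- equivalent_circuit(r[1], r[2], r[3])
    expect_equal(parallel_resistance(circ), harm(r))
    expect_lt(parallel_resistance(circ), min(r))
  }
  expect_error(equivalent_circuit(-1, 10, 10), "resistances must be > 0")
  expect_error(equivalent_circuit(0, 10, 10), "resistances must be > 0")
})

test_that("circuit_impedance follows the printed lumped form R + j*w*sum(C)", {
  ph_w1 <- probe_physics(frequency_hz = 1 / (2 * pi)) # w = 1 rad/s
  z <- circuit_impedance(equivalent_circuit(3, 3, 3, Cg = 1, Cl = 1, Cs = 0),
                         ph_w1)
  expect_equal(z$resistance, 1) # three 3-Ohm branches in parallel
  expect_equal(z$reactance, 2)  # w * (Cg + Cl + Cs) = 1 * 2

  # zero capacitance -> purely real
  z0 <- circuit_impedance(equivalent_circuit(10, 20, 40), ph_w1)
  expect_identical(z0$reactance, 0)

  # imaginary part linear in w, real part unchanged
  ph_w2 <- probe_physics(frequency_hz = 2 / (2 * pi))
  circ <- equivalent_circuit(5, 7, 11, Cg = 1e-12, Cl = 3e-12, Cs = 2e-12)
  z1 <- circuit_impedance(circ, ph_w1)
  z2 <- circuit_impedance(circ, ph_w2)
  expect_equal(z2$reactance, 2 * z1$reactance)
  expect_equal(z2$resistance, z1$resistance)
})

test_that("permittivity <-> capacitance is an exact inverse pair", {
  ph <- probe_physics()
  expect_equal(permittivity_from_capacitance(ph$k_geo * ph$eps0, ph), 1)
  expect_equal(permittivity_from_capacitance(81 * ph$k_geo * ph$eps0, ph), 81)
  eps <- c(1, 3, 81, 12.5)
  back <- permittivity_from_capacitance(
    capacitance_from_permittivity(eps, ph), ph)
  expect_equal(back, eps, tolerance = 1e-12)
  expect_error(permittivity_from_capacitance(-1e-12, ph), ">= 0")
})

test_that("mixture_impedance: simplified keeps only the liquid term", {
  ph <- probe_physics()
  dry <- phase_composition(V = 1, Vl = 0, Vg = 0.3, Vs = 0.5)
  expect_identical(mixture_impedance(dry, 10, ph, "simplified")$reactance, 0)

  wet <- phase_composition(V = 1, Vl = 1, eps_l = 81)
  expect_equal(mixture_impedance(wet, 10, ph, "simplified")$reactance,
               ph$w * ph$k_geo * ph$eps0 * 81)

  # full vs simplified differ exactly by the gas and solid terms
  comp <- phase_composition(V = 2, Vg = 0.4, Vl = 0.8, Vs = 0.6,
                            eps_g = 1, eps_l = 81, eps_s = 3)
  full <- mixture_impedance(comp, 10, ph, "full")$reactance
  simp <- mixture_impedance(comp, 10, ph, "simplified")$reactance
  extra <- ph$w * ph$k_geo * ph$eps0 *
    (comp$Vg / comp$V * comp$eps_g + comp$Vs / comp$V * comp$eps_s)
  expect_equal(full - simp, extra)

  # with Vg = Vs = 0 the two modes agree exactly
  lonly <- phase_composition(V = 1, Vl = 0.4)
  expect_equal(mixture_impedance(lonly, 10, ph, "full")$reactance,
               mixture_impedance(lonly, 10, ph, "simplified")$reactance)

  # strictly increasing in Vl
  xs <- vapply(seq(0, 1, by = 0.1), function(vl) {
    mixture_impedance(phase_composition(V = 1, Vl = vl), 10, ph,
                      "simplified")$reactance
  }, numeric(1))
  expect_true(all(diff(xs) > 0))

  expect_error(phase_composition(V = 1, Vl = 1.5), "exceed")
})

test_that("probe_voltage implements the reflection transfer function", {
  ph <- probe_physics(beta0 = 1, amplitude_v = 1)
  expect_equal(probe_voltage(50, ph), 0)           # matched load
  expect_equal(probe_voltage(150, ph), 1.0)        # Gamma = 0.5
  expect_equal(probe_voltage(1e12, ph), 2, tolerance = 1e-9) # open
  expect_no_error(probe_voltage(complex_impedance(0, 0), probe_physics()))
  expect_error(probe_voltage(complex(real = -50, imaginary = 0), ph),
               "singular")

  # amplification scales linearly
  ph5 <- probe_physics(beta0 = 5, amplitude_v = 2)
  expect_equal(probe_voltage(150, ph5), 10 * probe_voltage(150, ph))
})

test_that("reflection bound holds for all passive loads", {
  ph <- probe_physics(beta0 = 2, amplitude_v = 1.5)
  set.seed(11)
  re <- stats::runif(200, 0, 1e4)
  im <- stats::runif(200, -1e4, 1e4)
  u <- probe_voltage(complex(real = re, imaginary = im), ph)
  expect_true(all(abs(u) <= 2 * ph$beta0 * ph$A + 1e-12))
})

test_that("impedance_from_voltage inverts probe_voltage on resistive loads", {
  ph <- probe_physics(beta0 = 1, amplitude_v = 1)
  expect_equal(impedance_from_voltage(0, ph)$resistance, 50)
  expect_equal(impedance_from_voltage(1.0, ph)$resistance, 150)
  # round trip over a resistive grid up to 10 * ZL
  zp <- seq(0.5, 10 * ph$ZL, length.out = 60)
  back <- impedance_from_voltage(probe_voltage(zp, ph), ph)$resistance
  expect_equal(back, zp, tolerance = 1e-9)
  expect_error(impedance_from_voltage(2.0, ph), "no passive")
  expect_error(impedance_from_voltage(-2.5, ph), "no passive")
})

test_that("default_probe_physics spans the full-scale voltage", {
  ph <- default_probe_physics()
  u_at <- function(frac) {
    probe_voltage(mixture_impedance(phase_composition(1, Vl = frac), 10, ph,
                                    "simplified"), ph)
  }
  # the solve is linear in beta0 but the reflection real part sits on a
  # large offset, so cancellation limits agreement to ~1e-7 relative
  expect_equal(u_at(1) - u_at(0), 1.574, tolerance = 1e-6)
})

test_that("probe config round-trips through key=value and JSON files", {
  kv <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# probe constants", "frequency_hz = 1e8",
               "z_line_ohm = 50", "beta0 = 2.5", "amplitude_v = 1.2",
               "k_geo_m = 2e-3"), kv)
  ph <- read_probe_config(kv)
  expect_equal(ph$beta0, 2.5)
  expect_equal(ph$k_geo, 2e-3)
  expect_equal(ph$w, 2 * pi * 1e8)

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(frequency_hz = 5e7, beta0 = 3), js,
                       auto_unbox = TRUE)
  expect_equal(read_probe_config(js)$frequency_hz, 5e7)

  bad <- withr::local_tempfile(fileext = ".cfg")
  writeLines("not_a_key = 1", bad)
  expect_error(read_probe_config(bad), "unknown probe config key")
})
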