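test_that("parameter table reproduces the canonical rows and expands by strand symmetry", {
  tab <- step_param_table()
  expect_equal(nrow(tab), 16L)

  expect_equal(unlist(tab["AA", c("k_rho", "k_tau", "rho0", "tau0")]),
               c(k_rho = 0.2, k_tau = 0.406, rho0 = 0.76, tau0 = -1.84))
  expect_equal(unlist(tab["CG", c("k_rho", "k_tau", "rho0", "tau0")]),
               c(k_rho = 0.04, k_tau = 0.255, rho0 = 4.25, tau0 = 0))
  # complement of AA: shared stiffness and roll, flipped tilt
  expect_equal(unlist(tab["TT", c("k_rho", "k_tau", "rho0", "tau0")]),
               c(k_rho = 0.2, k_tau = 0.406, rho0 = 0.76, tau0 = 1.84))

  # brute-force symmetry check over all 16 steps
  for (s in tab$step) {
    rc <- revcomp(s)
    expect_equal(tab[s, "k_rho"], tab[rc, "k_rho"])
    expect_equal(tab[s, "k_tau"], tab[rc, "k_tau"])
    expect_equal(tab[s, "rho0"], tab[rc, "rho0"])
    expect_equal(tab[s, "tau0"], -tab[rc, "tau0"])
  }
  for (s in c("AT", "TA", "GC", "CG")) expect_identical(tab[s, "tau0"], 0)
  expect_true(all(tab$k_rho > 0) && all(tab$k_tau > 0))
})

test_that("parameter table rejects invalid inputs", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("step\tk_rho\tk_tau\trho0\ttau0", "AT\t-0.1\t0.6\t1\t0"), bad)
  expect_error(step_param_table(bad), "positive")
  writeLines(c("step\tk_rho\tk_tau\trho0\ttau0", "AT\t0.1\t0.6\t1\t0.5"), bad)
  expect_error(step_param_table(bad), "self-complementary")
  writeLines(c("step\tk_rho\tk_tau\trho0\ttau0", "AT\t0.1\t0.6\t1\t0"), bad)
  expect_error(step_param_table(bad), "no parameters")
})

test_that("accumulated twist is the half-step phase plus full twists, antisymmetric", {
  expect_equal(accumulated_twist(1, 34.8), 17.4)
  expect_equal(accumulated_twist(-1, 34.8), -17.4)
  expect_equal(accumulated_twist(3, 34.8), 87.0)
  i <- c(-64:-1, 1:64)
  expect_equal(accumulated_twist(i, 34.8), -accumulated_twist(-i, 34.8))
  expect_error(accumulated_twist(0), "invalid step index")
  expect_error(accumulated_twist(65), "invalid step index")
})

test_that("geometry constants are validated", {
  g <- elastic_geometry()
  expect_equal(g$alpha_total, 579)
  expect_equal(g$omega, 34.8)
  expect_equal(g$max_step, 64L)
  expect_error(elastic_geometry(contact_len = 128), "odd")
  expect_error(elastic_geometry(contact_len = 149, core_len = 147), "exceed")
})

test_that("torque has the closed form when equilibrium angles vanish", {
  tab <- step_param_table()
  tab$rho0[] <- 0
  tab$tau0[] <- 0
  set.seed(11)
  w <- random_dna(129)
  Om <- accumulated_twist(c(-64:-1, 1:64), 34.8) * pi / 180
  b <- strsplit(w, "")[[1]]
  steps <- vapply(c(-64:-1, 1:64), function(i) {
    first <- if (i > 0) 65 + i - 1 else 65 + i
    paste0(b[first], b[first + 1])
  }, "")
  denom <- sum(cos(Om)^2 / tab[steps, "k_rho"] +
               sin(Om)^2 / tab[steps, "k_tau"])
  expect_equal(torque(w, tab), 579 / denom, tolerance = 1e-12)
})

test_that("torque and placement energy match the brute-force oracle", {
  tab <- step_param_table()
  set.seed(42)
  for (gc in c(0.2, 0.5, 0.8)) {
    for (rep in 1:8) {
      w <- random_dna(129, gc)
      ora <- oracle_placement(w)
      expect_equal(torque(w, tab), ora$F_b, tolerance = 1e-9)
      pe <- placement_energy(w, tab, per_step = TRUE)
      expect_equal(pe$E_total, ora$E, tolerance = 1e-9)
      expect_equal(sum(pe$per_step$E), pe$E_total, tolerance = 1e-12)
      expect_gte(pe$E_total, 0)
    }
  }
  # poly-A window, the spec's fixed case
  expect_equal(placement_energy(strrep("A", 129), tab)$E_total,
               oracle_placement(strrep("A", 129))$E, tolerance = 1e-9)
})

test_that("placement energy is strand symmetric", {
  tab <- step_param_table()
  set.seed(7)
  for (rep in 1:30) {
    w <- random_dna(129, stats::runif(1, 0.25, 0.75))
    expect_equal(placement_energy(revcomp(w), tab)$E_total,
                 placement_energy(w, tab)$E_total, tolerance = 1e-9)
    expect_equal(torque(revcomp(w), tab), torque(w, tab), tolerance = 1e-9)
  }
})

test_that("realised bend angle is conserved at alpha_total", {
  tab <- step_param_table()
  set.seed(5)
  for (rep in 1:20) {
    expect_equal(total_bend_angle(random_dna(129), tab), 579,
                 tolerance = 1e-6)
  }
  expect_equal(total_bend_angle(strrep("G", 129), tab), 579,
               tolerance = 1e-6)
  g0 <- elastic_geometry(alpha_total = 0)
  expect_equal(total_bend_angle(random_dna(129), tab, g0), 0,
               tolerance = 1e-6)
})

test_that("energy depends only on the contacted stretch", {
  tab <- step_param_table()
  set.seed(13)
  core <- random_dna(129)
  w1 <- paste0(random_dna(9), core, random_dna(9))
  w2 <- paste0(random_dna(9), core, random_dna(9))
  expect_equal(placement_energy(w1, tab)$E_total,
               placement_energy(w2, tab)$E_total)
  expect_equal(placement_energy(w1, tab)$E_total,
               placement_energy(core, tab)$E_total)
})

test_that("ambiguous bases make a placement undefined, short windows error", {
  tab <- step_param_table()
  w <- random_dna(129)
  substr(w, 60, 60) <- "N"
  expect_true(is.na(placement_energy(w, tab)$E_total))
  expect_true(is.na(torque(w, tab)))
  expect_true(is.na(total_bend_angle(w, tab)))
  expect_error(placement_energy(random_dna(99), tab), "shorter")
  expect_error(placement_energy(random_dna(130), tab), "odd")
})

test_that("energy landscape agrees with per-window scoring", {
  tab <- step_param_table()
  set.seed(3)
  s <- random_dna(200)
  land <- energy_landscape(s, tab)
  expect_equal(land$dyad, 64:135)
  for (k in c(1L, 30L, nrow(land))) {
    w <- substr(s, land$dyad[k] + 1L - 64L, land$dyad[k] + 1L + 64L)
    expect_equal(land$energy[k], placement_energy(w, tab)$E_total,
                 tolerance = 1e-12)
  }
})
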