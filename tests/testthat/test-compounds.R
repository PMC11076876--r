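test_that("degree of reduction matches the generalized formula", {
  cases <- list(ethanol = list(c(2, 6, 1), 6),
                acetic = list(c(2, 4, 2), 4),
                co2 = list(c(1, 0, 2), 0),
                caproic = list(c(6, 12, 2), 16 / 3),
                methane = list(c(1, 4, 0), 8))
  for (cs in cases) {
    expect_equal(degree_of_reduction(cs[[1]][1], cs[[1]][2], cs[[1]][3]),
                 cs[[2]])
  }
  # biomass CH1.8O0.5N0.2 on the NH3-referenced scale
  expect_equal(degree_of_reduction(1, 1.8, 0.5, 0.2), 4.2)
  expect_error(degree_of_reduction(0, 2, 0), "carbon-free")
})

test_that("registry covers the product spectrum with consistent masses", {
  reg <- compound_registry()
  must_have <- c("acetate", "propionate", "n-butyrate", "i-butyrate",
                 "n-valerate", "n-caproate", "n-caprylate", "ethanol",
                 "propanol", "butanol", "hexanol", "co2", "h2", "ch4", "n2")
  expect_true(all(must_have %in% reg$name))
  # molar mass column agrees with the atom counts
  am <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)
  mw <- reg$n_C * am["C"] + reg$n_H * am["H"] + reg$n_O * am["O"] +
    reg$n_N * am["N"]
  expect_true(all(abs(mw - reg$molar_mass) <= 0.01))
  # gamma column is the formula applied to the atom counts
  carbon <- reg$n_C >= 1
  expect_equal(reg$gamma[carbon],
               (4 * reg$n_C + reg$n_H - 2 * reg$n_O - 3 * reg$n_N)[carbon] /
                 reg$n_C[carbon])
  expect_equal(reg$carbon_number, reg$n_C)
  # synonyms resolve
  expect_equal(resolve_compound(c("n-C6", "EtOH", "caproate", "i-C4")),
               c("n-caproate", "ethanol", "n-caproate", "i-butyrate"))
  expect_error(resolve_compound("unobtainium"), "unknown compound")
})

test_that("Cmol/mass conversions reproduce the printed reactor rates", {
  expect_equal(cmol_rate_to_mass_rate(163, "co2") / 1000, 7.17,
               tolerance = 0.005 / 7.17)
  expect_equal(cmol_rate_to_mass_rate(17.9, "hexanol") / 1000, 0.3,
               tolerance = 0.05 / 0.3)
  expect_equal(cmol_rate_to_mass_rate(7.6, "butanol"), 141,
               tolerance = 0.5 / 141)
  expect_equal(cmol_rate_to_mass_rate(15.9, "hexanol"), 271,
               tolerance = 0.5 / 271)
  expect_equal(cmol_rate_to_mass_rate(0, "n-caproate"), 0)
  expect_error(cmol_rate_to_mass_rate(1, "h2"), "no carbon")
})

test_that("mass/Cmol conversion round-trips to 1e-9 relative", {
  reg <- compound_registry()
  for (nm in reg$name[reg$n_C >= 1]) {
    x <- 137.423
    expect_equal(mass_rate_to_cmol_rate(cmol_rate_to_mass_rate(x, nm), nm),
                 x, tolerance = 1e-9)
  }
})

test_that("normal gas volumes convert via the molar volume", {
  expect_equal(gas_volume_to_moles(22.414), 1)
  expect_equal(gas_volume_to_moles(0), 0)
  # 6 NmL/min sustained for one day
  expect_equal(gas_volume_to_moles(6 * 1440), 8640 / 22.414)
  expect_equal(moles_to_gas_volume(gas_volume_to_moles(123.4)), 123.4)
  # overridable reference conditions
  expect_equal(gas_volume_to_moles(24, molar_volume = 24), 1)
  expect_error(gas_volume_to_moles(-1), "non-negative")
})

test_that("electron accounting closes for ethanol oxidation and every shipped reaction", {
  # EtOH + H2O -> acetate + 2 H2 is electron neutral on the adopted scale
  stoich <- c(ethanol = -1, h2o = -1, acetate = 1, h2 = 2)
  e <- sum(stoich * vapply(names(stoich), electrons_per_mol, numeric(1)))
  expect_equal(e, 0)
  rs <- reaction_set()
  epm <- vapply(rownames(rs$stoich), electrons_per_mol, numeric(1))
  expect_equal(unname(as.vector(epm %*% rs$stoich)),
               rep(0, ncol(rs$stoich)))
})
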