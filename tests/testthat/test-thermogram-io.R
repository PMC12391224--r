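test_that("wide and long dialects load to the identical thermogram set", {
  sim <- simulate_plate(mini_sim_config())
  wide <- withr::local_tempfile(fileext = ".csv")
  long <- withr::local_tempfile(fileext = ".tsv")
  write_thermograms(sim$thermograms, wide, format = "wide")
  write_thermograms(sim$thermograms, long, format = "long", sep = "\t")
  from_wide <- read_thermograms(wide, mini_layout())
  from_long <- read_thermograms(long, mini_layout())
  expect_equal(from_wide$powers, from_long$powers)
  expect_equal(from_wide$time_s, from_long$time_s)
})

test_that("reading the simulator's own output is the identity", {
  sim <- simulate_plate(mini_sim_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_thermograms(sim$thermograms, path)
  back <- read_thermograms(path, mini_layout())
  expect_equal(back$powers, sim$thermograms$powers, tolerance = 1e-12)
})

test_that("malformed trace files fail with informative errors", {
  lay <- mini_layout()
  sim <- simulate_plate(mini_sim_config())
  path <- withr::local_tempfile(fileext = ".csv")

  # a file holding only the reference wells names the missing sample wells
  refs_only <- data.frame(time_s = sim$thermograms$time_s,
                          sim$thermograms$powers[, c("A1", "F1", "A2", "F2")])
  data.table::fwrite(refs_only, path)
  expect_error(read_thermograms(path, lay), "4 well\\(s\\).*B1.*C2")

  # unknown well id is named
  refs_only$Z9 <- 0
  data.table::fwrite(refs_only, path)
  expect_error(read_thermograms(path, lay), "Z9")

  # non-monotone time (duplicated time point)
  full <- data.frame(time_s = sim$thermograms$time_s,
                     sim$thermograms$powers)
  broken <- rbind(full[1:10, ], full[10, ])
  data.table::fwrite(broken, path)
  expect_error(read_thermograms(path, lay), "strictly increasing")

  # an interior gap wider than twice the nominal interval is not interpolated
  gappy <- full[-(5:50), ]
  data.table::fwrite(gappy, path)
  expect_error(read_thermograms(path, lay), "gap")
})

test_that("heat table writes column-major with the documented header and round-trips", {
  sums <- tibble::tibble(
    well_id = c("D6", "B1"), group = c("Cells + Glucose", "No Cells"),
    total_heat_uJ = c(391500, 123.456), cells = c(150000L, 0L),
    heat_per_cell_uJ = c(2.61, NA)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_heat_table(sums, path)
  expect_identical(readLines(path, n = 1),
                   "well_id,group,total_heat_uJ,cells,heat_per_cell_uJ")
  back <- read_heat_table(path)
  expect_equal(back$well_id, c("B1", "D6"))  # column-major order
  row <- back[back$well_id == "D6", ]
  expect_equal(row$group, "Cells + Glucose")
  expect_equal(round(row$heat_per_cell_uJ, 2), 2.61)
  expect_equal(round(back$total_heat_uJ, 2), c(123.46, 391500))
  expect_error(write_heat_table(sums[0, ], path), "no heat summaries")
})
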