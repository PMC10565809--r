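test_that("loading capacity and efficiency reproduce the report arithmetic", {
  expect_equal(loading_capacity(9.0, 10), 100 * 9 / 19)
  expect_equal(report_rounding(loading_capacity(9.0, 10)), 47)
  expect_equal(loading_capacity(0, 10), 0)
  expect_equal(report_rounding(loading_capacity(19.3, 100)), 16)
  expect_equal(report_rounding(loading_capacity(2.4, 10)), 19)
  expect_error(loading_capacity(-1, 10), ">= 0")
  expect_error(loading_capacity(1, 0), "> 0")

  expect_equal(loading_efficiency(9.0, 10), 90)
  expect_equal(loading_efficiency(3.3, 3.3), 100)
  expect_equal(loading_efficiency(2.4, 8), 30)
  expect_warning(capped <- loading_efficiency(10.4, 10), "capping")
  expect_equal(capped, 100)
  expect_error(loading_efficiency(1, 0), "> 0")
})

test_that("LC is monotone in both arguments and inverts exactly", {
  sol <- seq(0, 9, by = 0.5)
  expect_false(is.unsorted(loading_capacity(sol, 10)))
  feeds <- seq(5, 100, by = 5)
  expect_false(is.unsorted(rev(loading_capacity(3, feeds))))

  expect_equal(solubility_from_lc(100 * 9 / 19, 10), 9.0)
  expect_equal(solubility_from_lc(0, 10), 0)
  expect_error(solubility_from_lc(100, 10), "< 100")
  set.seed(5)
  lc <- runif(1000, 0, 99); pf <- runif(1000, 1, 100)
  expect_equal(loading_capacity(solubility_from_lc(lc, pf), pf), lc,
               tolerance = 1e-9)
  # algebraic identity LC/(100-LC) = solubilized/polymer_feed
  sol <- runif(1000, 0, 50); pf <- runif(1000, 1, 100)
  lc2 <- loading_capacity(sol, pf)
  expect_equal(lc2 / (100 - lc2), sol / pf, tolerance = 1e-12)
})

test_that("stability summaries report retention and precipitation day", {
  rec <- formulation_record("pBuOx", "BT44", 10, 8,
                            solubility_from_lc(19, 10))
  s <- stability_series(rec, c(0, 1, 5, 15),
                        solubility_from_lc(c(19, 15, 10, 7), 10))
  out <- stability_summary(s)
  expect_equal(out$lc_by_day$lc, c(19, 15, 10, 7))
  expect_equal(out$retention_fraction, 7 / 19)   # about 0.37
  expect_true(is.na(out$time_to_complete_precipitation))

  const <- stability_series(rec, c(0, 5, 15), rep(rec$solubilized, 3))
  cs <- stability_summary(const)
  expect_equal(cs$retention_fraction, 1)
  expect_true(is.na(cs$time_to_complete_precipitation))

  gone <- stability_series(rec, c(0, 1, 5), c(rec$solubilized, 0, 0))
  expect_equal(stability_summary(gone)$time_to_complete_precipitation, 1)

  expect_error(stability_series(rec, c(0, 5, 1), c(2, 1, 1)),
               "strictly increasing")
  expect_error(stability_series(rec, c(1, 5, 15), c(2, 1, 1)), "day must be 0")
})

test_that("redispersion recovery and dosing arithmetic", {
  expect_equal(redispersion_recovery(16, 16, "cell_culture_media")$recovery, 1)
  r <- redispersion_recovery(16, 15, "saline")
  expect_equal(r$recovery, 0.9375)
  expect_identical(r$medium, "saline")
  expect_equal(redispersion_recovery(16, 0)$recovery, 0)
  expect_error(redispersion_recovery(0, 5), "> 0")

  expect_equal(required_concentration(50, 10)$required_gL, 5)
  expect_equal(required_concentration(25, 10)$required_gL, 2.5)
  expect_equal(required_concentration(0, 10)$required_gL, 0)
  expect_true(required_concentration(50, 10, 19.3)$feasible)
  expect_false(required_concentration(250, 10, 19.3)$feasible)

  expect_equal(mass_to_molar(0.64, 8100) * 1e6, 79, tolerance = 0.001)
  expect_equal(mass_to_molar(0.05776, 577.59) * 1e6, 100, tolerance = 1e-4)
  expect_equal(mass_to_molar(0, 500), 0)
  expect_error(mass_to_molar(1, 0), "> 0")
})

test_that("records and CSV input are validated with located errors", {
  expect_error(formulation_record("p", "d", 10, 2, 2.2), "tolerance")
  ok <- formulation_record("p", "d", 10, 2, 2.05)  # within 5%
  expect_equal(ok$solubilized, 2.05)

  path <- system.file("extdata", "bt44_formulations.csv",
                      package = "hspcompat")
  recs <- read_formulation_csv(path)
  expect_equal(nrow(recs), 25)
  expect_true(all(recs$solubilized <= recs$drug_feed * 1.05))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("polymer_id,drug_id,polymer_feed_gL,drug_feed_gL,solubilized_gL,day,medium",
               "p,d,10,2,1.5,0,water",
               "p,d,10,2,9.9,0,water"), bad)
  expect_error(read_formulation_csv(bad), "line 3")
  writeLines(c("polymer_id,drug_id,polymer_feed_gL,drug_feed_gL,solubilized_gL,day,medium",
               "p,d,10,2,1.5,zero,water"), bad)
  expect_error(read_formulation_csv(bad), "day")
})

test_that("formulation report recovers the observed solubilizer order", {
  recs <- read_formulation_csv(system.file("extdata",
                                           "bt44_formulations.csv",
                                           package = "hspcompat"))
  rep <- run_formulation_report(
    recs, predicted_order = c("pPrOx", "pBuOx", "pPentOx"))
  expect_identical(rep$observed_order, c("pPentOx", "pBuOx", "pPrOx"))
  expect_equal(rep$rank_agreement, -1)
  expect_equal(max(rep$per_record$lc_rounded), 47)
  stab <- rep$stability
  pbu <- stab[stab$polymer_id == "pBuOx" & stab$drug_feed == 8, ]
  expect_equal(pbu$retention_fraction,
               loading_capacity(0.75, 10) / loading_capacity(2.4, 10))
  expect_equal(report_rounding(pbu$lc_day0), 19)
  p2 <- stab[stab$polymer_id == "pPentOx" & stab$drug_feed == 2, ]
  expect_equal(p2$time_to_complete_precipitation, 1)
})
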