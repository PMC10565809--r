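tab <- load_group_table()

test_that("Fedors molar volume is an additive group sum", {
  v_ch3 <- tab$V_fedors[tab$name == "CH3"]
  expect_equal(fedors_molar_volume(c(CH3 = 2), tab), 2 * v_ch3)
  a <- c(CH3 = 2, CH2 = 3); b <- c(OH = 1, CO = 2)
  expect_equal(fedors_molar_volume(c(a, b), tab),
               fedors_molar_volume(a, tab) + fedors_molar_volume(b, tab))
  expect_error(fedors_molar_volume(integer(0), tab), "empty")
  # correction increments can drive the sum negative -> error
  expect_error(fedors_molar_volume(c(N = 2, ring_5plus = 1), tab),
               "non-positive")
})

test_that("single-group profile has the closed form (a/v, 0, 0)", {
  p <- hsp_from_groups(c(CH3 = 1), tab)
  v <- tab$V_fedors[tab$name == "CH3"]
  a <- tab$F_di[tab$name == "CH3"]
  expect_equal(p$delta_d, a / v)
  expect_equal(p$delta_p, 0)
  expect_equal(p$delta_h, 0)
  expect_equal(p$delta_total, a / v)
})

test_that("profiles are intensive: scaling counts and V leaves deltas fixed", {
  for (counts in list(c(CH3 = 1), c(CH2 = 2, OH = 1),
                      c(CH2 = 2, CO = 1, N = 1))) {
    v <- fedors_molar_volume(counts, tab)
    p1 <- hsp_from_groups(counts, tab, V = v)
    p4 <- hsp_from_groups(counts * 4, tab, V = 4 * v)
    expect_equal(p4$delta_d, p1$delta_d)
    expect_equal(p4$delta_p, p1$delta_p)
    expect_equal(p4$delta_h, p1$delta_h)
  }
})

test_that("delta_total obeys the root-sum-of-squares identity", {
  set.seed(11)
  for (i in 1:50) {
    counts <- random_counts(tab)
    p <- hsp_from_groups(counts, tab)
    expect_equal(p$delta_total^2,
                 p$delta_d^2 + p$delta_p^2 + p$delta_h^2,
                 tolerance = 1e-9)
    expect_gte(p$delta_total,
               max(p$delta_d, p$delta_p, p$delta_h) - 1e-12)
  }
})

test_that("hsp_from_groups matches the per-group summation oracle", {
  set.seed(23)
  for (i in 1:100) {
    counts <- random_counts(tab)
    V <- fedors_molar_volume(counts, tab)
    for (mode in c("linear", "rss")) {
      got <- hsp_from_groups(counts, tab, V = V, polar_sum = mode)
      want <- oracle_hsp(counts, tab, V, polar_sum = mode)
      expect_equal(c(got$delta_d, got$delta_p, got$delta_h, got$delta_total),
                   unname(want), tolerance = 1e-12)
    }
  }
})

test_that("oxazoline repeat-unit profile agrees with the hand spreadsheet", {
  # 2-n-propyl-2-oxazoline unit: CH3 + 4 CH2 + CO + N
  # Fd = 420 + 4*270 + 290 + 20 = 1810; Fp = 770 + 800 = 1570
  # Eh = 2000 + 5000 = 7000;  V = 33.5 + 4*16.1 + 10.8 - 9.0 = 99.7
  d <- decompose(pox_screen_molecules()$pPrOx, tab)
  p <- hsp_from_groups(d, tab)
  expect_equal(p$V, 99.7)
  expect_equal(p$delta_d, 1810 / 99.7)
  expect_equal(p$delta_p, 1570 / 99.7)
  expect_equal(p$delta_h, sqrt(7000 / 99.7))
  # orthodox polar form for comparison runs
  prss <- hsp_from_groups(d, tab, polar_sum = "rss")
  expect_equal(prss$delta_p, sqrt(770^2 + 800^2) / 99.7)
})

test_that("hansen_distance behaves as a metric in both weightings", {
  mk <- function(d, p, h) structure(
    list(molecule_id = "m", delta_d = d, delta_p = p, delta_h = h,
         delta_total = sqrt(d^2 + p^2 + h^2), V = 100),
    class = "hsp_profile")
  z <- mk(0, 0, 0); u <- mk(1, 0, 0)
  expect_equal(hansen_distance(u, u), 0)
  expect_equal(hansen_distance(u, z), 1)
  expect_equal(hansen_distance(u, z, weighted = TRUE), 2)
  set.seed(7)
  for (i in 1:200) {
    a <- random_profile(); b <- random_profile(); c <- random_profile()
    for (w in c(FALSE, TRUE)) {
      dab <- hansen_distance(a, b, w)
      expect_gte(dab, 0)
      expect_equal(dab, hansen_distance(b, a, w))
      expect_lte(hansen_distance(a, c, w),
                 dab + hansen_distance(b, c, w) + 1e-12)
    }
  }
})

test_that("legacy unit conversion scales by 2.0455", {
  expect_equal(mpa_from_cal(10), 20.455)
})
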