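solo <- printed_solo_ed50

test_that("additive ED50 reproduces published two-drug predictions", {
  cbz <- mixture_design(potency_estimate(solo["CBZ"], drug = "CBZ"),
                        data.frame(drug = "ISOP", dose = 25, ed50 = 235.7))
  expect_equal(additive_ed50(cbz)$ed50_add_total, 33.51, tolerance = 0.01 / 33.51)
  pb <- mixture_design(potency_estimate(solo["PB"], drug = "PB"),
                       data.frame(drug = "ISOP", dose = 50, ed50 = 235.7))
  expect_equal(additive_ed50(pb)$ed50_add_total, 72.73, tolerance = 0.01 / 72.73)
})

test_that("an empty mixture reduces the additive prediction to the drug alone", {
  varied <- potency_estimate(9.52, sem = 0.5, n = 16, drug = "CBZ")
  d <- mixture_design(varied, data.frame(drug = character(0),
                                         dose = numeric(0),
                                         ed50 = numeric(0)))
  add <- additive_ed50(d)
  expect_identical(add$ed50_add_total, varied$ed50)
  expect_identical(add$ed50_add_varied, varied$ed50)
  expect_equal(add$sem_add, varied$sem)  # SEM propagates unchanged
  expect_identical(add$n_add, varied$n_probit)
})

test_that("adjuncts that alone reach the additive ED50 are refused", {
  varied <- potency_estimate(10, drug = "V")
  expect_error(
    mixture_design(varied, data.frame(drug = "A", dose = 300, ed50 = 235.7)),
    "sum to >= 1")
  expect_error(
    mixture_design(varied, data.frame(drug = c("A", "B"), dose = c(120, 120),
                                      ed50 = c(235.7, 235.7))),
    "sum to >= 1")
})

test_that("the additive varied component is exactly linear in adjunct dose", {
  varied <- potency_estimate(100, drug = "V")
  ed50_adj <- 400
  doses <- c(40, 80, 120)
  comp <- vapply(doses, function(dd) {
    d <- mixture_design(varied, data.frame(drug = "A", dose = dd,
                                           ed50 = ed50_adj))
    additive_ed50(d)$ed50_add_varied
  }, numeric(1))
  # slope is -ED50_varied / ED50_adjunct per unit adjunct dose
  expect_equal(diff(comp) / diff(doses), rep(-100 / 400, 2), tolerance = 1e-12)
  # total crosses the adjunct's solo ED50 as the varied component reaches 0
  d_edge <- mixture_design(varied, data.frame(drug = "A",
                                              dose = ed50_adj * (1 - 1e-9),
                                              ed50 = ed50_adj))
  expect_equal(additive_ed50(d_edge)$ed50_add_total, ed50_adj,
               tolerance = 1e-6)
})

test_that("two adjuncts equal one pooled adjunct of the same total fraction", {
  varied <- potency_estimate(50, sem = 4, n = 16, drug = "V")
  two <- mixture_design(varied, data.frame(drug = c("A", "B"),
                                           dose = c(30, 20),
                                           ed50 = c(300, 200)))
  fsum <- 30 / 300 + 20 / 200
  pooled <- mixture_design(varied, data.frame(drug = "AB", dose = 50,
                                              ed50 = 50 / fsum))
  expect_equal(additive_ed50(two)$ed50_add_total,
               additive_ed50(pooled)$ed50_add_total, tolerance = 1e-12)
})

test_that("experimental mixture totals add the fixed doses with unchanged SEM", {
  pb <- potency_estimate(26.17, sem = 2.07, n = 16, drug = "PB")
  ex <- experimental_mixture_ed50(pb, 25)
  expect_equal(ex$ed50_exp_total, 51.17)
  expect_equal(ex$sem_exp, 2.07)
  expect_identical(ex$n_exp, 16L)
  cbz <- potency_estimate(8.44, sem = 0.84, n = 16, drug = "CBZ")
  expect_equal(experimental_mixture_ed50(cbz, 25)$ed50_exp_total, 33.44)
  expect_equal(experimental_mixture_ed50(cbz)$ed50_exp_total, 8.44)
})

test_that("fraction breakdown rounds half away from zero before summing", {
  pb <- potency_estimate(solo["PB"], drug = "PB")
  design <- mixture_design(pb, data.frame(drug = c("ISOP", "BOR"),
                                          dose = c(25, 25),
                                          ed50 = c(235.7, 250)))
  mix <- experimental_mixture_ed50(
    potency_estimate(62.25 - 50, sem = 2.52, n = 24, drug = "PB"), c(25, 25))
  fb <- fraction_breakdown(mix, design)
  expect_equal(fb$fractions$fraction, c(0.42, 0.11, 0.10))
  expect_equal(fb$fraction_index, 0.63)
})

test_that("a mixture sitting on the additivity line has fraction index 1", {
  varied <- potency_estimate(100, sem = 5, n = 16, drug = "V")
  design <- mixture_design(varied, data.frame(drug = "A", dose = 60,
                                              ed50 = 240))
  add <- additive_ed50(design)
  on_line <- experimental_mixture_ed50(
    potency_estimate(add$ed50_add_varied, drug = "V"), 60)
  fb <- fraction_breakdown(on_line, design)
  expect_equal(fb$fraction_index_raw, 1, tolerance = 1e-12)
  expect_equal(fb$fraction_index, 1, tolerance = 0.005)
})

test_that("percent change reproduces the published potency reductions", {
  expect_identical(percent_change(9.52, 7.32), 23L)
  expect_identical(percent_change(292, 169), 42L)
  expect_identical(percent_change(8.71, 7.27), 17L)
  expect_identical(percent_change(150, 150), 0L)
  # sign flips around equality: an increase reports as negative
  expect_identical(percent_change(100, 125), -25L)
  expect_error(percent_change(0, 10), "positive")
})

test_that("isobologram coordinates place A and E on the fixed-dose line", {
  cbz <- potency_estimate(solo["CBZ"], drug = "CBZ")
  design <- mixture_design(cbz, data.frame(drug = "ISOP", dose = 25,
                                           ed50 = 235.7))
  add <- additive_ed50(design)
  ex <- experimental_mixture_ed50(potency_estimate(8.44, drug = "CBZ"), 25)
  co <- isobologram_coordinates(design, add, ex)
  a <- co[co$series == "point_A", ]
  e <- co[co$series == "point_E", ]
  expect_equal(c(a$x, a$y), c(25, 8.51), tolerance = 0.001)
  expect_equal(c(e$x, e$y), c(25, 8.44), tolerance = 1e-12)
  # A lies on the segment joining (0, ED50_varied) and (ED50_adjunct, 0)
  expect_equal(a$y, 9.52 * (1 - a$x / 235.7), tolerance = 1e-12)
  line <- co[co$series == "additivity_line", ]
  expect_equal(line$x, c(0, 235.7))
  expect_equal(line$y, c(9.52, 0))
})

test_that("multi-adjunct isobolograms pool adjuncts onto one axis with a note", {
  varied <- potency_estimate(100, drug = "V")
  design <- mixture_design(varied, data.frame(drug = c("A", "B"),
                                              dose = c(30, 20),
                                              ed50 = c(300, 200)))
  add <- additive_ed50(design)
  ex <- experimental_mixture_ed50(potency_estimate(70, drug = "V"), c(30, 20))
  co <- isobologram_coordinates(design, add, ex)
  expect_match(attr(co, "pooling_note"), "pooled")
  a <- co[co$series == "point_A", ]
  expect_equal(a$x, 50)
  # pooled axis keeps A on the pooled additivity line
  x_ed50 <- 50 / (30 / 300 + 20 / 200)
  expect_equal(a$y, 100 * (1 - a$x / x_ed50), tolerance = 1e-12)
})
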