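panel <- load_drug_panel()
get_rec <- function(nm) panel[panel$name == nm, , drop = FALSE]

test_that("drug calls take the lowest significant concentration", {
  ap_doses <- data.frame(
    concentration = c(0.37, 1.11, 3.33, 10),
    significant = c(FALSE, TRUE, TRUE, TRUE),
    direction = c("none", "up", "up", "up"))
  call <- call_drug(ap_doses, get_rec("4-Aminopyridine"))
  expect_equal(call$direction, "up")
  expect_equal(call$lowest_significant_concentration, 1.11)
  expect_equal(call$activity, "neuronally_active")
  expect_true(call$seizure_flag)
  expect_equal(call$fold_over_cmax, 1.11 / 0.075)

  asp_doses <- data.frame(concentration = c(3.7, 11.11, 33.33, 100),
                          significant = FALSE, direction = "none")
  call2 <- call_drug(asp_doses, get_rec("Aspirin"))
  expect_equal(call2$direction, "none")
  expect_equal(call2$activity, "non_active")
  expect_false(call2$seizure_flag)
  expect_true(is.na(call2$lowest_significant_concentration))
  expect_equal(call2$call_concentration, 100)   # reported at the top dose

  cpz_doses <- data.frame(
    concentration = c(0.11, 0.33, 1, 3),
    significant = c(FALSE, FALSE, TRUE, TRUE),
    direction = c("none", "none", "down", "down"))
  call3 <- call_drug(cpz_doses, get_rec("Chlorpromazine"))
  expect_equal(call3$direction, "down")
  expect_equal(call3$activity, "neuronally_active")
  expect_false(call3$seizure_flag)

  expect_error(call_drug(ap_doses[1:3, ], get_rec("4-Aminopyridine")),
               "4 dose results")
})

test_that("fold over Cmax uses the range upper bound and tolerates absence", {
  expect_equal(round(fold_cmax(30, get_rec("Acetaminophen"))), 65)
  expect_true(is.na(fold_cmax(10, get_rec("Kainic Acid"))))
  expect_equal(fold_cmax(1, get_rec("4-Aminopyridine")), 1 / 0.075,
               tolerance = 1e-12)
  expect_equal(fold_cmax(1, get_rec("4-Aminopyridine"), bound = "low"),
               1 / 0.025, tolerance = 1e-12)
  expect_error(fold_cmax(0, get_rec("Aspirin")), "positive")
})

test_that("confusion matrices score calls against clinical labels", {
  calls2d <- load_significance_calls()
  calls2d <- calls2d[calls2d$culture == "2D", ]
  cm <- build_confusion(calls2d, panel)
  expect_equal(cm$fn, 5L)
  expect_equal(cm$fp, 0L)
  expect_equal(cm$tp, 17L)
  expect_equal(cm$tn, 3L)
  expect_equal(cm$tp + cm$fn, cm$n_active_expected)
  expect_equal(cm$tn + cm$fp, cm$n_negative_expected)

  calls3d <- load_significance_calls()
  calls3d <- calls3d[calls3d$culture == "3D", ]
  cm3 <- build_confusion(calls3d, panel)
  expect_equal(cm3$tp, 7L)
  expect_equal(cm3$tn, 3L)

  # toy panel with all-correct calls
  toy <- panel[panel$name %in% c("Aspirin", "4-Aminopyridine", "Serotonin"), ]
  toy_calls <- data.frame(drug = toy$name,
                          direction = c("none", "up", "down"))
  cmt <- build_confusion(toy_calls, rbind(
    toy, panel[panel$clinical_class == "vehicle", ]))
  expect_equal(cmt$fp + cmt$fn, 0L)

  expect_error(build_confusion(calls2d[-1, ], panel), "one call per panel drug")
})

test_that("predictivity metrics reproduce the published panel values", {
  m2 <- replay_table2("2D")$metrics
  expect_equal(m2$specificity, 100)
  expect_equal(round(m2$predictivity), 91)
  expect_equal(m2$predictivity, 100 * 20 / 22)
  expect_equal(m2$sensitivity, 100 * 17 / 22)
  expect_equal(m2$ppv, 100)

  m3 <- replay_table2("3D")$metrics
  expect_equal(round(m3$predictivity), 45)

  # permuting panel order changes nothing
  calls <- load_significance_calls()
  calls <- calls[calls$culture == "2D", ]
  set.seed(2)
  shuf <- calls[sample(nrow(calls)), ]
  m_shuf <- predictivity_metrics(build_confusion(shuf, panel))
  expect_equal(m_shuf$predictivity, m2$predictivity)
  expect_equal(m_shuf$sensitivity, m2$sensitivity)

  # zero denominators are NA, not 0
  cm0 <- structure(list(tp = 0L, fn = 0L, fp = 0L, tn = 2L,
                        n_active_expected = 0L, n_negative_expected = 2L),
                   class = "calosc_confusion")
  m0 <- predictivity_metrics(cm0)
  expect_true(is.na(m0$sensitivity))
  expect_true(is.na(m0$ppv))
  expect_equal(m0$specificity, 100)
})

test_that("replay carries fold-over-Cmax with absent values propagated", {
  r <- replay_table2("2D")
  ka <- r$calls[r$calls$drug == "Kainic Acid", ]
  expect_true(is.na(ka$fold_over_cmax))
  ap <- r$calls[r$calls$drug == "4-Aminopyridine", ]
  expect_equal(ap$fold_over_cmax, 1 / 0.075, tolerance = 1e-12)
})
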