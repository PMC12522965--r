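# loading, validation, and probabilistic description of the input table

test_that("bundled default file loads with the published values and fitted specs", {
  p <- default_params()
  tab <- p$table
  row <- tab[tab$parameter_id == "tp_hosp_death_icd", ]
  expect_equal(row$mean, 0.178)
  expect_equal(row$sd, 0.008)
  expect_identical(row$distribution, "beta")
  expect_identical(p$specs$tp_hosp_death_icd$family, "beta")

  expect_equal(tab$mean[tab$parameter_id == "cost_well_pharm"], 741)
  expect_equal(tab$sd[tab$parameter_id == "cost_well_pharm"], 1246)
  expect_identical(p$specs$cost_well_pharm$family, "gamma")

  # SD-less rows become fixed specs
  expect_identical(p$specs$tp_compl_well_icd$family, "fixed")
  expect_identical(p$specs$u_hosp_icd$family, "fixed")
  expect_identical(p$specs$cost_death_icd$family, "fixed")

  # settings defaults
  expect_equal(p$settings$dr_cost, 0.06)
  expect_equal(p$settings$dr_outcome, 0.03)
  expect_equal(p$settings$wtp, 13002)
  expect_true(p$free_calibrated)
})

test_that("stated exit probabilities sum to one and validation catches breakage", {
  tab <- default_parameter_table()
  expect_length(validate_parameter_table(tab), 0)

  bad <- tab
  bad$mean[bad$parameter_id == "tp_hosp_death_icd"] <- 0.3
  issues <- validate_parameter_table(bad)
  expect_true(any(grepl("VALIDATION_ERROR.*sum to", issues)))
})

test_that("domain violations are named in validation errors", {
  tab <- default_parameter_table()
  tab$mean[tab$parameter_id == "u_well_pharm"] <- 1.2
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f, row.names = FALSE, quote = FALSE, na = "")
  expect_error(load_parameter_table(f), "VALIDATION_ERROR.*u_well_pharm")

  tab2 <- default_parameter_table()
  tab2$sd[tab2$parameter_id == "tp_compl_death_icd"] <- 0.5  # >= sqrt(m(1-m))
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(tab2, f2, row.names = FALSE, quote = FALSE, na = "")
  expect_error(load_parameter_table(f2), "beta-infeasible.*tp_compl_death_icd")
})

test_that("missing mandatory rows are schema errors; free rows are optional defaults", {
  tab <- default_parameter_table()
  f <- tempfile(fileext = ".csv")
  utils::write.csv(tab[tab$parameter_id != "cost_well_icd", ], f,
                   row.names = FALSE, quote = FALSE, na = "")
  # omitted mandatory rows are filled from defaults, so the load succeeds
  p <- load_parameter_table(f)
  expect_equal(p$table$mean[p$table$parameter_id == "cost_well_icd"], 3398)

  # omitting the free block flags the set uncalibrated but keeps defaults
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(tab[!is_free_parameter(tab$parameter_id), ], f2,
                   row.names = FALSE, quote = FALSE, na = "")
  p2 <- load_parameter_table(f2)
  expect_false(p2$free_calibrated)
  expect_true(all(is_free_parameter(p2$table$parameter_id) |
                    p2$table$parameter_id %in% tab$parameter_id))

  # a malformed file is a schema error
  f3 <- tempfile(fileext = ".csv")
  writeLines("not,a,parameter,file\n1,2,3,4", f3)
  expect_error(load_parameter_table(f3), "SCHEMA_ERROR")
})

test_that("settings overrides take precedence over file rows and defaults", {
  p <- default_params(wtp = 999, dr_cost = 0.09)
  expect_equal(p$settings$wtp, 999)
  expect_equal(p$settings$dr_cost, 0.09)
  expect_error(cea_settings(nope = 1), "unknown setting")
})

test_that("sample_parameters: reproducible, degenerate at zero SD, rows renormalised", {
  p <- default_params()
  set.seed(7); d1 <- sample_parameters(p)
  set.seed(7); d2 <- sample_parameters(p)
  expect_identical(d1, d2)

  # all-fixed table draws the means exactly
  pz <- zero_uncertainty(p)
  set.seed(1)
  expect_identical(as.vector(sample_parameters(pz)), as.vector(base_values(pz)))

  # every draw respects domains and row stochasticity
  set.seed(11)
  for (i in 1:200) {
    d <- sample_parameters(p)
    tp <- d[startsWith(names(d), "tp_")]
    expect_true(all(tp >= 0 & tp <= 1))
    expect_true(all(d[startsWith(names(d), "cost_")] >= 0))
    expect_true(all(d[startsWith(names(d), "u_")] >= 0 &
                      d[startsWith(names(d), "u_")] <= 1))
    expect_equal(unname(d["tp_hosp_well_icd"] + d["tp_hosp_death_icd"]), 1,
                 tolerance = 1e-9)
    expect_equal(unname(d["tp_compl_well_icd"] + d["tp_compl_rej_icd"] +
                          d["tp_compl_death_icd"]), 1, tolerance = 1e-9)
    expect_equal(unname(d["tp_rej_well_icd"] + d["tp_rej_death_icd"]), 1,
                 tolerance = 1e-9)
    expect_equal(unname(d["tp_hosp_well_pharm"] + d["tp_hosp_death_pharm"]), 1,
                 tolerance = 1e-9)
  }
})

test_that("sampled marginal moments match the published (mean, sd)", {
  p <- default_params()
  set.seed(123)
  draws <- replicate(4000, sample_parameters(p)["tp_hosp_death_pharm"])
  expect_lt(abs(mean(draws) - 0.284), 3 * 0.009 / sqrt(4000))
  expect_lt(abs(sd(draws) - 0.009), 3 * 0.009 / sqrt(2 * 4000))
})
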