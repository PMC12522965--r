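# deterministic (one-way, tornado, two-way) and probabilistic sensitivity

test_that("one_way_dsa: widths, monotone cost leverage, discount-rate range", {
  p <- default_params()

  zero <- one_way_dsa(p, "cost_well_icd", bounds = c(3398, 3398))
  expect_equal(zero$range_width, 0)

  cw <- one_way_dsa(p, "cost_well_icd")
  expect_true(is.finite(cw$low_icer) && is.finite(cw$high_icer))
  # ICD well-state cost enters delta-cost positively
  expect_gt(cw$high_icer, cw$low_icer)

  for (id in c("dr_cost", "dr_outcome")) {
    b <- dsa_bounds(p, id)
    expect_equal(unname(b), c(0.03, 0.09))
    e <- one_way_dsa(p, id)
    expect_true(is.finite(e$low_icer) && is.finite(e$high_icer))
  }

  # SD-less parameters use the 25% fallback
  b <- dsa_bounds(p, "cost_death_icd")
  expect_equal(unname(b), c(2082.75, 3471.25))
})

test_that("tornado: permutation, ordering, pivot, and qualitative top ranks", {
  p <- default_params()
  tor <- tornado(p)
  all_ids <- c(p$table$parameter_id, "dr_cost", "dr_outcome")
  expect_setequal(tor$parameter_id, all_ids)
  expect_equal(nrow(tor), length(all_ids))
  w <- tor$range_width
  expect_true(all(diff(w[is.finite(w)]) <= 1e-12))
  expect_true(is.finite(attr(tor, "base_icer")))

  # the reported most-influential parameters (well-state costs, discount
  # rates) rank among the widest bars -- qualitative check only
  top6 <- tor$parameter_id[1:6]
  expect_true("cost_well_icd" %in% top6)
  expect_true("cost_well_pharm" %in% top6)
  expect_true(any(c("dr_cost", "dr_outcome") %in% top6))

  sub <- tornado(p, "cost_well_icd")
  expect_equal(nrow(sub), 1)
})

test_that("tornado with all uncertainty removed has zero widths, sorted by id", {
  p <- zero_uncertainty(default_params())
  ids <- c("cost_well_icd", "u_well_icd", "cost_hosp_pharm")
  tor <- tornado(p, ids)
  # fallback still widens SD-less parameters; force zero-width bounds
  tor0 <- do.call(rbind, lapply(sort(ids), function(id) {
    b <- base_values(p)[[id]]
    one_way_dsa(p, id, bounds = c(b, b))
  }))
  expect_true(all(tor0$range_width == 0))
  expect_identical(tor0$parameter_id, sort(ids))
})

test_that("two_way_dsa: degenerate grid, corner signs, published ranges", {
  p <- default_params()
  base_pref <- if (run_base_case(p)$cea$cost_effective) "ICD" else "PHARM"
  deg <- two_way_dsa(p, range_a = c(3398, 3398), range_b = c(741, 741),
                     grid_n = 2)
  expect_true(all(deg$preferred == base_pref))

  grid <- two_way_dsa(p, grid_n = 6)
  expect_equal(nrow(grid), 36)
  # low ICD cost + high pharm cost favors ICD relative to the opposite corner
  corner_icd <- grid[grid$value_a == min(grid$value_a) &
                       grid$value_b == max(grid$value_b), ]
  corner_pharm <- grid[grid$value_a == max(grid$value_a) &
                         grid$value_b == min(grid$value_b), ]
  expect_gt(corner_icd$nmb_icd - corner_icd$nmb_pharm,
            corner_pharm$nmb_icd - corner_pharm$nmb_pharm)
  expect_identical(corner_pharm$preferred, "PHARM")
  # default ranges are the published ones
  expect_equal(range(grid$value_a), c(563, 9096))
  expect_equal(range(grid$value_b), c(42, 9195))
})

test_that("run_psa: seeded reproducibility and stability under extension", {
  p <- default_params()
  s1 <- run_psa(p, n_iter = 40, seed = 99)
  s2 <- run_psa(p, n_iter = 40, seed = 99)
  expect_identical(s1, s2)
  s3 <- run_psa(p, n_iter = 60, seed = 99)
  expect_equal(s3[1:40, ], s1[1:40, ], ignore_attr = TRUE)
  expect_false(identical(run_psa(p, n_iter = 40, seed = 100)$cost_icd,
                         s1$cost_icd))
  expect_true(all(is.finite(as.matrix(s1[, -1]))))
})

test_that("degenerate PSA reproduces the deterministic base case exactly", {
  p <- zero_uncertainty(default_params())
  s <- run_psa(p, n_iter = 3, seed = 5)
  base <- run_base_case(p)
  expect_identical(unique(s$cost_icd), base$icd$discounted_cost)
  expect_identical(unique(s$qaly_icd), base$icd$discounted_qaly)
  expect_identical(unique(s$cost_pharm), base$pharm$discounted_cost)
  expect_identical(unique(s$qaly_pharm), base$pharm$discounted_qaly)
  # and is invariant to the seed
  expect_identical(s$cost_icd, run_psa(p, n_iter = 3, seed = 77)$cost_icd)
})

test_that("ceac: step function for a point sample, CEAC(0), monotonicity", {
  one <- data.frame(iteration = 1, cost_icd = 200, qaly_icd = 2,
                    cost_pharm = 100, qaly_pharm = 1,
                    delta_cost = 100, delta_effect = 1)
  class(one) <- c("psa_sample", class(one))
  cv <- ceac(one, wtp_grid = c(0, 50, 99, 101, 1000))
  expect_equal(cv$prob_ce, c(0, 0, 0, 1, 1))

  p <- default_params()
  s <- run_psa(p, n_iter = 120, seed = 3)
  curve <- ceac(s, wtp_grid = seq(0, 50000, 1000), wtp = 13002)
  expect_equal(curve$prob_ce[curve$wtp == 0], mean(s$delta_cost < 0))
  expect_true(all(curve$prob_ce >= 0 & curve$prob_ce <= 1))
  if (all(s$delta_effect > 0)) expect_true(all(diff(curve$prob_ce) >= 0))
  expect_error(ceac(s[0, ]), "empty")
  expect_error(ceac(s, wtp_grid = c(2, 1)), "sorted")
})

test_that("ce_scatter_export: one row per iteration, deterministic under zero SD", {
  p <- default_params()
  s <- run_psa(p, n_iter = 3, seed = 1)
  sc <- ce_scatter_export(s, wtp = 13002)
  expect_equal(nrow(sc), 3)
  expect_identical(names(sc), c("iteration", "delta_effect", "delta_cost"))
  expect_equal(attr(sc, "wtp"), 13002)

  sz <- ce_scatter_export(run_psa(zero_uncertainty(p), n_iter = 4, seed = 1))
  expect_equal(length(unique(sz$delta_cost)), 1)
  expect_equal(length(unique(sz$delta_effect)), 1)
})
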