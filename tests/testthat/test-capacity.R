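test_that("density bound follows (NI/Np)*(L/D)", {
  expect_equal(density_bound(1000, 10000, 5, 1), 0.5)
  expect_equal(density_bound(100, 100, 3, 3), 1)
  expect_equal(density_bound(1000, 10000, 5, 2),
               density_bound(1000, 10000, 5, 1) / 2)
})

test_that("map-count product formula reproduces its simple closed cases", {
  tr <- track_discretization(1, 0.1)
  cn <- exclusion_constraint(0.2, 0.1)
  # a single field: Np * Nbins choices
  p1 <- capacity_params(5, 5, fields_per_cell = 1 / 5)
  expect_equal(exact_map_count(p1, tr, cn, log = FALSE), 5 * 10)
  # two fields, one interneuron class
  p2 <- capacity_params(4, 1, fields_per_cell = 1 / 2)
  M <- 2; NpNb <- 4 * 10; per <- 4 / 1 * 2
  expect_equal(exact_map_count(p2, tr, cn, log = FALSE),
               NpNb * (NpNb - per) / 2)
  # saturation errors out rather than returning nonsense
  p_sat <- capacity_params(4, 1, fields_per_cell = 2)
  expect_error(exact_map_count(p_sat, tr, cn), "saturated")
})

test_that("map count decreases in exclusion size and field load", {
  tr <- track_discretization(5, 0.1)
  Ds <- c(0.2, 0.5, 1, 1.5)
  counts_D <- sapply(Ds, function(D)
    exact_map_count(capacity_params(100, 20, 0.5), tr,
                    exclusion_constraint(D, 0.1)))
  expect_true(all(diff(counts_D) < 0))
  Fs <- c(0.2, 0.4, 0.6, 0.8)
  cn <- exclusion_constraint(0.5, 0.1)
  # per-map log count normalized per field must fall as load grows
  counts_F <- sapply(Fs, function(f)
    exact_map_count(capacity_params(100, 20, f), tr, cn) /
      round(f * 100))
  expect_true(all(diff(counts_F) < 0))
})

test_that("Stirling approximation tracks the exact form and its limits", {
  tr <- track_discretization(5, 0.1)
  cn <- exclusion_constraint(1, 0.1)
  # relative log agreement at moderate field numbers
  p <- capacity_params(500, 100, fields_per_cell = 0.2)  # F*Np = 100
  rel <- abs(log_map_count_stirling(p, tr, cn) - exact_map_count(p, tr, cn)) /
    exact_map_count(p, tr, cn)
  expect_lt(rel, 0.01)
  # enormous interneuron pools remove the constraint: Stirling of the
  # unconstrained count ln((Np*Nbins)^M / M!)
  p_inf <- capacity_params(500, 1e9, fields_per_cell = 0.2)
  M <- 100
  unconstrained <- M * log(500 * tr$n_bins) - lgamma(M + 1)
  expect_equal(log_map_count_stirling(p_inf, tr, cn), unconstrained,
               tolerance = 0.01 * unconstrained)
})

test_that("product formula matches brute-force enumeration where it is exact", {
  # two same-interneuron fields, odd exclusion zone
  tr <- track_discretization(0.8, 0.1)
  cn3 <- exclusion_constraint(0.3, 0.1)
  p <- capacity_params(2, 1, 1)
  expect_equal(exact_map_count(p, tr, cn3, log = FALSE),
               brute_force_map_count(p, tr, cn3))
  # three fields with a one-bin zone (zones cannot overlap)
  tr3 <- track_discretization(0.3, 0.1)
  cn1 <- exclusion_constraint(0.1, 0.1)
  p3 <- capacity_params(3, 1, 1)
  expect_equal(exact_map_count(p3, tr3, cn1, log = FALSE),
               brute_force_map_count(p3, tr3, cn1))
  # mixed interneurons, odd zone
  tr6 <- track_discretization(0.6, 0.1)
  p22 <- capacity_params(2, 2, 1)
  expect_equal(exact_map_count(p22, tr6, cn3, log = FALSE),
               brute_force_map_count(p22, tr6, cn3))
})

test_that("outside the exact regime the formula's bias is measured, not hidden", {
  # even zone: the per-field exclusion is direction-dependent, so dividing
  # the ordered count by M! overcounts the enumerated truth
  tr <- track_discretization(0.6, 0.1)
  cn2 <- exclusion_constraint(0.2, 0.1)
  p <- capacity_params(2, 2, 1)
  formula <- exact_map_count(p, tr, cn2, log = FALSE)
  truth <- brute_force_map_count(p, tr, cn2)
  expect_gt(formula, truth)
  expect_lt((formula - truth) / truth, 0.25)
  # three fields with overlapping odd zones: the sequential subtraction
  # double-removes shared bins and therefore undercounts
  tr9 <- track_discretization(0.9, 0.1)
  cn3 <- exclusion_constraint(0.3, 0.1)
  p3 <- capacity_params(3, 1, 1)
  formula3 <- exact_map_count(p3, tr9, cn3, log = FALSE)
  truth3 <- brute_force_map_count(p3, tr9, cn3)
  expect_lt(formula3, truth3)
  expect_lt((truth3 - formula3) / truth3, 0.25)
  expect_error(brute_force_map_count(capacity_params(50, 10, 1),
                                     track_discretization(5, 0.1),
                                     cn3), "too large")
})

test_that("assembly counts follow the choose-interneurons construction", {
  p_all <- capacity_params(10000, 1000, 1, assembly_size = 1000)
  expect_equal(log_assembly_count(p_all), 1000 * log(10))
  p_one <- capacity_params(10000, 1000, 1, assembly_size = 1)
  expect_equal(log_assembly_count(p_one), log(10000))
  expect_error(log_assembly_count(capacity_params(10, 5, 1)), "not set")
  # headline population: the formula gives ~10^240, and its Stirling
  # expansion agrees to within a percent in log
  p <- capacity_params(10000, 1000, 0.2, assembly_size = 100)
  l10 <- nat_to_log10(log_assembly_count(p))
  expect_equal(l10, 239.805, tolerance = 0.01)
  expect_equal(log_assembly_count(p, stirling = TRUE), log_assembly_count(p),
               tolerance = 0.01 * log_assembly_count(p))
})

test_that("sequence counts deplete the interneuron pool correctly", {
  p1 <- capacity_params(10000, 1000, 1, assembly_size = 100,
                        sequence_length = 1)
  p1a <- capacity_params(10000, 1000, 1, assembly_size = 100)
  expect_equal(log_sequence_count(p1), log_assembly_count(p1a))
  # exhausting the pool: the final factor is C(n, n) = 1
  pfull <- capacity_params(1000, 100, 1, assembly_size = 50,
                           sequence_length = 2)
  ppart <- capacity_params(1000, 100, 1, assembly_size = 50,
                           sequence_length = 1)
  expect_equal(log_sequence_count(pfull) - log_sequence_count(ppart),
               lchoose(50, 50) + 50 * log(1000 / 100))
  expect_error(log_sequence_count(
    capacity_params(1000, 100, 1, assembly_size = 60, sequence_length = 2)),
    "exceeds")
})

test_that("random maps are uniform, seeded, and unconstrained", {
  tr <- track_discretization(5, 0.1)
  m0 <- random_map(0, 4, tr)
  expect_length(m0$bins, 0)
  m1 <- random_map(500, 10, tr, seed = 42)
  m2 <- random_map(500, 10, tr, seed = 42)
  expect_identical(m1$bins, m2$bins)
  big <- random_map(1e5, 10, tr, seed = 7)
  p <- chisq.test(tabulate(big$bins + 1, tr$n_bins))$p.value
  expect_gt(p, 0.001)
})

test_that("optimal maps space same-interneuron fields maximally", {
  tr4 <- track_discretization(4, 1)
  m <- optimal_map(4, 1, tr4)
  expect_equal(m$bins, 0:3)
  expect_equal(map_centers_m(m), c(0.5, 1.5, 2.5, 3.5))
  m22 <- optimal_map(4, 2, tr4)   # interleaved quarters
  expect_equal(m22$bins, 0:3)
  expect_equal(m22$interneuron, c(1, 2, 1, 2))
  # minimum same-interneuron circular distance equals L/(n_active/n_int)
  tr <- track_discretization(5, 0.1)
  mo <- optimal_map(20, 4, tr)
  for (j in 1:4) {
    b <- sort(mo$bins[mo$interneuron == j])
    d <- diff(c(b, b[1] + tr$n_bins))
    expect_true(all(d == tr$n_bins / 5))  # 5 cells per interneuron
  }
  expect_error(optimal_map(10, 3, tr), "divide")
})

test_that("map verification flags violating same-interneuron pairs only", {
  tr <- track_discretization(5, 0.1)
  cn <- exclusion_constraint(0.5, 0.1)
  mo <- optimal_map(20, 4, tr, constraint = cn)
  expect_equal(nrow(verify_map(mo)), 0)
  # two same-interneuron cells in one bin: exactly one violation
  m_bad <- place_field_map(c(3, 3, 10), c(1, 1, 1), tr, cn)
  v <- verify_map(m_bad)
  expect_equal(nrow(v), 1)
  expect_equal(c(v$cell_i, v$cell_j), c(1, 2))
  # adjacent bins with a one-bin zone: distance 1 >= 1, no violation
  cn1 <- exclusion_constraint(0.1, 0.1)
  m_adj <- place_field_map(c(3, 4), c(1, 1), tr, cn1)
  expect_equal(nrow(verify_map(m_adj)), 0)
  # different interneurons never violate
  m_diff <- place_field_map(c(3, 3), c(1, 2), tr, cn)
  expect_equal(nrow(verify_map(m_diff)), 0)
})
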