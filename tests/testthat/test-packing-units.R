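test_that("every hexamer yields six units with owner/donor bijections", {
  for (fx in list(compact_fixture(), expanded_fixture())) {
    units <- build_packing_units(fx$model, cpaf_scheme())
    expect_equal(nrow(units), 6)
    expect_setequal(units$owner_chain, LETTERS[1:6])
    expect_setequal(units$adjacent_chain, LETTERS[1:6])
    expect_true(all(units$owner_chain != units$adjacent_chain))
    expect_false(anyDuplicated(units$name) > 0)
  }
})

test_that("unit names follow the conformation/nucleotide convention", {
  units <- build_packing_units(compact_fixture()$model, cpaf_scheme())
  expect_setequal(sub("'$", "", units$name), c("Com-ATP", "Com-ADP", "Com-Apo"))
  expect_equal(units$conformation[1], "compact")
  gexp <- expanded_fixture()
  uexp <- build_packing_units(gexp$model, cpaf_scheme())
  expect_setequal(sub("'$", "", uexp$name), c("Exp-ATP", "Exp-ADP1", "Exp-ADP2"))
  gclo <- closed_fixture()
  st <- label_chain_states(gclo$model, cpaf_scheme(),
                           reference = compact_fixture()$model)
  uclo <- build_packing_units(gclo$model, cpaf_scheme(), states = st)
  expect_setequal(sub("'$", "", uclo$name), c("Clo-ATP*", "Clo-Apo1", "Clo-Apo2"))
})

test_that("the adjacent CAD donor matches the planted adjacency", {
  for (fx in list(compact_fixture(), expanded_fixture())) {
    units <- build_packing_units(fx$model, cpaf_scheme())
    ord <- attr(units, "chain_order")
    # planted adjacency: the donor is the cyclically previous chain
    for (i in seq_len(6)) {
      p <- match(units$owner_chain[i], ord)
      expect_equal(units$adjacent_chain[i], ord[((p - 2) %% 6) + 1])
    }
  }
})

test_that("unit construction and metrics are equivariant under global motion", {
  g <- compact_fixture(); sch <- cpaf_scheme()
  u1 <- build_packing_units(g$model, sch)
  m1 <- packing_unit_metrics(u1, g$model, sch)
  set.seed(21)
  R <- rand_rotation(); tr <- rnorm(3, 0, 30)
  m2 <- g$model
  xyz <- t(R %*% t(as.matrix(m2$atoms[, c("x", "y", "z")])) + tr)
  m2$atoms$x <- xyz[, 1]; m2$atoms$y <- xyz[, 2]; m2$atoms$z <- xyz[, 3]
  u2 <- build_packing_units(m2, sch)
  mm2 <- packing_unit_metrics(u2, m2, sch)
  k1 <- order(u1$owner_chain); k2 <- order(u2$owner_chain)
  expect_equal(u1$name[k1], u2$name[k2])
  expect_equal(u1$nucleotide_label[k1], u2$nucleotide_label[k2])
  expect_equal(m1$r347_g284[k1], mm2$r347_g284[k2], tolerance = 1e-6)
  expect_equal(m1$r347_state[k1], mm2$r347_state[k2])
})

test_that("interface distances equal the generator's analytic ground truth", {
  for (fx in list(compact_fixture(), expanded_fixture(), closed_fixture())) {
    units <- build_packing_units(fx$model, cpaf_scheme())
    pm <- packing_unit_metrics(units, fx$model, cpaf_scheme())
    measured <- stats::setNames(pm$r347_g284, units$owner_chain)
    expect_equal(measured[names(fx$truth$r347_g284)], fx$truth$r347_g284,
                 tolerance = 1e-6)
  }
})

test_that("C2-symmetric hexamers pass the unit symmetry-consistency check", {
  g <- compact_fixture(); sch <- cpaf_scheme()
  pm <- packing_unit_metrics(build_packing_units(g$model, sch), g$model, sch)
  sym <- attr(pm, "symmetry_check")
  expect_false(is.null(sym))
  expect_true(all(sym$consistent))
  expect_true(all(sym$delta_distance <= 0.5))
})

test_that("non-hexameric inputs are rejected", {
  g <- compact_fixture()
  m <- g$model
  m$atoms <- m$atoms[m$atoms$chain %in% c("A", "B", "C"), ]
  expect_error(build_packing_units(m, cpaf_scheme()), "hexamer")
})
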