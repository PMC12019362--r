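test_that("the planted register, event kinds and twists are recovered exactly", {
  pr <- pair_fixture(); sch <- cpaf_scheme()
  cm <- map_catalytic_events(pr$model_a, pr$model_b, sch)
  expect_equal(cm$register_deg_cw, pr$truth$register_deg_cw)
  expect_equal(cm$direction_summary, "clockwise")
  expect_equal(cm$alignment_twist_deg, 60, tolerance = 1e-6)
  kinds <- vapply(cm$events, function(e) e$kind, character(1))
  expect_equal(sort(kinds),
               sort(rep(c("ATP_BINDING", "HYDROLYSIS", "ADP_RELEASE"), each = 2)))
  truth_ev <- c(pr$truth$events, pr$truth$release_events)
  for (ev in cm$events) {
    te <- Filter(function(e) e$kind == ev$kind &&
                   e$source_chain == ev$source_chain, truth_ev)
    expect_length(te, 1)
    te <- te[[1]]
    for (d in c("CAD", "NTD", "THREE_HELIX_BUNDLE"))
      expect_equal(ev$twist_deg[[d]], te$twist_cw[[d]], tolerance = 1e-6,
                   info = paste(ev$kind, d))
    for (a in c("D116", "C196", "G284", "E331"))
      expect_equal(ev$displacement[[a]], te$displacement[[a]], tolerance = 1e-6,
                   info = paste(ev$kind, a))
  }
})

test_that("event partition covers every packing unit of both states", {
  pr <- pair_fixture(); sch <- cpaf_scheme()
  cm <- map_catalytic_events(pr$model_a, pr$model_b, sch)
  src_a <- unlist(lapply(cm$events, function(e)
    if (e$direction == "expanding") e$source_unit else e$target_unit))
  tgt_b <- unlist(lapply(cm$events, function(e)
    if (e$direction == "expanding") e$target_unit else e$source_unit))
  carry_a <- cm$carries$src_chain
  units_a <- cm$units_a; units_b <- cm$units_b
  covered_a <- c(src_a, units_a$name[match(carry_a, units_a$owner_chain)])
  covered_b <- c(tgt_b, units_b$name[match(cm$carries$tgt_chain, units_b$owner_chain)])
  expect_setequal(unique(covered_a), units_a$name)
  expect_setequal(unique(covered_b), units_b$name)
  # each unit at most once as an expanding source and once as a target
  exp_src <- vapply(Filter(function(e) e$direction == "expanding", cm$events),
                    function(e) e$source_unit, character(1))
  expect_false(anyDuplicated(exp_src) > 0)
})

test_that("reversing the state order negates the register and swaps kinds", {
  pr <- pair_fixture(); sch <- cpaf_scheme()
  fwd <- map_catalytic_events(pr$model_a, pr$model_b, sch)
  rev <- map_catalytic_events(pr$model_b, pr$model_a, sch)
  expect_equal(rev$register_deg_cw, -fwd$register_deg_cw)
  expect_true(isTRUE(rev$inverted))
  count <- function(m, k) sum(vapply(m$events, function(e) e$kind == k, logical(1)))
  expect_equal(count(rev, "ATP_BINDING"), count(fwd, "ADP_RELEASE"))
  expect_equal(count(rev, "ADP_RELEASE"), count(fwd, "ATP_BINDING"))
  expect_equal(count(rev, "HYDROLYSIS"), count(fwd, "HYDROLYSIS"))
})

test_that("identical states map as non-catalytic with zero event metrics", {
  g <- compact_fixture(); sch <- cpaf_scheme()
  cm <- map_catalytic_events(g$model, g$model, sch)
  expect_true(cm$non_catalytic)
  expect_equal(cm$register_deg_cw, 0)
  expect_length(cm$events, 0)
  expect_lt(cm$alignment_rmsd, 1e-9)
})

test_that("event metrics are invariant under a common global rigid motion", {
  pr <- pair_fixture(); sch <- cpaf_scheme()
  set.seed(31)
  R <- rand_rotation(); tr <- rnorm(3, 0, 25)
  move <- function(m) {
    xyz <- t(R %*% t(as.matrix(m$atoms[, c("x", "y", "z")])) + tr)
    m$atoms$x <- xyz[, 1]; m$atoms$y <- xyz[, 2]; m$atoms$z <- xyz[, 3]
    m
  }
  cm1 <- map_catalytic_events(pr$model_a, pr$model_b, sch)
  cm2 <- map_catalytic_events(move(pr$model_a), move(pr$model_b), sch)
  expect_equal(cm2$register_deg_cw, cm1$register_deg_cw)
  key <- function(m) vapply(m$events, function(e) paste(e$kind, e$source_chain), character(1))
  o1 <- order(key(cm1)); o2 <- order(key(cm2))
  for (k in seq_along(o1)) {
    e1 <- cm1$events[[o1[k]]]; e2 <- cm2$events[[o2[k]]]
    expect_equal(abs(e2$twist_deg[["CAD"]]), abs(e1$twist_deg[["CAD"]]), tolerance = 1e-6)
    expect_equal(e2$displacement, e1$displacement, tolerance = 1e-6)
  }
})

test_that("mapping failure is diagnosed with per-register mismatch counts", {
  g1 <- compact_fixture(); sch <- cpaf_scheme()
  g2 <- fixture("apo6", function()
    generate_hexamer(synthetic_spec(seed = 106, labels = rep("APO", 6),
                                    symmetry = "exact_C6", place_ligands = FALSE,
                                    label = "allapo")))
  expect_error(map_catalytic_events(g1$model, g2$model, sch),
               "mapping failure.*mismatches")
})

test_that("pore-loop heights and spans equal the planted values", {
  sch <- cpaf_scheme()
  for (fx in list(compact_fixture(), expanded_fixture())) {
    pm <- pore_metrics(fx$model, sch)
    expect_equal(pm$loop_heights[names(fx$truth$loop_heights)],
                 fx$truth$loop_heights, tolerance = 1e-6)
    expect_equal(pm$height_span_asym, fx$truth$loop_height_span, tolerance = 1e-6)
  }
  # planar loops: all-equal heights, zero span
  flat <- generate_hexamer(synthetic_spec(seed = 107, labels = rep("APO", 6),
                                          place_ligands = FALSE, label = "flat"))
  pmf <- pore_metrics(flat$model, sch)
  expect_equal(pmf$height_span_asym, 0, tolerance = 1e-9)
  # planted 0/10/20 A loop elevations give a 20 A span
  g <- generate_hexamer(synthetic_spec(seed = 108, labels = rep("APO", 6),
                                       loop_heights = c(0, 10, 20, 0, 10, 20),
                                       place_ligands = FALSE, label = "stairs"))
  expect_equal(pore_metrics(g$model, sch)$height_span_asym, 20, tolerance = 1e-6)
  expect_equal(g$truth$loop_height_span, 20)
})

test_that("the closed-state transition hypothesis pairs ATP* with its clockwise APO neighbour", {
  gclo <- closed_fixture(); sch <- cpaf_scheme()
  st <- label_chain_states(gclo$model, sch, reference = compact_fixture()$model)
  units <- build_packing_units(gclo$model, sch, states = st)
  hyp <- closed_transition_hypothesis(st, units)
  expect_equal(nrow(hyp), 2)
  expect_setequal(hyp$atp_star_chain, names(gclo$truth$labels)[gclo$truth$labels == "ATP_STAR"])
  expect_true(all(hyp$binding_label == "APO"))
})
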