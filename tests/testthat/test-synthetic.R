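test_that("generation is byte-identical for a fixed seed", {
  d1 <- tempfile(); d2 <- tempfile()
  run_synth(synthetic_spec(seed = 5, noise_sigma = 0.2), d1)
  run_synth(synthetic_spec(seed = 5, noise_sigma = 0.2), d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (k in seq_along(f1)) expect_identical(readLines(f1[k]), readLines(f2[k]))
})

test_that("inconsistent specs are rejected", {
  expect_error(synthetic_spec(labels = c("ATP", "ADP")), "length 6")
  expect_error(synthetic_spec(labels = rep("XTP", 6)), "invalid label")
  expect_error(synthetic_spec(labels = c("ATP", rep("APO", 5)),
                              symmetry = "exact_C6"), "uniform")
  expect_error(synthetic_spec(labels = c("ATP", "ADP", "APO", "APO", "ADP", "ATP"),
                              symmetry = "exact_C2"), "period 3")
  expect_error(synthetic_spec(noise_sigma = -1), "noise_sigma")
  expect_error(generate_state_pair(synthetic_spec(
    labels = c("ATP_STAR", "APO", "APO", "ATP_STAR", "APO", "APO"))), "ATP/ADP/APO")
})

test_that("generated models survive the structure_io round trip", {
  g <- generate_hexamer(synthetic_spec(seed = 6, noise_sigma = 0.1))
  f <- tempfile(fileext = ".pdb")
  write_structure(g$model, f)
  m <- read_structure(f, quiet = TRUE)
  expect_equal(nrow(m$atoms), nrow(g$model$atoms))
  expect_equal(length(chain_ids(m)), 6)
})

test_that("the planted C2/C6 axes and labels are recovered from written files", {
  d <- tempfile()
  run_synth(synthetic_spec(seed = 8, label = "fix"), d)
  m <- read_structure(file.path(d, "fix.pdb"), label = "fix", quiet = TRUE)
  ax <- find_symmetry_axis(m, 2)
  expect_lt(hexcycle:::vec_angle(ax$direction, c(0, 0, 1)), 0.1)
  st <- label_chain_states(m, cpaf_scheme())
  manifest <- jsonlite::read_json(file.path(d, "ground_truth.json"))
  expect_equal(stats::setNames(st$label, st$chain),
               unlist(manifest$labels)[st$chain])
})

test_that("recovery error grows with the planted noise level", {
  sch <- cpaf_scheme()
  err_at <- function(sigma) {
    errs <- vapply(1:3, function(k) {
      pr <- generate_state_pair(synthetic_spec(seed = 200 + k, noise_sigma = sigma,
                                               label = "a"), 1, "b")
      cm <- map_catalytic_events(pr$model_a, pr$model_b, sch)
      tws <- unlist(lapply(cm$events, function(e) {
        te <- Filter(function(x) x$kind == e$kind && x$source_chain == e$source_chain,
                     c(pr$truth$events, pr$truth$release_events))[[1]]
        abs(e$twist_deg[c("CAD", "NTD", "THREE_HELIX_BUNDLE")] -
              unlist(te$twist_cw[c("CAD", "NTD", "THREE_HELIX_BUNDLE")]))
      }))
      max(tws)
    }, numeric(1))
    mean(errs)
  }
  e0 <- err_at(0); e3 <- err_at(0.3); e5 <- err_at(0.5)
  expect_lt(e0, 1e-6)
  expect_lt(e3, 2)   # the documented noisy-recovery band
  expect_gt(e5, e0)
})
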