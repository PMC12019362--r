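test_that("superposition recovers planted rigid transforms to 1e-9", {
  set.seed(42)
  # identity on identical sets
  P4 <- matrix(rnorm(12), 4, 3)
  fit0 <- superpose(P4, P4)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$transform$R, diag(3), tolerance = 1e-9)
  # planted 25 degree rotation about z plus translation (1,2,3)
  P <- matrix(rnorm(150), 50, 3)
  R0 <- hexcycle:::rot_axis(c(0, 0, 1), hexcycle:::deg2rad(25))
  Q <- t(R0 %*% t(P) + c(1, 2, 3))
  fit <- superpose(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(rotation_angle(fit$transform), 25, tolerance = 1e-9)
  expect_error(superpose(P[1:2, ], Q[1:2, ]), "at least 3")
  expect_warning(superpose(cbind(1:5, 0, 0), cbind(1:5, 0, 0)), "degenerate")
})

test_that("superposition matches the closed-form quaternion oracle", {
  set.seed(7)
  for (k in 1:20) {
    n <- sample(3:40, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    Q <- matrix(rnorm(3 * n), n, 3)   # unrelated clouds: nontrivial optimum
    fit <- superpose(P, Q)
    oracle <- horn_superpose(P, Q)
    expect_equal(fit$rmsd, oracle$rmsd, tolerance = 1e-9)
  }
})

test_that("superpose(A,B) and superpose(B,A) are mutually inverse", {
  set.seed(8)
  P <- matrix(rnorm(90), 30, 3)
  Q <- matrix(rnorm(90), 30, 3)
  ab <- superpose(P, Q)$transform
  ba <- superpose(Q, P)$transform
  comp <- compose_transform(ba, ab)
  expect_equal(comp$R, diag(3), tolerance = 1e-8)
  expect_equal(comp$t, c(0, 0, 0), tolerance = 1e-8)
})

test_that("twist decomposition is signed, additive, and matches brute force", {
  z <- c(0, 0, 1)
  expect_equal(rotation_about_axis(rigid_transform(), z), 0)
  # a 42 degree clockwise rotation seen from +z is a -42 right-handed rotation
  Rcw <- rigid_transform(hexcycle:::rot_axis(z, -hexcycle:::deg2rad(42)))
  expect_equal(rotation_about_axis(Rcw, z, "from_positive_axis"), 42, tolerance = 1e-9)
  expect_equal(rotation_about_axis(Rcw, z, "from_negative_axis"), -42, tolerance = 1e-9)
  # a rotation about x has zero twist about z
  Rx <- rigid_transform(hexcycle:::rot_axis(c(1, 0, 0), hexcycle:::deg2rad(70)))
  expect_equal(rotation_about_axis(Rx, z), 0, tolerance = 1e-9)
  # twist of a general rotation agrees with a brute-force decomposition
  set.seed(9)
  for (k in 1:5) {
    R <- rand_rotation()
    ax <- hexcycle:::unitv(rnorm(3))
    tw <- rotation_about_axis(rigid_transform(R), ax)
    bf <- -brute_twist(R, ax)     # brute force returns the right-handed angle
    expect_equal(tw, bf, tolerance = 1e-3)
  }
  # additivity for rotations about a common axis
  set.seed(10)
  a1 <- runif(1, -170, 170); a2 <- runif(1, -170, 170)
  R1 <- rigid_transform(hexcycle:::rot_axis(z, hexcycle:::deg2rad(a1)))
  R2 <- rigid_transform(hexcycle:::rot_axis(z, hexcycle:::deg2rad(a2)))
  R12 <- compose_transform(R2, R1)
  s <- rotation_about_axis(R12, z)
  gap <- abs(s - rotation_about_axis(R1, z) - rotation_about_axis(R2, z)) %% 360
  expect_lt(min(gap, 360 - gap), 1e-9)
})

test_that("symmetry axes are recovered exactly on planted C2 and C6 hexamers", {
  g2 <- compact_fixture()
  ax2 <- find_symmetry_axis(g2$model, 2)
  expect_lt(hexcycle:::vec_angle(ax2$direction, c(0, 0, 1)), 0.1)
  expect_lt(ax2$residual_rmsd, 1e-6)
  expect_equal(ax2$angle_deg, 180, tolerance = 1e-6)
  g6 <- fixture("c6", function()
    generate_hexamer(synthetic_spec(seed = 105, labels = rep("ADP", 6),
                                    symmetry = "exact_C6", label = "c6")))
  ax6 <- find_symmetry_axis(g6$model, 6)
  expect_lt(hexcycle:::vec_angle(ax6$direction, c(0, 0, 1)), 0.1)
  expect_equal(ax6$angle_deg, 60, tolerance = 1e-6)
  # single chain cannot be mapped
  m1 <- g2$model
  m1$atoms <- m1$atoms[m1$atoms$chain == "A" & !m1$atoms$het, ]
  expect_error(find_symmetry_axis(m1, 2), "2 chains|multiple")
})

test_that("the recovered axis is equivariant under a global rigid transform", {
  g <- compact_fixture()
  set.seed(11)
  R <- rand_rotation(); tr <- rnorm(3, 0, 20)
  m2 <- g$model
  xyz <- t(R %*% t(as.matrix(m2$atoms[, c("x", "y", "z")])) + tr)
  m2$atoms$x <- xyz[, 1]; m2$atoms$y <- xyz[, 2]; m2$atoms$z <- xyz[, 3]
  ax <- find_symmetry_axis(m2, 2)
  planted <- as.numeric(R %*% c(0, 0, 1))
  ang <- min(hexcycle:::vec_angle(ax$direction, planted),
             hexcycle:::vec_angle(-ax$direction, planted))
  expect_lt(ang, 0.1)
})

test_that("Calpha distances and displacements are exact on planted geometry", {
  a <- data.frame(elety = "CA", element = "C", resid = "GLY", chain = c("A", "B"),
                  resno = c(1L, 1L), insert = "", x = c(0, 3), y = c(0, 4),
                  z = 0, o = 1, b = 0, het = FALSE)
  m <- structure_model(a)
  expect_equal(ca_distance(m, "A", 1, "B", 1), 5)
  expect_error(ca_distance(m, "A", 2, "B", 1), "missing Calpha")
  # identical states under the identity alignment move nothing
  g <- compact_fixture()
  expect_equal(residue_displacement(g$model, g$model, rigid_transform(), "A", 284), 0)
  # planted 7 A translation of one chain
  m2 <- g$model
  sel <- m2$atoms$chain == "C" & !m2$atoms$het
  m2$atoms$z[sel] <- m2$atoms$z[sel] + 7
  expect_equal(residue_displacement(g$model, m2, rigid_transform(), "C", 284),
               7, tolerance = 1e-9)
  expect_equal(residue_displacement(g$model, m2, rigid_transform(), "A", 284), 0)
})

test_that("for tiny point sets no random rigid transform beats the fitted one", {
  set.seed(12)
  for (n in c(3, 5)) {
    P <- matrix(rnorm(3 * n), n, 3)
    Q <- matrix(rnorm(3 * n), n, 3)
    best <- superpose(P, Q)$rmsd
    cm <- colMeans(P)
    worst <- min(vapply(seq_len(10000), function(k) {
      R <- rand_rotation()
      moved <- t(R %*% t(sweep(P, 2, cm)))
      # optimal translation for this rotation is centroid matching
      moved <- sweep(moved, 2, colMeans(Q) - colMeans(moved), `+`)
      sqrt(mean(rowSums((moved - Q)^2)))
    }, numeric(1)))
    expect_lte(best, worst + 1e-12)
  }
})
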