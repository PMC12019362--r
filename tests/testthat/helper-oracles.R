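# Shared oracles and fixture helpers.

# Horn's closed-form quaternion solution to the least-squares rigid
# superposition problem: an implementation independent of the package's
# SVD (Kabsch) path, used as the reference oracle.
horn_superpose <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  S <- crossprod(P, Q)
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
                2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
                2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
              3, 3)
  moved <- t(R %*% t(P))
  list(R = R, t = ct - as.numeric(R %*% cm),
       rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

# brute-force swing/twist decomposition: the twist angle about `axis` that
# minimises the residual rotation angle, found by grid refinement
brute_twist <- function(R, axis, lo = -180, hi = 180, iters = 60) {
  resid <- function(a) {
    Rt <- hexcycle:::rot_axis(axis, hexcycle:::deg2rad(a))
    acos(pmin(1, pmax(-1, (sum(diag(t(Rt) %*% R)) - 1) / 2)))
  }
  for (k in seq_len(iters)) {
    g <- seq(lo, hi, length.out = 41)
    v <- vapply(g, resid, numeric(1))
    i <- which.min(v)
    lo <- g[max(1, i - 1)]; hi <- g[min(41, i + 1)]
  }
  (lo + hi) / 2
}

rand_rotation <- function() {
  ax <- hexcycle:::unitv(rnorm(3))
  hexcycle:::rot_axis(ax, runif(1, 0, pi))
}

# cached standard fixtures so expensive generation runs once per suite
.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

compact_fixture <- function() fixture("compact", function()
  generate_hexamer(synthetic_spec(seed = 101, label = "compact")))
expanded_fixture <- function() fixture("expanded", function()
  generate_hexamer(synthetic_spec(seed = 102,
                                  labels = c("ADP", "ATP", "ADP", "ADP", "ATP", "ADP"),
                                  label = "expanded")))
closed_fixture <- function() fixture("closed", function()
  generate_hexamer(synthetic_spec(seed = 103,
                                  labels = c("ATP_STAR", "APO", "APO", "ATP_STAR", "APO", "APO"),
                                  label = "closed")))
pair_fixture <- function() fixture("pair", function()
  generate_state_pair(synthetic_spec(seed = 104, label = "compact"),
                      register_shift_cw = 1, label_b = "expanded"))

cpaf_scheme <- function() fixture("scheme", function() default_scheme())

# deposited PDB entries are not shipped with the package (they must be
# downloaded from the PDB); this resolves a local copy if the user has
# placed one under inst/extdata/deposited/
deposited_model <- function(id, label) {
  dir <- system.file("extdata", "deposited", package = "hexcycle")
  for (ext in c(".cif", ".cif.gz", ".pdb", ".pdb.gz")) {
    p <- file.path(dir, paste0(id, ext))
    if (file.exists(p)) return(read_structure(p, label = label, quiet = TRUE))
  }
  stop(sprintf(paste0("deposited entry %s not available: download it from the ",
                      "PDB into inst/extdata/deposited/ to run this validation"),
               id), call. = FALSE)
}
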