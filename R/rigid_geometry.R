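# Core rigid-body machinery: least-squares superposition (Kabsch, via SVD),
# rotation decomposition (twist about a chosen axis), symmetry-axis
# detection, and Calpha distance/displacement measurement.
#
# Sign convention for reported angles: "clockwise" is defined as seen from
# the chosen viewpoint along the axis.  The package's default viewpoint is
# the platform-facing side of the hexamer (the "top view"), i.e. looking
# down the +axis direction, under which a clockwise rotation is a negative
# right-handed rotation.

#' Construct a rigid transform
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param t length-3 translation vector; the transform maps `x` to `R x + t`.
#' @export
rigid_transform <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  if (!all(dim(R) == c(3, 3))) stopf("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8)
    stopf("rotation matrix is not special orthogonal within 1e-8")
  structure(list(R = R, t = as.numeric(t)), class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform a `rigid_transform`.
#' @param x numeric 3-vector or n x 3 matrix.
#' @export
apply_transform <- function(transform, x) {
  if (is.null(dim(x))) return(as.numeric(transform$R %*% x + transform$t))
  t(transform$R %*% t(x) + transform$t)
}

#' Invert a rigid transform
#' @inheritParams apply_transform
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$R), -as.numeric(t(transform$R) %*% transform$t))
}

#' Compose two rigid transforms (`b` applied after `a`)
#' @param a,b `rigid_transform` objects.
#' @return transform mapping `x` to `b(a(x))`.
#' @export
compose_transform <- function(b, a) {
  rigid_transform(b$R %*% a$R, as.numeric(b$R %*% a$t) + b$t)
}

#' Rotation angle of a transform in degrees, in [0, 180]
#' @inheritParams apply_transform
#' @export
rotation_angle <- function(transform) {
  rad2deg(acos(max(-1, min(1, (sum(diag(transform$R)) - 1) / 2))))
}

#' Rotation axis (unit vector) of a transform
#'
#' For a rotation by angle theta about axis a (right-handed), returns a.
#' The identity has no defined axis and returns `c(0, 0, 1)`.
#' @inheritParams apply_transform
#' @export
rotation_axis <- function(transform) {
  q <- .quat_from_rot(transform$R)
  v <- q[2:4]
  if (vnorm(v) < 1e-12) return(c(0, 0, 1))
  if (q[1] < 0) v <- -v   # canonical: angle in [0, 180]
  unitv(v)
}

# unit quaternion (w, x, y, z) from rotation matrix; numerically stable branch
.quat_from_rot <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / vnorm(q)
}

#' Least-squares rigid superposition of paired point sets
#'
#' Kabsch's solution: the returned transform minimises the RMSD between
#' `transform(mobile)` and `target` over all proper rigid transforms.
#' Points are paired by row index.
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3.
#' @return list with `transform` (a `rigid_transform`), `rmsd` (Angstrom)
#'   and `n` (number of point pairs used).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)))
    stopf("point sets differ in size: %d vs %d", nrow(mobile), nrow(target))
  n <- nrow(mobile)
  if (n < 3) stopf("superposition needs at least 3 point pairs, got %d", n)
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  H <- crossprod(P, Q)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    warnf("degenerate (collinear) point set; superposition is not unique")
  tr <- rigid_transform(R, ct - as.numeric(R %*% cm))
  dev <- apply_transform(tr, mobile) - target
  list(transform = tr, rmsd = sqrt(mean(rowSums(dev^2))), n = n)
}

#' Signed rotation component (twist) about a given axis
#'
#' Twist/swing decomposition: the transform's rotation is factored as a
#' rotation about `axis` (the twist, returned here) composed with a rotation
#' about an axis perpendicular to it (the swing).  The sign is chosen so
#' that a rotation that appears clockwise to an observer at the stated
#' viewpoint is positive.
#'
#' @inheritParams apply_transform
#' @param axis unit 3-vector.
#' @param viewpoint `"from_positive_axis"` (default; the hexamer top view
#'   when the axis points at the platform) or `"from_negative_axis"`.
#' @return signed angle in degrees in (-180, 180].
#' @export
rotation_about_axis <- function(transform, axis,
                                viewpoint = c("from_positive_axis",
                                              "from_negative_axis")) {
  viewpoint <- match.arg(viewpoint)
  a <- unitv(axis)
  q <- .quat_from_rot(transform$R)
  proj <- sum(q[2:4] * a)
  twist_rh <- 2 * atan2(proj, q[1])          # right-handed about +a
  twist_rh <- rad2deg(twist_rh)
  twist_rh <- ((twist_rh + 180) %% 360) - 180
  cw <- -twist_rh                            # clockwise seen from +a
  out <- if (viewpoint == "from_positive_axis") cw else -cw
  if (out <= -180) out <- out + 360
  out
}

.default_mapping <- function(chains, order) {
  n <- length(chains)
  if (n %% order != 0)
    stopf("chain count %d is not a multiple of symmetry order %d", n, order)
  step <- n / order
  stats::setNames(chains[(seq_len(n) - 1 + step) %% n + 1], chains)
}

#' Best-fit rotational symmetry axis of an oligomer
#'
#' Finds the rigid transform that maps every chain onto its symmetry mate
#' (for C2 on a hexamer: chain i onto chain i+3) by least-squares
#' superposition of all shared Calpha atoms, and reports its rotation axis.
#' The axis is oriented so that the fitted rotation is a positive
#' right-handed rotation about it; for order 2 (a 180 degree rotation, where
#' both orientations are equivalent) the orientation with a non-negative z
#' component is reported.
#'
#' @param model a `structure_model`.
#' @param order symmetry order (>= 2).
#' @param chain_mapping named character vector pairing each chain with its
#'   mate under one rotation step; default maps chain i to chain
#'   i + n/order cyclically in file order.
#' @param residual_ceiling warn-and-flag threshold on the residual RMSD (A).
#' @return a `symmetry_axis` object: `order`, `direction` (unit 3-vector),
#'   `point` (on the axis), `angle_deg` (fitted rotation), `residual_rmsd`,
#'   `flagged`.
#' @export
find_symmetry_axis <- function(model, order = 2, chain_mapping = NULL,
                               residual_ceiling = 3) {
  chains <- chain_ids(model)
  if (is.null(chain_mapping)) {
    if (length(chains) < 2) stopf("mapping error: need >= 2 chains, got %d", length(chains))
    chain_mapping <- .default_mapping(chains, order)
  }
  if (!all(chains %in% names(chain_mapping)))
    stopf("mapping error: unpaired chain(s): %s",
          paste(setdiff(chains, names(chain_mapping)), collapse = ", "))
  mob <- NULL; tgt <- NULL
  for (cc in chains) {
    mate <- chain_mapping[[cc]]
    a <- .ca_range(model, cc, -Inf, Inf)
    b <- .ca_range(model, mate, -Inf, Inf)
    shared <- intersect(rownames(a), rownames(b))
    mob <- rbind(mob, a[shared, , drop = FALSE])
    tgt <- rbind(tgt, b[shared, , drop = FALSE])
  }
  fit <- superpose(mob, tgt)
  ax <- rotation_axis(fit$transform)
  ang <- rotation_angle(fit$transform)
  if (order == 2 && ax[3] < 0) ax <- -ax
  centroid <- colMeans(mob)
  # point on the axis: solve (I - R) p = t for the component normal to the axis
  M <- diag(3) - fit$transform$R
  p <- tryCatch({
    sol <- qr.solve(M + tcrossprod(ax), fit$transform$t)
    sol - sum(sol * ax) * ax + sum(centroid * ax) * ax
  }, error = function(e) centroid)
  flagged <- fit$rmsd > residual_ceiling
  if (flagged)
    warnf("symmetry-axis residual RMSD %.2f A exceeds ceiling %.2f A",
          fit$rmsd, residual_ceiling)
  structure(list(order = as.integer(order), direction = ax, point = p,
                 angle_deg = ang, residual_rmsd = fit$rmsd, flagged = flagged,
                 n_ca = fit$n),
            class = "symmetry_axis")
}

#' @export
print.symmetry_axis <- function(x, ...) {
  cat(sprintf("<symmetry_axis> C%d  direction (%.4f, %.4f, %.4f)\n",
              x$order, x$direction[1], x$direction[2], x$direction[3]))
  cat(sprintf("  fitted rotation %.2f deg, residual RMSD %.3f A over %d Calpha%s\n",
              x$angle_deg, x$residual_rmsd, x$n_ca,
              if (x$flagged) "  [FLAGGED: residual above ceiling]" else ""))
  invisible(x)
}

#' Calpha-Calpha distance between two residues
#'
#' @param model a `structure_model`.
#' @param chain_a,residue_a,chain_b,residue_b residue addresses.
#' @return distance in Angstrom.
#' @export
ca_distance <- function(model, chain_a, residue_a, chain_b, residue_b) {
  vnorm(.ca_of(model, chain_a, residue_a) - .ca_of(model, chain_b, residue_b))
}

#' Residual Calpha displacement of a residue between two aligned states
#'
#' After mapping state A into state B's frame with `alignment`, the
#' displacement is the distance between the transformed position of the
#' residue's Calpha in A and its Calpha in B.
#'
#' @param state_a,state_b `structure_model` objects.
#' @param alignment `rigid_transform` mapping state A coordinates into
#'   state B's frame.
#' @param chain,residue residue address in state A.
#' @param chain_b chain holding the corresponding residue in state B
#'   (defaults to `chain`; differs when a chain-register shift applies).
#' @return displacement in Angstrom.
#' @export
residue_displacement <- function(state_a, state_b, alignment, chain, residue,
                                 chain_b = chain) {
  pa <- apply_transform(alignment, .ca_of(state_a, chain, residue))
  vnorm(pa - .ca_of(state_b, chain_b, residue))
}
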