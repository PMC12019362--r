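# Seeded toy hexamers with planted ground truth.
#
# Chains are idealised Calpha traces (not real folds) arranged about the
# z axis with 60 degree spacing.  Each chain's domains are placed by a
# label-dependent rigid transform: a clockwise twist about the hexamer axis
# plus a z lift (CAD) or inward radial shift (3HB/NTD).  Because those
# placements are exact rigid motions about the axis, the per-domain twist
# angles recovered by the analysis pipeline equal the planted values to
# numerical precision on noise-free fixtures.  Side-chain proxy atoms for
# the arginine fingers and the nucleotide ligands are positioned *after*
# the rigid placements, directly in final coordinates, so the requested
# engaged/disengaged/intermediate classifications hold by construction
# under the default thresholds.  Planted interface distances are recorded
# analytically in the ground truth, not asserted to match any particular
# real structure.

.SYN_LABELS <- c("ATP", "ADP", "APO", "ATP_STAR")

# label-dependent placement parameters (clockwise degrees, Angstrom)
.SYN_CAD_TWIST <- c(ATP = 42, ADP = 0, APO = 0, ATP_STAR = 42)
.SYN_HB_TWIST  <- c(ATP = 0,  ADP = 30, APO = 0, ATP_STAR = 0)
.SYN_CAD_LIFT  <- c(ATP = 7.5, ADP = 3, APO = 0, ATP_STAR = 7.5)
.SYN_HB_INWARD <- c(ATP = 3,  ADP = 0, APO = 0, ATP_STAR = 3)

#' Specify a synthetic hexamer
#'
#' The defaults emulate the study conditions of the CpaF catalytic cycle:
#' six chains with C2 symmetry, the compact-state label pattern
#' (ATP, ADP, APO) twice, a 42 degree clockwise CAD twist planted on ATP
#' binding and a 30 degree clockwise 3HB/NTD twist on hydrolysis.
#'
#' @param seed integer RNG seed; the generator is deterministic given the
#'   spec.
#' @param labels chain nucleotide/state labels, length 6, drawn from
#'   `ATP`, `ADP`, `APO`, `ATP_STAR`.
#' @param symmetry `"exact_C2"` (labels must repeat with period 3),
#'   `"exact_C6"` (all labels equal), or `"none"` (small per-chain rigid
#'   jitter breaks the symmetry).
#' @param noise_sigma isotropic Gaussian coordinate jitter (A).
#' @param cad_twist,hb_twist planted clockwise twists (degrees, top view)
#'   of the CAD and of the 3HB+NTD block, named by label.
#' @param cad_lift planted CAD z lift per label (A); this is what raises
#'   the extended pore loop of nucleotide-bound chains.
#' @param hb_inward planted inward radial shift of the 3HB+NTD block (A).
#' @param arginine_states optional per-unit override (length 6, values
#'   `engaged`/`disengaged`/`intermediate`); default derives from the
#'   pocket: ATP engaged, ADP disengaged, empty intermediate.
#' @param loop_heights optional extra per-chain CAD elevation (A) on top of
#'   `cad_lift`, for planting custom pore-loop height patterns.
#' @param place_ligands plant ATP/ADP/Mg ligands in the pockets.
#' @param label model label.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(seed = 1,
                           labels = c("ATP", "ADP", "APO", "ATP", "ADP", "APO"),
                           symmetry = c("exact_C2", "exact_C6", "none"),
                           noise_sigma = 0,
                           cad_twist = .SYN_CAD_TWIST,
                           hb_twist = .SYN_HB_TWIST,
                           cad_lift = .SYN_CAD_LIFT,
                           hb_inward = .SYN_HB_INWARD,
                           arginine_states = NULL,
                           loop_heights = NULL,
                           place_ligands = TRUE,
                           label = "synthetic") {
  symmetry <- match.arg(symmetry)
  if (length(labels) != 6) stopf("labels must have length 6, got %d", length(labels))
  if (!all(labels %in% .SYN_LABELS))
    stopf("invalid label(s): %s", paste(setdiff(labels, .SYN_LABELS), collapse = ", "))
  if (symmetry == "exact_C6" && length(unique(labels)) != 1)
    stopf("inconsistent spec: exact_C6 requires uniform chain labels")
  if (symmetry == "exact_C2" && !identical(labels[1:3], labels[4:6]))
    stopf("inconsistent spec: exact_C2 requires labels to repeat with period 3")
  if (!is.null(arginine_states) && length(arginine_states) != 6)
    stopf("arginine_states must have length 6")
  if (!is.null(loop_heights) && length(loop_heights) != 6)
    stopf("loop_heights must have length 6")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  structure(list(seed = as.integer(seed), labels = labels, symmetry = symmetry,
                 noise_sigma = noise_sigma, cad_twist = cad_twist,
                 hb_twist = hb_twist, cad_lift = cad_lift,
                 hb_inward = hb_inward, arginine_states = arginine_states,
                 loop_heights = loop_heights, place_ligands = place_ligands,
                 label = label),
            class = "synthetic_spec")
}

# deterministic base Calpha trace in the position-0 frame; columns
# resno, domain, az (deg), r, z.  Anchor residues sit at fixed positions.
.syn_template <- function() {
  arc <- function(resnos, domain, r0, ramp, az0, az1, z0, z1) {
    n <- length(resnos)
    i <- seq_len(n)
    data.frame(resno = resnos, domain = domain,
               az = seq(az0, az1, length.out = n),
               r = r0 + ramp * cos(i * 0.9),
               z = seq(z0, z1, length.out = n) + 0.6 * sin(i * 0.7))
  }
  tpl <- rbind(
    arc(80:146, "THREE_HELIX_BUNDLE", 11, 4, -25, 25, 8, 20),
    arc(147:270, "NTD", 19, 4, -36, 20, 0, 8),
    arc(271:501, "CAD", 25, 2.5, -45, 32, -2, 4))
  fix <- function(resno, az, r, z) {
    k <- match(resno, tpl$resno)
    tpl$az[k] <<- az; tpl$r[k] <<- r; tpl$z[k] <<- z
  }
  fix(116, 0, 11, 12)            # D116, pore-lining 3HB marker
  fix(196, -10, 20, 5)           # C196, NTD marker
  fix(217, -25, 18, 3)           # R217
  fix(223, -20, 18, 3.5)         # R223
  # Walker A arc, centroid at (r 24, az -30, z 0.5); G284 exactly at az -30
  wa_az <- c(-30, -27, -33, -28.5, -31.5, -30)
  wa_z <- c(0, 1, 0.5, 0.8, 0.3, 0.4)
  for (k in seq_along(284:289)) fix((284:289)[k], wa_az[k], 24, wa_z[k])
  # extended pore loop projecting into the pore; E331 at (r 9, az 5, z 3)
  pl <- 325:337
  for (k in seq_along(pl)) fix(pl[k], seq(-6, 16, length.out = 13)[k], 9,
                               seq(2.6, 3.4, length.out = 13)[k])
  fix(331, 5, 9, 3)
  fix(347, -4, 24, 1)            # R347 Calpha on alpha9
  tpl
}

.cyl2cart <- function(az_deg, r, z) {
  cbind(x = r * cos(deg2rad(az_deg)), y = r * sin(deg2rad(az_deg)), z = z)
}

# rigid placement of one domain's local coordinates for one chain:
# inward radial shift and z lift in the position-0 frame, clockwise twist
# about the global axis, then rotation to the chain position.
.syn_place <- function(xyz, theta_deg, cw_twist_deg, inward = 0, lift = 0) {
  m <- as.matrix(xyz)
  # inward shift acts along -x in the position-0 frame
  m[, 1] <- m[, 1] - inward
  m[, 3] <- m[, 3] + lift
  t(rotz(deg2rad(theta_deg - cw_twist_deg)) %*% t(m))
}

.syn_chain_params <- function(spec, lab) {
  list(cad_cw = spec$cad_twist[[lab]], hb_cw = spec$hb_twist[[lab]],
       lift = spec$cad_lift[[lab]], inward = spec$hb_inward[[lab]])
}

# final-coordinate anchor position for one chain (pre-jitter, pre-noise)
.syn_anchor_pos <- function(tpl, spec, chain_idx, resno, extra_lift = 0) {
  k <- match(resno, tpl$resno)
  p <- .syn_chain_params(spec, spec$labels[chain_idx])
  dom <- tpl$domain[k]
  xyz <- .cyl2cart(tpl$az[k], tpl$r[k], tpl$z[k])
  if (dom == "CAD")
    .syn_place(xyz, 60 * (chain_idx - 1), p$cad_cw, 0, p$lift + extra_lift)[1, ]
  else
    .syn_place(xyz, 60 * (chain_idx - 1), p$hb_cw, p$inward, 0)[1, ]
}

.arg_sidechain <- function(ca, u) {
  u <- unitv(u)
  perp <- unitv(pracma_cross(u, if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
  rbind(CB = ca + 1.5 * u, CG = ca + 2.6 * u, CD = ca + 3.9 * u,
        NE = ca + 4.9 * u, CZ = ca + 4.5 * u + 0.4 * perp,
        NH1 = ca + 5.7 * u, NH2 = ca + 5.2 * u + 1.1 * perp)
}

.atom_rows <- function(xyz, elety, element, resid, chain, resno, het = FALSE) {
  data.frame(elety = elety, element = element, resid = resid, chain = chain,
             resno = as.integer(resno), insert = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
             het = het, stringsAsFactors = FALSE)
}

#' Generate a synthetic hexamer with planted ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with `model` (a `structure_model`) and `truth` (a
#'   `synthetic_truth` list holding everything planted: axis, chain order,
#'   labels, conformer groups, arginine states, analytic interface
#'   distances, pore-loop heights and span).
#' @export
generate_hexamer <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) stopf("spec must be a synthetic_spec")
  set.seed(spec$seed)
  .syn_build(spec)
}

.syn_build <- function(spec) {
  tpl <- .syn_template()
  chains <- LETTERS[1:6]
  extra <- spec$loop_heights %||% rep(0, 6)
  # per-chain rigid jitter for asymmetric fixtures
  jitter <- lapply(1:6, function(i) {
    if (spec$symmetry != "none") return(rigid_transform())
    ax <- unitv(stats::rnorm(3))
    rigid_transform(rot_axis(ax, deg2rad(stats::runif(1, 0.2, 0.8))),
                    stats::runif(3, -0.4, 0.4))
  })
  place_chain_ca <- function(i) {
    lab <- spec$labels[i]
    p <- .syn_chain_params(spec, lab)
    theta <- 60 * (i - 1)
    is_cad <- tpl$domain == "CAD"
    xyz <- matrix(0, nrow(tpl), 3)
    xyz[is_cad, ] <- .syn_place(.cyl2cart(tpl$az[is_cad], tpl$r[is_cad], tpl$z[is_cad]),
                                theta, p$cad_cw, 0, p$lift + extra[i])
    xyz[!is_cad, ] <- .syn_place(.cyl2cart(tpl$az[!is_cad], tpl$r[!is_cad], tpl$z[!is_cad]),
                                 theta, p$hb_cw, p$inward, 0)
    cen <- colMeans(xyz)
    sweep(apply_transform(jitter[[i]], sweep(xyz, 2, cen)), 2, -cen)
  }
  ca_list <- lapply(1:6, place_chain_ca)

  aa_for <- function(resno) {
    anchors <- c("116" = "ASP", "196" = "CYS", "217" = "ARG", "223" = "ARG",
                 "284" = "GLY", "287" = "LYS", "288" = "THR", "312" = "GLU",
                 "331" = "GLU", "347" = "ARG", "357" = "GLU")
    out <- anchors[as.character(resno)]
    out[is.na(out)] <- "ALA"
    out
  }
  atoms <- do.call(rbind, lapply(1:6, function(i)
    .atom_rows(ca_list[[i]], "CA", "C", aa_for(tpl$resno), chains[i], tpl$resno)))

  # helper: final anchor position of chain i (jitter included)
  anchor_pos <- function(i, resno) {
    ca_list[[i]][match(resno, tpl$resno), ]
  }
  wa_centroid <- function(i) colMeans(ca_list[[i]][match(284:289, tpl$resno), ])
  axis_point <- c(0, 0, 0)
  inward_at <- function(p) {
    r <- p - axis_point
    r[3] <- 0
    -unitv(r)
  }

  # pocket of chain i: its own Walker A; nucleotide = its label
  pocket_nuc <- ifelse(spec$labels %in% c("APO", "ATP_STAR"), "APO", spec$labels)
  arg_req <- spec$arginine_states %||%
    ifelse(pocket_nuc == "ATP", "engaged",
           ifelse(pocket_nuc == "ADP", "disengaged", "intermediate"))

  lig_atoms <- NULL
  p0 <- vector("list", 6)
  for (i in 1:6) {
    if (pocket_nuc[i] == "APO" || !spec$place_ligands) next
    wc <- wa_centroid(i)
    p0[[i]] <- wc + 2.0 * inward_at(wc)
  }

  side_atoms <- NULL
  for (i in 1:6) {
    prev <- (i - 2) %% 6 + 1          # adjacent CAD donor of unit i
    pocket_ref <- p0[[i]] %||% wa_centroid(i)
    req <- arg_req[i]
    # R347 belongs to the previous chain's CAD and serves pocket i
    ca347 <- anchor_pos(prev, 347)
    u347 <- switch(req,
                   engaged = unitv(pocket_ref - ca347),
                   disengaged = unitv(ca347 - pocket_ref),
                   intermediate = inward_at(ca347))
    sc <- .arg_sidechain(ca347, u347)
    if (req == "engaged" && !is.null(p0[[i]]))
      sc["NH1", ] <- ca347 + (vnorm(p0[[i]] - ca347) - 2.9) * u347
    side_atoms <- rbind(side_atoms,
                        .atom_rows(sc, rownames(sc), substr(rownames(sc), 1, 1),
                                   "ARG", chains[prev], 347))
    # R217 / R223 on the owner NTD serve the same pocket
    for (rr in c(217, 223)) {
      car <- anchor_pos(i, rr)
      ur <- if (req == "disengaged") unitv(car - pocket_ref)
            else unitv(pocket_ref - car)
      scr <- .arg_sidechain(car, ur)
      side_atoms <- rbind(side_atoms,
                          .atom_rows(scr, rownames(scr), substr(rownames(scr), 1, 1),
                                     "ARG", chains[i], rr))
    }
    # ligand
    if (!is.null(p0[[i]])) {
      w <- unitv(pracma_cross(c(0, 0, 1), inward_at(wa_centroid(i))))
      base <- p0[[i]]
      if (pocket_nuc[i] == "ATP") {
        pg <- base + 0.8 * w; pb <- base - 0.8 * w; pa <- base - 2.4 * w
        nh1 <- ca347 + (vnorm(base - ca347) - 2.9) * u347
        o3g <- pg + 1.4 * unitv(nh1 - pg)
        lx <- rbind(PA = pa, PB = pb, PG = pg, O3G = o3g,
                    O1G = pg + c(0, 0, 1.4), O2G = pg - 1.4 * w,
                    O1B = pb + c(0, 0, 1.4), O1A = pa + c(0, 0, 1.4))
        lig_atoms <- rbind(lig_atoms,
                           .atom_rows(lx, rownames(lx),
                                      substr(rownames(lx), 1, 1), "ATP",
                                      chains[i], 601, het = TRUE))
      } else {
        pa <- base - 0.8 * w; pb <- base + 0.8 * w
        lx <- rbind(PA = pa, PB = pb, O1B = pb + c(0, 0, 1.4),
                    O2B = pb + 1.4 * w, O1A = pa + c(0, 0, 1.4))
        lig_atoms <- rbind(lig_atoms,
                           .atom_rows(lx, rownames(lx),
                                      substr(rownames(lx), 1, 1), "ADP",
                                      chains[i], 601, het = TRUE))
      }
      mg <- base + c(0, 0, 2.2)
      lig_atoms <- rbind(lig_atoms,
                         .atom_rows(rbind(MG = mg), "MG", "MG", "MG",
                                    chains[i], 701, het = TRUE))
    }
  }

  all_atoms <- rbind(atoms, side_atoms, lig_atoms)
  if (spec$noise_sigma > 0) {
    n <- nrow(all_atoms)
    all_atoms$x <- all_atoms$x + stats::rnorm(n, 0, spec$noise_sigma)
    all_atoms$y <- all_atoms$y + stats::rnorm(n, 0, spec$noise_sigma)
    all_atoms$z <- all_atoms$z + stats::rnorm(n, 0, spec$noise_sigma)
  }
  model <- structure_model(all_atoms, label = spec$label, source_path = "synthetic")

  # ---- ground truth (analytic, pre-noise, pre-jitter where relevant) ----
  g284 <- function(i) .syn_anchor_pos(tpl, spec, i, 284, extra[i])
  r347 <- function(i) .syn_anchor_pos(tpl, spec, i, 347, extra[i])
  d_347_284 <- vapply(1:6, function(i) {
    prev <- (i - 2) %% 6 + 1
    vnorm(r347(prev) - g284(i))
  }, numeric(1))
  lifts <- vapply(1:6, function(i) spec$cad_lift[[spec$labels[i]]] + extra[i],
                  numeric(1))
  # E331 base z is 3, the Walker A centroid plane sits at base z 0.5
  heights <- 2.5 + lifts - mean(lifts)
  span_asym <- max(heights[1:3]) - min(heights[1:3])

  truth <- structure(list(
    seed = spec$seed, symmetry = spec$symmetry, noise_sigma = spec$noise_sigma,
    axis_direction = c(0, 0, 1), axis_point = axis_point,
    chain_order = chains, adjacency = "previous",
    labels = stats::setNames(spec$labels, chains),
    nucleotides = stats::setNames(pocket_nuc, chains),
    conformers = stats::setNames(sub("ATP_STAR", "ATP", spec$labels), chains),
    arginine_states = stats::setNames(arg_req, chains),
    r347_g284 = stats::setNames(d_347_284, chains),
    loop_heights = stats::setNames(heights, chains),
    loop_height_span = span_asym,
    cad_twist = spec$cad_twist, hb_twist = spec$hb_twist,
    cad_lift = spec$cad_lift), class = "synthetic_truth")
  list(model = model, truth = truth)
}

.TRANSITION <- c(APO = "ATP", ATP = "ADP", ADP = "ADP")   # forward (binding/hydrolysis/carry)

#' Generate a pair of hexamer states related by a catalytic transition
#'
#' State A is built from `spec_a`; state B carries the transitioned labels
#' (APO to ATP, ATP to ADP, ADP carried) under a planted clockwise
#' chain-register shift, with the label-dependent domain placements
#' supplying the planted per-domain twists.  The ground truth records the
#' register, the event kinds, the per-domain clockwise twist of every
#' event, and the anchor displacement tables.
#'
#' @param spec_a a [synthetic_spec()] for the source state; labels must not
#'   contain `ATP_STAR`.
#' @param register_shift_cw clockwise register shift in chain positions
#'   (+1 mirrors the compact-to-expanded transition).
#' @param label_b model label for the target state.
#' @return list with `model_a`, `model_b` and `truth` (a
#'   `synthetic_pair_truth`).
#' @export
generate_state_pair <- function(spec_a, register_shift_cw = 1L,
                                label_b = "state_b") {
  if (!inherits(spec_a, "synthetic_spec")) stopf("spec_a must be a synthetic_spec")
  if (any(spec_a$labels == "ATP_STAR"))
    stopf("inconsistent spec: state pairs are defined for ATP/ADP/APO labels")
  s <- as.integer(register_shift_cw)
  if (!s %in% c(-1L, 1L)) stopf("register_shift_cw must be +1 or -1")
  idx_b <- function(j) ((j - 1L + s) %% 6L) + 1L  # A chain paired with B pos j
  labels_b <- vapply(1:6, function(j) .TRANSITION[[spec_a$labels[idx_b(j)]]],
                     character(1))
  set.seed(spec_a$seed)
  a <- .syn_build(spec_a)
  spec_b <- spec_a
  spec_b$labels <- labels_b
  spec_b$label <- label_b
  if (spec_b$symmetry == "exact_C6" && length(unique(labels_b)) != 1)
    spec_b$symmetry <- "exact_C2"
  b <- .syn_build(spec_b)

  chains <- LETTERS[1:6]
  tpl <- .syn_template()
  doms <- c("THREE_HELIX_BUNDLE", "NTD", "CAD")
  anchor_dom <- c(D116 = "THREE_HELIX_BUNDLE", C196 = "NTD",
                  G284 = "CAD", E331 = "CAD")
  anchor_res <- c(D116 = 116, C196 = 196, G284 = 284, E331 = 331)
  pos0 <- function(lab, resno) {
    sp <- spec_a; sp$labels <- rep(lab, 6)
    .syn_anchor_pos(tpl, sp, 1, resno)
  }
  events <- lapply(1:6, function(j) {
    la <- spec_a$labels[idx_b(j)]; lb <- labels_b[j]
    kind <- if (la == "APO") "ATP_BINDING" else if (la == "ATP") "HYDROLYSIS" else "CARRY"
    tw <- c(THREE_HELIX_BUNDLE = spec_a$hb_twist[[lb]] - spec_a$hb_twist[[la]],
            NTD = spec_a$hb_twist[[lb]] - spec_a$hb_twist[[la]],
            CAD = spec_a$cad_twist[[lb]] - spec_a$cad_twist[[la]])
    disp <- vapply(names(anchor_res), function(nm)
      vnorm(pos0(lb, anchor_res[[nm]]) - pos0(la, anchor_res[[nm]])), numeric(1))
    list(source_chain = chains[idx_b(j)], target_chain = chains[j],
         from = la, to = lb, kind = kind, twist_cw = tw, displacement = disp)
  })
  release <- lapply(1:6, function(q) {
    # reverse (contraction) pairing: B chain q maps onto A chain q - s
    ia <- ((q - 1 - s) %% 6) + 1
    la <- labels_b[q]; lb <- spec_a$labels[ia]
    if (!(la == "ADP" && lb == "APO")) return(NULL)
    tw <- c(THREE_HELIX_BUNDLE = spec_a$hb_twist[[lb]] - spec_a$hb_twist[[la]],
            NTD = spec_a$hb_twist[[lb]] - spec_a$hb_twist[[la]],
            CAD = spec_a$cad_twist[[lb]] - spec_a$cad_twist[[la]])
    disp <- vapply(names(anchor_res), function(nm)
      vnorm(pos0(lb, anchor_res[[nm]]) - pos0(la, anchor_res[[nm]])), numeric(1))
    list(source_chain = chains[q], target_chain = chains[ia],
         from = la, to = lb, kind = "ADP_RELEASE", twist_cw = tw,
         displacement = disp)
  })
  release <- release[!vapply(release, is.null, logical(1))]
  truth <- structure(list(
    register_shift_cw = s, register_deg_cw = 60 * s,
    reverse_shift_cw = -s,
    pairing = data.frame(a_chain = chains[vapply(1:6, idx_b, integer(1))],
                         b_chain = chains),
    events = events, release_events = release,
    labels_a = stats::setNames(spec_a$labels, chains),
    labels_b = stats::setNames(labels_b, chains),
    truth_a = a$truth, truth_b = b$truth), class = "synthetic_pair_truth")
  list(model_a = a$model, model_b = b$model, truth = truth)
}
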