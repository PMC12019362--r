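# Mapping catalytic events between two hexamer states.
#
# The two states are related by a one-position chain-register shift about
# the shared symmetry axis: superposing them so that corresponding
# monomers align rotates the register by 60 degrees (clockwise in the
# expanding direction).  The register is found by exhaustive search over
# cyclic shifts, scored by catalytic-transition consistency of the
# chain-state labels (APO->ATP binding, ATP->ADP hydrolysis, ADP carried).
# ADP release is mapped in the contracting direction (later state onto the
# earlier one) on the same axis, where the original earlier-state model
# stands in for the post-cycle hexamer.  The inter-state alignment is
# fitted on the label-unchanged ("carry") chains, the ones not undergoing
# a catalytic event.

.FORWARD_RULES <- list(APO = "ATP", ATP = "ADP", ADP = "ADP")
.REVERSE_RULES <- list(ATP = "ATP", ADP = c("ADP", "APO"))

.shift_mismatches <- function(lab_a, lab_b, s, rules) {
  n <- length(lab_a)
  sum(vapply(seq_len(n), function(p) {
    la <- lab_a[p]; lb <- lab_b[((p - 1 + s) %% n) + 1]
    allowed <- rules[[la]] %||% character(0)
    !(lb %in% allowed)
  }, logical(1)))
}

.canonical_shift <- function(s, n = 6) {
  s <- s %% n
  ifelse(s > n / 2, s - n, s)
}

# whole-hexamer alignment for a given pairing, fitted on the given chain
# pairs (falls back to all pairs)
.pair_alignment <- function(model_src, model_tgt, pairs, fit_pairs = NULL) {
  use <- if (!is.null(fit_pairs) && nrow(fit_pairs)) fit_pairs else pairs
  mob <- NULL; tgt <- NULL
  for (k in seq_len(nrow(use))) {
    a <- .ca_range(model_src, use$src_chain[k], -Inf, Inf)
    b <- .ca_range(model_tgt, use$tgt_chain[k], -Inf, Inf)
    sh <- intersect(rownames(a), rownames(b))
    mob <- rbind(mob, a[sh, , drop = FALSE])
    tgt <- rbind(tgt, b[sh, , drop = FALSE])
  }
  superpose(mob, tgt)
}

.domain_ca_sets <- function(model, owner, adjacent, scheme) {
  cad <- scheme$domains$CAD
  list(THREE_HELIX_BUNDLE = .ca_range(model, owner,
                                      scheme$domains$THREE_HELIX_BUNDLE[1],
                                      scheme$domains$THREE_HELIX_BUNDLE[2]),
       NTD = .ca_range(model, owner, scheme$domains$NTD[1], scheme$domains$NTD[2]),
       CAD = .ca_range(model, owner, cad[1], cad[2]),
       CAD_adjacent = .ca_range(model, adjacent, cad[1], cad[2]))
}

.event_build <- function(model_src, model_tgt, units_src, units_tgt,
                         src_chain, tgt_chain, kind, alignment, axis, scheme,
                         viewpoint, direction) {
  u_src <- units_src[units_src$owner_chain == src_chain, ]
  u_tgt <- units_tgt[units_tgt$owner_chain == tgt_chain, ]
  ds <- .domain_ca_sets(model_src, src_chain, u_src$adjacent_chain, scheme)
  dt <- .domain_ca_sets(model_tgt, tgt_chain, u_tgt$adjacent_chain, scheme)
  transforms <- lapply(names(ds), function(nm) {
    sh <- intersect(rownames(ds[[nm]]), rownames(dt[[nm]]))
    if (length(sh) < 3) return(NULL)
    superpose(apply_transform(alignment, ds[[nm]][sh, , drop = FALSE]),
              dt[[nm]][sh, , drop = FALSE])$transform
  })
  names(transforms) <- names(ds)
  twists <- vapply(names(transforms), function(nm) {
    if (is.null(transforms[[nm]])) return(NA_real_)
    rotation_about_axis(transforms[[nm]], axis$direction, viewpoint)
  }, numeric(1))
  anchors <- c("D116", "C196", "G284", "E331")
  disp <- vapply(anchors, function(nm) {
    resno <- scheme$anchors[[nm]]
    tryCatch(residue_displacement(model_src, model_tgt, alignment,
                                  src_chain, resno, chain_b = tgt_chain),
             error = function(e) NA_real_)
  }, numeric(1))
  structure(list(kind = kind, direction = direction,
                 source_chain = src_chain, target_chain = tgt_chain,
                 source_unit = u_src$name, target_unit = u_tgt$name,
                 transforms = transforms, twist_deg = twists,
                 displacement = disp, axis = axis, viewpoint = viewpoint),
            class = "catalytic_event")
}

#' @export
print.catalytic_event <- function(x, ...) {
  cat(sprintf("<catalytic_event> %s  %s -> %s (%s)\n", x$kind,
              x$source_unit, x$target_unit, x$direction))
  tw <- paste(sprintf("%s %+.1f", names(x$twist_deg), x$twist_deg), collapse = ", ")
  cat("  twists (deg, clockwise from viewpoint):", tw, "\n")
  dp <- paste(sprintf("%s %.1f", names(x$displacement), x$displacement), collapse = ", ")
  cat("  anchor displacements (A):", dp, "\n")
  invisible(x)
}

#' Map the catalytic events between two hexamer states
#'
#' Finds the chain-register shift under which every chain-state transition
#' from `state_a` to `state_b` is catalytically consistent, aligns the two
#' hexamers on the label-unchanged chains, and instantiates ATP-binding and
#' hydrolysis events (expanding direction) plus ADP-release events
#' (contracting direction, later state mapped back onto the earlier one on
#' the same axis).  If `state_a` turns out to be the later state the map is
#' computed in the opposite order and inverted: the register is negated and
#' binding/release kinds swap.
#'
#' @param state_a,state_b `structure_model` hexamers (e.g. compact and
#'   expanded).
#' @param scheme a `domain_scheme`.
#' @param thresholds see [default_thresholds()].
#' @param viewpoint viewpoint for signed angles, see
#'   [rotation_about_axis()].
#' @return an object of class `cycle_map`: register shift and rotation,
#'   direction summary, the fitted alignments, six `catalytic_event`
#'   objects (three kinds, each twice by C2 symmetry) plus the carry
#'   pairings, and the per-register mismatch diagnostics.
#' @export
map_catalytic_events <- function(state_a, state_b, scheme,
                                 thresholds = default_thresholds(),
                                 viewpoint = "from_positive_axis") {
  if (!nzchar(state_a$label)) state_a$label <- "state_a"
  if (!nzchar(state_b$label)) state_b$label <- "state_b"
  if (identical(state_a$label, state_b$label))
    state_b$label <- paste0(state_b$label, "_b")
  st_a <- label_chain_states(state_a, scheme, reference = state_b, thresholds = thresholds)
  st_b <- label_chain_states(state_b, scheme, reference = state_a, thresholds = thresholds)
  units_a <- build_packing_units(state_a, scheme, states = st_a, thresholds = thresholds)
  units_b <- build_packing_units(state_b, scheme, states = st_b, thresholds = thresholds)
  ord_a <- attr(units_a, "chain_order"); ord_b <- attr(units_b, "chain_order")
  lab_a <- st_a$label[match(ord_a, st_a$chain)]
  lab_b <- st_b$label[match(ord_b, st_b$chain)]

  mm <- data.frame(shift = 0:5,
                   forward = vapply(0:5, function(s)
                     .shift_mismatches(lab_a, lab_b, s, .FORWARD_RULES), numeric(1)),
                   identity = vapply(0:5, function(s)
                     .shift_mismatches(lab_a, lab_b, s,
                                       as.list(stats::setNames(c("ATP", "ADP", "APO", "ATP_STAR"),
                                                               c("ATP", "ADP", "APO", "ATP_STAR")))),
                     numeric(1)))
  ok_fwd <- mm$shift[mm$forward == 0]
  if (!length(ok_fwd)) {
    # maybe the arguments are in the reverse temporal order
    rev_ok <- vapply(0:5, function(s)
      .shift_mismatches(lab_b, lab_a, s, .FORWARD_RULES), numeric(1))
    if (any(rev_ok == 0)) {
      inner <- map_catalytic_events(state_b, state_a, scheme, thresholds, viewpoint)
      return(.invert_cycle_map(inner))
    }
    ok_id <- mm$shift[mm$identity == 0]
    if (length(ok_id)) {
      s <- .canonical_shift(ok_id[which.min(abs(.canonical_shift(ok_id)))])
      pairs <- data.frame(src_chain = ord_a,
                          tgt_chain = ord_b[((seq_len(6) - 1 + s) %% 6) + 1])
      fit <- .pair_alignment(state_a, state_b, pairs)
      return(structure(list(register_shift = s, register_deg_cw = 0,
                            non_catalytic = TRUE, direction_summary = "none",
                            axis = attr(units_b, "axis"),
                            alignment = fit$transform,
                            alignment_rmsd = fit$rmsd,
                            events = list(), carries = pairs,
                            mismatch_table = mm, viewpoint = viewpoint,
                            units_a = units_a, units_b = units_b),
                       class = "cycle_map"))
    }
    stopf(paste0("mapping failure: no chain register yields a consistent ",
                 "transition map\n  per-register forward mismatches: ",
                 paste(sprintf("s=%d:%d", mm$shift, mm$forward), collapse = ", ")))
  }
  # shifts s and s+3 are equivalent under C2; take the canonical representative
  cand <- unique(vapply(ok_fwd, .canonical_shift, numeric(1)))
  cand <- cand[abs(cand) == 1]
  if (!length(cand))
    stopf("mapping failure: consistent register is not a one-position shift (%s)",
          paste(ok_fwd, collapse = ","))
  if (length(cand) > 1)
    stopf("mapping failure: register is ambiguous (+60 and -60 both consistent)")
  s <- cand[1]
  # pairing: A chain at cyclic position p maps onto B chain at p + s;
  # positions are counterclockwise in the top view, so a negative s is a
  # clockwise register rotation
  idx_b <- ((seq_len(6) - 1 + s) %% 6) + 1
  pairs <- data.frame(src_chain = ord_a, tgt_chain = ord_b[idx_b],
                      from = lab_a, to = lab_b[idx_b],
                      stringsAsFactors = FALSE)
  register_deg_cw <- -60 * s
  carries <- pairs[pairs$from == "ADP" & pairs$to == "ADP", ]
  fit <- .pair_alignment(state_a, state_b, pairs, carries)
  axis_b <- attr(units_b, "axis"); axis_a <- attr(units_a, "axis")
  align_twist <- rotation_about_axis(fit$transform, axis_b$direction, viewpoint)

  events <- list()
  for (k in seq_len(nrow(pairs))) {
    kind <- if (pairs$from[k] == "APO" && pairs$to[k] == "ATP") "ATP_BINDING"
            else if (pairs$from[k] == "ATP" && pairs$to[k] == "ADP") "HYDROLYSIS"
            else next
    events[[length(events) + 1]] <-
      .event_build(state_a, state_b, units_a, units_b,
                   pairs$src_chain[k], pairs$tgt_chain[k], kind, fit$transform,
                   axis_b, scheme, viewpoint, "expanding")
  }
  # ADP release: contracting direction, the earlier state standing in for
  # the post-cycle hexamer on the same axis
  rev_mm <- vapply(0:5, function(ss)
    .shift_mismatches(lab_b, lab_a, ss, .REVERSE_RULES), numeric(1))
  rev_ok <- (0:5)[rev_mm == 0]
  if (length(rev_ok)) {
    srv <- .canonical_shift(rev_ok[which.min(abs(.canonical_shift(rev_ok)))])
    idx_a <- ((seq_len(6) - 1 + srv) %% 6) + 1
    rpairs <- data.frame(src_chain = ord_b, tgt_chain = ord_a[idx_a],
                         from = lab_b, to = lab_a[idx_a],
                         stringsAsFactors = FALSE)
    rcarry <- rpairs[rpairs$from == rpairs$to, ]
    rfit <- .pair_alignment(state_b, state_a, rpairs, rcarry)
    for (k in seq_len(nrow(rpairs))) {
      if (!(rpairs$from[k] == "ADP" && rpairs$to[k] == "APO")) next
      events[[length(events) + 1]] <-
        .event_build(state_b, state_a, units_b, units_a,
                     rpairs$src_chain[k], rpairs$tgt_chain[k], "ADP_RELEASE",
                     rfit$transform, axis_a, scheme, viewpoint, "contracting")
    }
  } else {
    warnf("no consistent contracting register; ADP-release events not mapped")
  }
  structure(list(register_shift = s, register_deg_cw = register_deg_cw,
                 non_catalytic = FALSE,
                 direction_summary = if (register_deg_cw > 0) "clockwise"
                                     else "counterclockwise",
                 axis = axis_b, axis_a = axis_a,
                 alignment = fit$transform, alignment_rmsd = fit$rmsd,
                 alignment_twist_deg = align_twist,
                 events = events, carries = carries, pairs = pairs,
                 mismatch_table = mm, viewpoint = viewpoint,
                 units_a = units_a, units_b = units_b),
            class = "cycle_map")
}

.invert_cycle_map <- function(map) {
  swap <- c(ATP_BINDING = "ADP_RELEASE", HYDROLYSIS = "HYDROLYSIS",
            ADP_RELEASE = "ATP_BINDING")
  map$register_deg_cw <- -map$register_deg_cw
  map$register_shift <- -map$register_shift
  map$direction_summary <- if (map$register_deg_cw > 0) "clockwise"
                           else if (map$register_deg_cw < 0) "counterclockwise"
                           else map$direction_summary
  map$inverted <- TRUE
  map$events <- lapply(map$events, function(ev) {
    ev$kind <- swap[[ev$kind]]
    tmp <- ev$source_chain; ev$source_chain <- ev$target_chain; ev$target_chain <- tmp
    tmp <- ev$source_unit; ev$source_unit <- ev$target_unit; ev$target_unit <- tmp
    ev$transforms <- lapply(ev$transforms, function(tr)
      if (is.null(tr)) NULL else invert_transform(tr))
    ev$twist_deg <- -ev$twist_deg
    ev
  })
  map
}

#' @export
print.cycle_map <- function(x, ...) {
  cat("<cycle_map>\n")
  if (isTRUE(x$non_catalytic)) {
    cat("  register 0 (non-catalytic: chain states are unchanged)\n")
    return(invisible(x))
  }
  cat(sprintf("  register: %+d position(s), %+.0f deg %s (viewpoint %s)\n",
              x$register_shift, x$register_deg_cw, x$direction_summary,
              x$viewpoint))
  cat(sprintf("  alignment twist %.1f deg, fit RMSD %.2f A on carry chains\n",
              x$alignment_twist_deg %||% NA, x$alignment_rmsd))
  for (ev in x$events)
    cat(sprintf("  %-12s %-10s -> %-10s  CAD %+6.1f  NTD %+6.1f  3HB %+6.1f deg\n",
                ev$kind, ev$source_unit, ev$target_unit,
                ev$twist_deg[["CAD"]], ev$twist_deg[["NTD"]],
                ev$twist_deg[["THREE_HELIX_BUNDLE"]]))
  invisible(x)
}

#' Signed per-domain rotation of a catalytic event
#'
#' The twist of the event's domain transform about the hexamer axis,
#' clockwise-positive as seen from the stated viewpoint.
#'
#' @param event a `catalytic_event` from [map_catalytic_events()].
#' @param domain `"CAD"`, `"NTD"`, `"THREE_HELIX_BUNDLE"` (alias `"3HB"`)
#'   or `"CAD_adjacent"`.
#' @param axis optional `symmetry_axis` overriding the event's stored axis.
#' @param viewpoint see [rotation_about_axis()]; defaults to the event's.
#' @return signed angle in degrees.
#' @export
event_rotation <- function(event, domain, axis = NULL, viewpoint = NULL) {
  if (identical(domain, "3HB")) domain <- "THREE_HELIX_BUNDLE"
  tr <- event$transforms[[domain]]
  if (is.null(tr)) stopf("domain %s is unresolved in this event", domain)
  rotation_about_axis(tr, (axis %||% event$axis)$direction,
                      viewpoint %||% event$viewpoint)
}

#' Anchor displacement table of a catalytic event
#'
#' Calpha displacements of the anchor residues (D116, C196, G284, E331)
#' after the event's whole-hexamer alignment; anchors missing in either
#' state are `NA`.
#'
#' @param event a `catalytic_event`.
#' @return named numeric vector (Angstrom).
#' @export
event_displacements <- function(event) event$displacement

#' Pore-loop heights and pore geometry of a hexamer
#'
#' All quantities are measured in the axis frame: heights are coordinates
#' along the hexamer axis relative to the plane of the six Walker A
#' centroids, so only height differences are meaningful.  The extended
#' pore loop is referenced either by its anchor residue (E331 by default)
#' or by the interval centroid.
#'
#' @param model a `structure_model` hexamer.
#' @param scheme a `domain_scheme`.
#' @param loop_reference `"anchor"` or `"centroid"`.
#' @param axis optional precomputed `symmetry_axis`.
#' @param thresholds see [default_thresholds()].
#' @return object of class `pore_metrics`: per-chain loop heights (A),
#'   the height span within the asymmetric unit (max minus min over three
#'   cyclically consecutive chains), D116 Calpha distances between
#'   adjacent 3HBs, and a pore diameter estimate (twice the mean radial
#'   D116 distance from the axis).
#' @export
pore_metrics <- function(model, scheme, loop_reference = c("anchor", "centroid"),
                         axis = NULL, thresholds = default_thresholds()) {
  loop_reference <- match.arg(loop_reference)
  if (is.null(axis)) axis <- .hexamer_axis(model, thresholds)
  dirn <- unitv(axis$direction)
  chains <- .cyclic_chain_order(model, axis)
  wa_z <- vapply(chains, function(cc)
    sum(.motif_centroid(model, cc, scheme, "WALKER_A") * dirn), numeric(1))
  z0 <- mean(wa_z)
  ref_pos <- function(cc) {
    if (loop_reference == "anchor") .ca_of(model, cc, scheme$anchors[["E331"]])
    else {
      iv <- scheme$motifs$EXTENDED_PORE_LOOP
      colMeans(.ca_range(model, cc, iv[1], iv[2]))
    }
  }
  heights <- vapply(chains, function(cc) sum(ref_pos(cc) * dirn) - z0, numeric(1))
  span_asym <- max(heights[1:3]) - min(heights[1:3])
  d116 <- scheme$anchors[["D116"]]
  d116_pos <- lapply(chains, function(cc) .ca_of(model, cc, d116))
  hb_dist <- vapply(seq_len(6), function(i)
    vnorm(d116_pos[[i]] - d116_pos[[i %% 6 + 1]]), numeric(1))
  names(hb_dist) <- paste0(chains, "-", chains[c(2:6, 1)])
  radial <- vapply(d116_pos, function(p) {
    rel <- p - axis$point
    vnorm(rel - sum(rel * dirn) * dirn)
  }, numeric(1))
  structure(list(chains = chains, loop_heights = heights,
                 height_span_asym = span_asym,
                 d116_adjacent = hb_dist,
                 pore_diameter = 2 * mean(radial),
                 loop_reference = loop_reference, axis = axis),
            class = "pore_metrics")
}

#' @export
print.pore_metrics <- function(x, ...) {
  cat("<pore_metrics>\n  loop heights (A):",
      paste(sprintf("%s %.1f", x$chains, x$loop_heights), collapse = "  "), "\n")
  cat(sprintf("  height span (asymmetric unit): %.1f A\n", x$height_span_asym))
  cat(sprintf("  pore diameter estimate: %.1f A\n", x$pore_diameter))
  invisible(x)
}

#' Closed-state transition hypothesis
#'
#' A descriptive record pairing the ATP*-labelled chains of a closed
#' hexamer with the additional ATP-binding events (at their
#' clockwise-adjacent APO chains) that would carry the hexamer into the
#' compact state and prime the catalytic cycle.
#'
#' @param states a chain-state table from [label_chain_states()] for a
#'   closed-state hexamer.
#' @param units the matching `packing_units` object (supplies the cyclic
#'   chain order).
#' @return data frame with the hypothesised binding sites.
#' @export
closed_transition_hypothesis <- function(states, units) {
  ord <- attr(units, "chain_order")
  lab <- states$label[match(ord, states$chain)]
  star <- which(lab == "ATP_STAR")
  if (!length(star))
    return(data.frame(atp_star_chain = character(),
                      binding_chain = character(), note = character()))
  # the clockwise neighbour is the previous chain in counterclockwise order
  cwn <- ((star - 2) %% 6) + 1
  data.frame(atp_star_chain = ord[star], binding_chain = ord[cwn],
             binding_label = lab[cwn],
             note = "hypothesised ATP binding here would trigger binding + hydrolysis into the compact state",
             stringsAsFactors = FALSE)
}
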