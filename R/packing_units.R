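# Packing-unit construction: one full chain plus the CAD of the adjacent
# chain, whose interface forms a single nucleotide pocket.  Adjacency (which
# neighbour donates its CAD) is resolved geometrically: the donor is the
# neighbour whose R347 Calpha lies closest to the owner's Walker A centroid.

.hexamer_axis <- function(model, thresholds = default_thresholds()) {
  ax <- tryCatch(suppressWarnings(find_symmetry_axis(
    model, 2, residual_ceiling = thresholds$axis_residual_ceiling)),
    error = function(e) NULL)
  if (!is.null(ax) && !ax$flagged) return(ax)
  # fall back to the plane normal of the Calpha cloud (smallest-variance
  # principal direction) for asymmetric assemblies
  ca <- do.call(rbind, lapply(chain_ids(model), function(cc)
    .ca_range(model, cc, -Inf, Inf)))
  ev <- eigen(stats::cov(ca), symmetric = TRUE)
  dirn <- ev$vectors[, 3]
  if (dirn[3] < 0) dirn <- -dirn
  structure(list(order = NA_integer_, direction = unitv(dirn),
                 point = colMeans(ca), angle_deg = NA_real_,
                 residual_rmsd = if (is.null(ax)) NA_real_ else ax$residual_rmsd,
                 flagged = TRUE, n_ca = nrow(ca)),
            class = "symmetry_axis")
}

# chains ordered counterclockwise in the top view (seen from +axis)
.cyclic_chain_order <- function(model, axis) {
  dirn <- unitv(axis$direction)
  u <- if (abs(dirn[1]) < 0.9) unitv(pracma_cross(dirn, c(1, 0, 0))) else
    unitv(pracma_cross(dirn, c(0, 1, 0)))
  v <- pracma_cross(dirn, u)
  ang <- vapply(chain_ids(model), function(cc) {
    cen <- colMeans(.ca_range(model, cc, -Inf, Inf)) - axis$point
    atan2(sum(cen * v), sum(cen * u))
  }, numeric(1))
  names(sort(ang))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.state_abbrev <- c(closed = "Clo", compact = "Com", expanded = "Exp", other = "Oth")
.nuc_abbrev <- c(ATP = "ATP", ADP = "ADP", APO = "Apo", ATP_STAR = "ATP*")

# infer the hexamer conformation from its chain-state composition
.infer_conformation <- function(labels) {
  tab <- table(factor(labels, levels = c("ATP", "ADP", "APO", "ATP_STAR")))
  if (tab[["ATP_STAR"]] == 2 && tab[["APO"]] == 4) "closed"
  else if (tab[["ATP"]] == 2 && tab[["ADP"]] == 2 && tab[["APO"]] == 2) "compact"
  else if (tab[["ATP"]] == 2 && tab[["ADP"]] == 4) "expanded"
  else "other"
}

#' Build the six packing units of a hexamer
#'
#' Unit i comprises full chain i (3HB+NTD+CAD) and the CAD of the
#' cyclically previous chain, the one whose alpha9/R347 faces chain i's
#' Walker A pocket.  Units are named `{Clo|Com|Exp|Oth}-{ATP|ADP|Apo|ATP*}`
#' with numeric suffixes when a nucleotide label repeats within the
#' asymmetric unit, and a trailing `'` on the second symmetry copy so names
#' stay unique within the hexamer.
#'
#' @param model a `structure_model` with exactly six protein chains.
#' @param scheme a `domain_scheme`.
#' @param chain_order optional cyclic chain ordering (counterclockwise in
#'   the top view); derived from the geometry when `NULL` and validated
#'   against it otherwise.
#' @param states optional chain-state table from [label_chain_states()]
#'   (computed without a reference model when omitted).
#' @param conformation hexamer conformation (`"closed"`, `"compact"`,
#'   `"expanded"`, `"other"` or `"auto"` to infer from the state
#'   composition).
#' @param thresholds see [default_thresholds()].
#' @return object of class `packing_units`: a data frame with one row per
#'   unit (`unit`, `name`, `conformation`, `owner_chain`, `adjacent_chain`,
#'   `nucleotide_label`, `asym_index`), with the axis and cyclic order as
#'   attributes.
#' @export
build_packing_units <- function(model, scheme, chain_order = NULL,
                                states = NULL, conformation = "auto",
                                thresholds = default_thresholds()) {
  chains <- chain_ids(model)
  if (length(chains) != 6)
    stopf("packing units need a hexamer; model has %d chains", length(chains))
  axis <- .hexamer_axis(model, thresholds)
  geo_order <- .cyclic_chain_order(model, axis)
  if (is.null(chain_order)) chain_order <- geo_order
  else {
    ok <- any(vapply(seq_len(6), function(k)
      identical(unname(geo_order), unname(chain_order[((seq_len(6) + k - 2) %% 6) + 1])),
      logical(1)))
    if (!ok)
      stopf("adjacency error: supplied chain order (%s) contradicts the geometric cyclic order (%s)",
            paste(chain_order, collapse = ","), paste(geo_order, collapse = ","))
  }
  if (is.null(states)) states <- label_chain_states(model, scheme, thresholds = thresholds)
  lab <- states$label[match(chain_order, states$chain)]

  # geometric adjacency: donor of unit i is the neighbour whose R347 is
  # nearest chain i's Walker A centroid
  r347 <- scheme$anchors[["R347"]]
  donor_dir <- vapply(seq_len(6), function(i) {
    owner <- chain_order[i]
    wa <- .motif_centroid(model, owner, scheme, "WALKER_A")
    prv <- chain_order[(i - 2) %% 6 + 1]
    nxt <- chain_order[i %% 6 + 1]
    dp <- vnorm(.ca_of(model, prv, r347) - wa)
    dn <- vnorm(.ca_of(model, nxt, r347) - wa)
    if (dp <= dn) -1L else 1L
  }, integer(1))
  # majority vote across chains: in open (APO) pockets the facing R347 has
  # swung away, so a minority of per-chain votes can point the wrong way
  if (sum(donor_dir) == 0)
    stopf("adjacency error: CAD donor direction is tied across chains (%s)",
          paste(donor_dir, collapse = ","))
  dd <- if (sum(donor_dir) < 0) -1L else 1L
  adjacent <- chain_order[((seq_len(6) - 1 + dd) %% 6) + 1]

  conf <- if (identical(conformation, "auto")) .infer_conformation(lab) else conformation
  if (identical(conformation, "auto") && nzchar(model$label) &&
      tolower(model$label) %in% names(.state_abbrev))
    conf <- tolower(model$label)

  # asymmetric unit starts at the first ATP (else ATP*, else first chain)
  start <- match("ATP", lab)
  if (is.na(start)) start <- match("ATP_STAR", lab)
  if (is.na(start)) start <- 1L
  pos <- ((seq_len(6) - start) %% 6) + 1    # 1..6 from the asym start
  asym_index <- ((pos - 1) %% 3) + 1
  base <- paste0(.state_abbrev[[conf]], "-", .nuc_abbrev[lab])
  # number repeated labels within the asymmetric unit by cyclic position,
  # then copy the numbering to the symmetric twin (same asym_index)
  name <- base
  for (l in unique(lab)) {
    in_asym <- which(lab == l & pos <= 3)
    if (length(in_asym) > 1) {
      in_asym <- in_asym[order(pos[in_asym])]
      for (k in seq_along(in_asym)) {
        twin <- which(lab == l & asym_index == asym_index[in_asym[k]])
        name[twin] <- paste0(base[twin], k)
      }
    }
  }
  name[pos > 3] <- paste0(name[pos > 3], "'")

  units <- data.frame(unit = seq_len(6), name = name, conformation = conf,
                      owner_chain = chain_order, adjacent_chain = adjacent,
                      nucleotide_label = lab, asym_index = asym_index,
                      stringsAsFactors = FALSE)
  structure(units, class = c("packing_units", "data.frame"),
            axis = axis, chain_order = chain_order, donor_direction = dd,
            model_label = model$label)
}

#' Per-unit geometric metrics
#'
#' The R347-G284 Calpha distance across the alpha9/Walker-A interface, the
#' arginine-finger state report, and whether R347 of the adjacent CAD
#' coordinates the bound nucleotide (true only for engaged ATP pockets).
#' For C2-symmetric hexamers a symmetry-consistency check compares units i
#' and i+3.
#'
#' @param units a `packing_units` object.
#' @param model the `structure_model` the units were built from.
#' @param scheme a `domain_scheme`.
#' @param thresholds see [default_thresholds()].
#' @return object of class `packing_unit_metrics`: data frame with one row
#'   per unit (`name`, `nucleotide_label`, `r347_g284`, `r347_state`,
#'   `r217_state`, `r223_state`, `coordinated`), with the full arginine
#'   reports and the symmetry check as attributes.
#' @export
packing_unit_metrics <- function(units, model, scheme,
                                 thresholds = default_thresholds()) {
  axis <- attr(units, "axis")
  reports <- lapply(seq_len(nrow(units)), function(i)
    classify_arginine_states(units[i, ], model, scheme, axis, thresholds))
  rows <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    st <- function(res) r$states$state[r$states$residue == res]
    data.frame(unit = units$unit[i], name = units$name[i],
               nucleotide_label = units$nucleotide_label[i],
               r347_g284 = r$r347_g284_distance,
               r347_state = st("R347"), r217_state = st("R217"),
               r223_state = st("R223"),
               coordinated = identical(st("R347"), "engaged"),
               stringsAsFactors = FALSE)
  }))
  sym <- NULL
  if (!is.null(axis$order) && identical(axis$order, 2L)) {
    sym <- do.call(rbind, lapply(1:3, function(i) {
      data.frame(pair = sprintf("%s/%s", rows$name[i], rows$name[i + 3]),
                 delta_distance = abs(rows$r347_g284[i] - rows$r347_g284[i + 3]),
                 consistent = abs(rows$r347_g284[i] - rows$r347_g284[i + 3]) <=
                   thresholds$symmetry_tol_dist &&
                   rows$r347_state[i] == rows$r347_state[i + 3])
    }))
  }
  structure(rows, class = c("packing_unit_metrics", "data.frame"),
            reports = reports, symmetry_check = sym)
}

#' @export
print.packing_units <- function(x, ...) {
  cat(sprintf("<packing_units> %s hexamer (%s)\n", x$conformation[1],
              attr(x, "model_label")))
  print.data.frame(x)
  invisible(x)
}

#' @export
print.packing_unit_metrics <- function(x, ...) {
  cat("<packing_unit_metrics>\n")
  print.data.frame(cbind(x[, c("name", "nucleotide_label")],
                         r347_g284 = round(x$r347_g284, 2),
                         x[, c("r347_state", "coordinated")]))
  sym <- attr(x, "symmetry_check")
  if (!is.null(sym) && all(sym$consistent))
    cat("  C2 symmetry consistency: ok\n")
  else if (!is.null(sym))
    cat("  C2 symmetry consistency: FAILED for",
        paste(sym$pair[!sym$consistent], collapse = ", "), "\n")
  invisible(x)
}
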