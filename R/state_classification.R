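# Nucleotide assignment, conformational clustering and arginine-finger
# state classification.
#
# The active-site pocket of chain i sits between its own Walker A motif and
# the alpha9 helix (R347) of the adjacent chain's CAD.  A nucleotide is
# assigned to the chain whose Walker A Calpha centroid is nearest its
# phosphate centroid.  Chains are grouped into conformers by all-vs-all
# Calpha superposition and single-linkage clustering; a chain in the
# ATP-bound conformer group without an assignable nucleotide is the ATP*
# state.

#' Default classification thresholds
#'
#' @param contact_cutoff maximum phosphate-centroid to Walker-A-centroid
#'   distance (A) for nucleotide assignment.
#' @param hbond_cutoff maximum guanidinium-N to phosphate-O distance (A) for
#'   an engaged arginine finger.
#' @param d_engaged maximum R347-G284 Calpha distance (A) compatible with an
#'   engaged alpha9/Walker-A interface (midpoint between the ~8 A engaged
#'   and ~15 A disengaged regimes).
#' @param linkage_cutoff single-linkage height (A RMSD) separating
#'   conformer groups.
#' @param ambiguity_margin two pockets closer than this (A) to one ligand
#'   trigger an ambiguity error.
#' @param axis_residual_ceiling warn threshold for symmetry-axis fits (A).
#' @param symmetry_tol_dist,symmetry_tol_angle tolerances (A, degrees) for
#'   the C2 symmetry-consistency check on packing-unit metrics.
#' @param min_shared_residues minimum shared Calpha count for a pairwise
#'   chain superposition.
#' @export
default_thresholds <- function(contact_cutoff = 10, hbond_cutoff = 3.5,
                               d_engaged = 10, linkage_cutoff = 2,
                               ambiguity_margin = 0.5,
                               axis_residual_ceiling = 3,
                               symmetry_tol_dist = 0.5,
                               symmetry_tol_angle = 2,
                               min_shared_residues = 20) {
  list(contact_cutoff = contact_cutoff, hbond_cutoff = hbond_cutoff,
       d_engaged = d_engaged, linkage_cutoff = linkage_cutoff,
       ambiguity_margin = ambiguity_margin,
       axis_residual_ceiling = axis_residual_ceiling,
       symmetry_tol_dist = symmetry_tol_dist,
       symmetry_tol_angle = symmetry_tol_angle,
       min_shared_residues = min_shared_residues)
}

.phosphate_centroid <- function(lig_atoms) {
  p <- lig_atoms[lig_atoms$element == "P", , drop = FALSE]
  if (!nrow(p)) p <- lig_atoms
  colMeans(as.matrix(p[, c("x", "y", "z")]))
}

#' Assign active-site nucleotides to chains
#'
#' Each ATP/ADP ligand is assigned to the chain whose Walker A Calpha
#' centroid is nearest its phosphate centroid (and within
#' `contact_cutoff`); chains without a nucleotide are APO.  Mg ions attach
#' to the pocket of their nearest nucleotide and never define a state on
#' their own.  Non-nucleotide ligands are reported but leave the chain APO.
#'
#' @param model a `structure_model`.
#' @param scheme a `domain_scheme` with a `WALKER_A` motif.
#' @param thresholds see [default_thresholds()].
#' @return data frame, one row per chain: `chain`, `nucleotide`
#'   (`ATP`/`ADP`/`APO`), `magnesium`, `analog`, `pocket_contact_count`,
#'   `min_contact_distance`.
#' @export
assign_nucleotides <- function(model, scheme, thresholds = default_thresholds()) {
  chains <- chain_ids(model)
  wa <- lapply(chains, function(cc) .motif_centroid(model, cc, scheme, "WALKER_A"))
  names(wa) <- chains
  out <- data.frame(chain = chains, nucleotide = "APO", magnesium = FALSE,
                    analog = FALSE, pocket_contact_count = 0L,
                    min_contact_distance = NA_real_,
                    stringsAsFactors = FALSE)
  lt <- ligand_table(model)
  nucs <- lt[lt$ligand %in% c("ATP", "ADP"), , drop = FALSE]
  nuc_pocket <- character(0)
  for (i in seq_len(nrow(nucs))) {
    la <- ligand_atoms(model, nucs$chain[i], nucs$resno[i])
    pc <- .phosphate_centroid(la)
    d <- vapply(wa, function(w) vnorm(w - pc), numeric(1))
    ds <- sort(d)
    if (length(ds) > 1 && ds[2] - ds[1] < thresholds$ambiguity_margin)
      stopf("ambiguous pocket for %s ligand (chains %s at %.2f / %.2f A)",
            nucs$ligand[i], paste(names(d)[order(d)][1:2], collapse = ", "),
            ds[1], ds[2])
    if (ds[1] > thresholds$contact_cutoff) {
      warnf("orphan %s ligand: %.1f A from the nearest Walker A pocket",
            nucs$ligand[i], ds[1])
      next
    }
    cc <- names(which.min(d))
    row <- match(cc, out$chain)
    if (out$nucleotide[row] != "APO")
      warnf("chain %s pocket already holds %s; extra %s ignored",
            cc, out$nucleotide[row], nucs$ligand[i])
    else {
      out$nucleotide[row] <- nucs$ligand[i]
      out$analog[row] <- nucs$analog[i]
      xyz <- as.matrix(la[, c("x", "y", "z")])
      dd <- sqrt(colSums((t(xyz) - wa[[cc]])^2))
      out$pocket_contact_count[row] <- sum(dd <= thresholds$contact_cutoff)
      out$min_contact_distance[row] <- min(dd)
      nuc_pocket[paste(nucs$chain[i], nucs$resno[i])] <- cc
    }
  }
  mgs <- lt[lt$ligand == "MG", , drop = FALSE]
  for (i in seq_len(nrow(mgs))) {
    la <- ligand_atoms(model, mgs$chain[i], mgs$resno[i])
    mgpos <- colMeans(as.matrix(la[, c("x", "y", "z")]))
    # nearest assigned nucleotide's pocket
    best <- NULL; bestd <- Inf
    for (k in seq_len(nrow(nucs))) {
      cc <- nuc_pocket[paste(nucs$chain[k], nucs$resno[k])]
      if (is.na(cc)) next
      na <- ligand_atoms(model, nucs$chain[k], nucs$resno[k])
      d <- vnorm(.phosphate_centroid(na) - mgpos)
      if (d < bestd) { bestd <- d; best <- cc }
    }
    if (!is.null(best)) out$magnesium[match(best, out$chain)] <- TRUE
  }
  out
}

# domain-restricted shared-Calpha matrix pair for two chain records
.shared_ca <- function(rec_a, rec_b) {
  shared <- intersect(rownames(rec_a), rownames(rec_b))
  list(a = rec_a[shared, , drop = FALSE], b = rec_b[shared, , drop = FALSE])
}

# Calpha matrix of one chain restricted to folded domains (3HB+NTD+CAD)
.folded_ca <- function(model, chain, scheme) {
  keep <- setdiff(names(scheme$domains), "IDR")
  m <- do.call(rbind, lapply(keep, function(nm) {
    d <- scheme$domains[[nm]]
    .ca_range(model, chain, d[1], d[2])
  }))
  m[order(as.integer(rownames(m))), , drop = FALSE]
}

#' Cluster chains into conformational groups
#'
#' All-vs-all least-squares superposition of folded-domain Calpha atoms
#' gives a pairwise RMSD matrix; single-linkage clustering at
#' `linkage_cutoff` defines the groups.  Each group is labelled by the
#' majority nucleotide of its members (`ATP_CONF`/`ADP_CONF`/`APO_CONF`);
#' an APO-majority group that contains at least one ATP-bound chain is
#' promoted to `ATP_CONF`, which is what makes ATP* chains detectable.
#'
#' @param models a `structure_model` or list of them (the paper-style
#'   18-chain analysis passes all three hexamers at once).
#' @param scheme a `domain_scheme`.
#' @param thresholds see [default_thresholds()].
#' @return object of class `conformation_groups`: list with `membership`
#'   (data frame `model`, `chain`, `nucleotide`, `group`, `group_label`),
#'   `groups` (per-group label and mean intra-group RMSD) and `rmsd`
#'   (the full matrix).
#' @export
cluster_chain_conformations <- function(models, scheme,
                                        thresholds = default_thresholds()) {
  if (inherits(models, "structure_model")) models <- list(models)
  labs <- vapply(seq_along(models), function(i) {
    l <- models[[i]]$label
    if (nzchar(l)) l else paste0("model", i)
  }, character(1))
  if (anyDuplicated(labs)) stopf("model labels must be unique: %s",
                                 paste(labs, collapse = ", "))
  entries <- do.call(rbind, lapply(seq_along(models), function(i) {
    nuc <- assign_nucleotides(models[[i]], scheme, thresholds)
    data.frame(model = labs[i], chain = nuc$chain, nucleotide = nuc$nucleotide,
               stringsAsFactors = FALSE)
  }))
  n <- nrow(entries)
  if (n < 2) stopf("need at least 2 chains to cluster, got %d", n)
  cas <- lapply(seq_len(n), function(i) {
    m <- models[[match(entries$model[i], labs)]]
    .folded_ca(m, entries$chain[i], scheme)
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sh <- .shared_ca(cas[[i]], cas[[j]])
    if (nrow(sh$a) < thresholds$min_shared_residues) {
      warnf("chain pair %s:%s / %s:%s shares only %d residues; pair excluded",
            entries$model[i], entries$chain[i], entries$model[j],
            entries$chain[j], nrow(sh$a))
      D[i, j] <- D[j, i] <- Inf
    } else D[i, j] <- D[j, i] <- superpose(sh$a, sh$b)$rmsd
  }
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  grp <- stats::cutree(hc, h = thresholds$linkage_cutoff)
  entries$group <- grp
  glab <- vapply(sort(unique(grp)), function(g) {
    nucs <- entries$nucleotide[grp == g]
    tab <- sort(table(nucs), decreasing = TRUE)
    major <- names(tab)[1]
    if (major == "APO" && any(nucs == "ATP")) major <- "ATP"
    if (length(tab) > 1 && sum(tab == max(tab)) > 1 && major == "APO")
      return("unresolved")
    paste0(major, "_CONF")
  }, character(1))
  entries$group_label <- glab[entries$group]
  groups <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    idx <- which(grp == g)
    pr <- if (length(idx) > 1) D[idx, idx][upper.tri(diag(length(idx)))] else 0
    data.frame(group = g, group_label = glab[g], n = length(idx),
               mean_rmsd = mean(pr[is.finite(pr)]))
  }))
  structure(list(membership = entries, groups = groups, rmsd = D),
            class = "conformation_groups")
}

#' @export
print.conformation_groups <- function(x, ...) {
  cat("<conformation_groups>\n")
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    mem <- x$membership[x$membership$group == g$group, ]
    cat(sprintf("  %-10s n=%d  mean intra RMSD %.2f A  [%s]\n",
                g$group_label, g$n, g$mean_rmsd,
                paste(paste0(mem$model, ":", mem$chain), collapse = " ")))
  }
  invisible(x)
}

#' Compose nucleotide occupancy and conformation into chain state labels
#'
#' Final labels are `ATP`, `ADP`, `APO` or `ATP_STAR`.  `ATP_STAR` is an
#' APO pocket on a chain whose conformer group is ATP-bound; detecting it
#' therefore requires at least one genuinely ATP-bound chain in the joint
#' clustering, which is why `reference` models (e.g. a nucleotide-soaked
#' hexamer) can be supplied alongside the model of interest.
#'
#' @param model the `structure_model` to label.
#' @param scheme a `domain_scheme`.
#' @param reference optional `structure_model` or list of models included
#'   in the clustering but not reported.
#' @param thresholds see [default_thresholds()].
#' @return data frame: `chain`, `nucleotide`, `magnesium`, `conformation`,
#'   `label`, `flag`.
#' @export
label_chain_states <- function(model, scheme, reference = NULL,
                               thresholds = default_thresholds()) {
  if (!nzchar(model$label)) model$label <- "model1"
  models <- list(model)
  if (!is.null(reference)) {
    if (inherits(reference, "structure_model")) reference <- list(reference)
    models <- c(models, reference)
  }
  cl <- cluster_chain_conformations(models, scheme, thresholds)
  nuc <- assign_nucleotides(model, scheme, thresholds)
  mem <- cl$membership[cl$membership$model == model$label, ]
  out <- merge(nuc, mem[, c("chain", "group_label")], by = "chain", sort = FALSE)
  out <- out[match(chain_ids(model), out$chain), ]
  out$conformation <- out$group_label
  out$label <- out$nucleotide
  out$flag <- ""
  star <- out$nucleotide == "APO" & out$conformation == "ATP_CONF"
  out$label[star] <- "ATP_STAR"
  unresolved <- out$conformation == "unresolved"
  out$flag[unresolved] <- "conformation unresolved; label from nucleotide only"
  out$flag[out$analog] <- trimws(paste(out$flag[out$analog],
                                       "ATP analogue normalised to ATP"))
  rownames(out) <- NULL
  out[, c("chain", "nucleotide", "magnesium", "conformation", "label", "flag")]
}

# inward radial unit vector at point p relative to an axis
.inward_radial <- function(p, axis) {
  dirn <- unitv(axis$direction)
  rel <- p - axis$point
  radial <- rel - sum(rel * dirn) * dirn
  -unitv(radial)
}

.sidechain_atom <- function(model, chain, resno, elety) {
  at <- chain_atoms(model, chain)
  row <- at[at$resno == resno & at$elety == elety, , drop = FALSE]
  if (!nrow(row)) return(NULL)
  as.numeric(row[1, c("x", "y", "z")])
}

# minimum guanidinium-N to phosphate-O distance for one arginine vs one ligand
.min_no_dist <- function(model, chain, resno, lig, gamma_only = FALSE) {
  ns <- lapply(c("NH1", "NH2", "NE"), function(a) .sidechain_atom(model, chain, resno, a))
  ns <- ns[!vapply(ns, is.null, logical(1))]
  if (!length(ns) || is.null(lig)) return(NA_real_)
  os <- lig[lig$element == "O", , drop = FALSE]
  if (gamma_only) {
    g <- os[grepl("G$", os$elety), , drop = FALSE]
    if (nrow(g)) os <- g
  }
  if (!nrow(os)) return(NA_real_)
  oxyz <- as.matrix(os[, c("x", "y", "z")])
  min(vapply(ns, function(p) min(sqrt(colSums((t(oxyz) - p)^2))), numeric(1)))
}

#' Classify the arginine-finger states of one packing unit
#'
#' R347 (alpha9 of the adjacent CAD) and R217/R223 (NTD of the owner chain)
#' are classified as `engaged`, `disengaged` or `intermediate` from their
#' side-chain orientation and active-site geometry:
#' \itemize{
#'   \item R347 engaged: the pocket holds ATP, a guanidinium nitrogen lies
#'     within `hbond_cutoff` of a gamma-phosphate oxygen, the R347-G284
#'     Calpha distance is at most `d_engaged`, and the CA-to-CZ direction
#'     points at the pocket;
#'   \item R347 intermediate: not engaged and CA-to-CZ makes less than 90
#'     degrees with the inward radial direction toward the hexamer pore;
#'   \item R347 disengaged: otherwise (CA-to-CZ away from the pocket and
#'     the alpha9/Walker-A interface open beyond `d_engaged`);
#'   \item R217/R223 engaged: nucleotide present and CA-to-CZ toward the
#'     pocket centroid; intermediate: toward the (empty) pocket;
#'     disengaged: away from the pocket.
#' }
#' Residues without side-chain atoms are `unresolved`.
#'
#' @param unit one row of a [build_packing_units()] table (or a list with
#'   `owner_chain` and `adjacent_chain`).
#' @param model the `structure_model` holding the unit.
#' @param scheme a `domain_scheme`.
#' @param axis a `symmetry_axis` defining the pore direction (computed from
#'   the model when `NULL`).
#' @param thresholds see [default_thresholds()].
#' @return object of class `arginine_report`: per-residue state and the
#'   supporting metrics (minimum N-O distance, angle to the pocket
#'   centroid, angle to the pore axis inward radial), plus the R347-G284
#'   Calpha distance.
#' @export
classify_arginine_states <- function(unit, model, scheme, axis = NULL,
                                     thresholds = default_thresholds()) {
  owner <- unit$owner_chain; adj <- unit$adjacent_chain
  anc <- scheme$anchors
  for (a in c("R347", "G284")) if (!a %in% names(anc))
    stopf("missing anchor %s in scheme", a)
  if (is.null(axis)) axis <- find_symmetry_axis(model, 2)
  nuc <- assign_nucleotides(model, scheme, thresholds)
  pocket_nuc <- nuc$nucleotide[nuc$chain == owner]
  wa_cent <- .motif_centroid(model, owner, scheme, "WALKER_A")
  lig <- NULL
  if (pocket_nuc != "APO") {
    lt <- ligand_table(model)
    lt <- lt[lt$ligand == pocket_nuc, , drop = FALSE]
    best <- which.min(vapply(seq_len(nrow(lt)), function(i)
      vnorm(.phosphate_centroid(ligand_atoms(model, lt$chain[i], lt$resno[i])) - wa_cent),
      numeric(1)))
    lig <- ligand_atoms(model, lt$chain[best], lt$resno[best])
  }
  pocket_centroid <- if (!is.null(lig)) .phosphate_centroid(lig) else wa_cent
  d_r347_g284 <- ca_distance(model, adj, anc[["R347"]], owner, anc[["G284"]])

  classify_one <- function(chain, resno, is_r347) {
    ca <- tryCatch(.ca_of(model, chain, resno), error = function(e) NULL)
    if (is.null(ca)) stopf("missing anchor residue %d in chain %s", resno, chain)
    cz <- .sidechain_atom(model, chain, resno, "CZ")
    if (is.null(cz))
      return(data.frame(residue = NA, state = "unresolved", min_no_dist = NA,
                        pocket_angle = NA, pore_angle = NA))
    dirn <- cz - ca
    pocket_angle <- vec_angle(dirn, pocket_centroid - ca)
    pore_angle <- vec_angle(dirn, .inward_radial(ca, axis))
    minno <- .min_no_dist(model, chain, resno, lig, gamma_only = is_r347)
    state <- if (is_r347) {
      if (pocket_nuc == "ATP" && !is.na(minno) && minno <= thresholds$hbond_cutoff &&
          d_r347_g284 <= thresholds$d_engaged && pocket_angle < 90) "engaged"
      else if (pore_angle < 90) "intermediate"
      else "disengaged"
    } else {
      if (pocket_nuc != "APO" && pocket_angle < 90) "engaged"
      else if (pocket_angle < 90) "intermediate"
      else "disengaged"
    }
    data.frame(residue = NA, state = state, min_no_dist = minno,
               pocket_angle = pocket_angle, pore_angle = pore_angle)
  }
  rows <- rbind(
    cbind(residue = "R217", classify_one(owner, anc[["R217"]], FALSE)[-1]),
    cbind(residue = "R223", classify_one(owner, anc[["R223"]], FALSE)[-1]),
    cbind(residue = "R347", classify_one(adj, anc[["R347"]], TRUE)[-1]))
  rownames(rows) <- NULL
  structure(list(states = rows, r347_g284_distance = d_r347_g284,
                 pocket_nucleotide = pocket_nuc,
                 owner_chain = owner, adjacent_chain = adj),
            class = "arginine_report")
}

#' @export
print.arginine_report <- function(x, ...) {
  cat(sprintf("<arginine_report> pocket of chain %s (%s), alpha9 from chain %s\n",
              x$owner_chain, x$pocket_nucleotide, x$adjacent_chain))
  cat(sprintf("  R347-G284 Calpha distance: %.2f A\n", x$r347_g284_distance))
  for (i in seq_len(nrow(x$states)))
    cat(sprintf("  %-5s %-12s (N-O %.5s A, pocket %.5s deg, pore %.5s deg)\n",
                x$states$residue[i], x$states$state[i],
                format(x$states$min_no_dist[i], digits = 3),
                format(x$states$pocket_angle[i], digits = 3),
                format(x$states$pore_angle[i], digits = 3)))
  invisible(x)
}
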