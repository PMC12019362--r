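# Domain architecture of a PilT/VirB11-like motor chain and the residue
# anchors used by every downstream measurement.  The built-in profile
# describes Caulobacter crescentus CpaF: a 79-residue intrinsically
# disordered region (IDR, never resolved), a three-helix bundle (3HB,
# 80-146) lining the hexamer pore, an N-terminal domain (NTD) and a
# C-terminal ATPase domain (CAD) joined by a flexible linker.  The NTD/CAD
# split residue is not a measured quantity; it defaults to 270 (past loop 8,
# before the Walker A motif) and no anchor-based measurement depends on it.

.CPAF_ANCHORS <- c(D116 = 116, C196 = 196, N189 = 189, V200 = 200,
                   S201 = 201, P212 = 212, D215 = 215, R217 = 217,
                   R223 = 223, G284 = 284, K287 = 287, T288 = 288,
                   E312 = 312, T325 = 325, E331 = 331, G334 = 334,
                   T337 = 337, R347 = 347, E357 = 357)

#' The default CpaF domain scheme
#'
#' @param nc_split last residue of the NTD (default 270); the CAD starts at
#'   `nc_split + 1`.
#' @return a `domain_scheme` object.
#' @export
default_scheme <- function(nc_split = 270L) {
  domain_scheme(
    domains = list(IDR = c(1L, 79L), THREE_HELIX_BUNDLE = c(80L, 146L),
                   NTD = c(147L, nc_split), CAD = c(nc_split + 1L, 501L)),
    motifs = list(ALPHA5 = c(189L, 200L), LOOP8 = c(201L, 212L),
                  WALKER_A = c(284L, 289L), EXTENDED_PORE_LOOP = c(325L, 337L),
                  ALPHA9 = c(343L, 355L)),
    anchors = .CPAF_ANCHORS,
    nc_split = as.integer(nc_split))
}

#' Construct and validate a domain scheme
#'
#' @param domains named list of length-2 integer vectors (inclusive residue
#'   intervals, author numbering), ordered and non-overlapping.
#' @param motifs named list of intervals for secondary-structure motifs.
#' @param anchors named integer vector of single anchor residues; each must
#'   fall inside exactly one domain.
#' @param nc_split NTD/CAD boundary residue.
#' @export
domain_scheme <- function(domains, motifs = list(), anchors = integer(),
                          nc_split = NA_integer_) {
  iv <- function(v, nm) {
    if (length(v) != 2 || any(is.na(v)) || v[1] > v[2])
      stopf("interval '%s' must be start <= end, got [%s]", nm,
            paste(v, collapse = ", "))
    as.integer(v)
  }
  domains <- Map(iv, domains, names(domains))
  motifs <- Map(iv, motifs, names(motifs))
  m <- do.call(rbind, domains)
  ord <- order(m[, 1])
  if (any(m[ord, , drop = FALSE][-1, 1] <= m[ord, 2][-nrow(m)]))
    stopf("domain intervals overlap")
  for (nm in names(anchors)) {
    inside <- vapply(domains, function(d) anchors[[nm]] >= d[1] && anchors[[nm]] <= d[2], logical(1))
    if (sum(inside) != 1)
      stopf("anchor %s (residue %d) lies inside %d domains; expected exactly 1",
            nm, anchors[[nm]], sum(inside))
  }
  structure(list(domains = domains, motifs = motifs,
                 anchors = vapply(anchors, as.integer, integer(1)),
                 nc_split = as.integer(nc_split)),
            class = "domain_scheme")
}

#' @export
print.domain_scheme <- function(x, ...) {
  cat("<domain_scheme>\n  domains:\n")
  for (nm in names(x$domains))
    cat(sprintf("    %-20s %d-%d\n", nm, x$domains[[nm]][1], x$domains[[nm]][2]))
  cat(sprintf("  motifs: %s\n", paste(names(x$motifs), collapse = ", ")))
  cat(sprintf("  anchors: %s\n", paste(names(x$anchors), collapse = " ")))
  invisible(x)
}

#' Load a domain scheme from a YAML config file
#'
#' The file supplies `domains:`, optionally `motifs:`, `anchors:` and
#' `nc_split:`; fields not given fall back to the built-in CpaF profile.
#' A top-level `profile: cpaf_default` with no other keys returns the
#' default scheme unchanged.
#'
#' @param path YAML file path, or `NULL` for the default profile.
#' @return a `domain_scheme`.
#' @export
load_scheme <- function(path = NULL) {
  if (is.null(path)) return(default_scheme())
  cfg <- yaml::read_yaml(path)
  base <- default_scheme(nc_split = cfg$nc_split %||% 270L)
  dom <- base$domains
  for (nm in names(cfg$domains)) dom[[nm]] <- as.integer(unlist(cfg$domains[[nm]]))
  mot <- base$motifs
  for (nm in names(cfg$motifs)) mot[[nm]] <- as.integer(unlist(cfg$motifs[[nm]]))
  anc <- base$anchors
  for (nm in names(cfg$anchors)) anc[[nm]] <- as.integer(cfg$anchors[[nm]])
  domain_scheme(dom, mot, anc, nc_split = cfg$nc_split %||% base$nc_split)
}

.domain_of <- function(scheme, resno) {
  out <- rep(NA_character_, length(resno))
  for (nm in names(scheme$domains)) {
    d <- scheme$domains[[nm]]
    out[resno >= d[1] & resno <= d[2]] <- nm
  }
  out
}

#' Annotate the residues of a model with domain labels
#'
#' Every modelled residue of every protein chain receives exactly one domain
#' label, or the out-of-range flag `"OUT_OF_RANGE"` when it falls outside all
#' scheme intervals.  Anchors missing from the model (e.g. the IDR, which is
#' never resolved) are listed per chain.
#'
#' @param model a `structure_model`.
#' @param scheme a `domain_scheme`.
#' @return named list (per chain) of `domain_annotation` objects with fields
#'   `labels` (named by residue number), `missing_anchors`, and `ca_by_domain`
#'   (list of Calpha coordinate matrices).
#' @export
annotate_domains <- function(model, scheme) {
  out <- lapply(chain_ids(model), function(cc) {
    at <- chain_atoms(model, cc)
    resnos <- sort(unique(at$resno))
    if (!length(resnos)) {
      warnf("chain %s has no residues inside any scheme interval", cc)
      return(structure(list(chain = cc, labels = character(),
                            missing_anchors = names(scheme$anchors),
                            ca_by_domain = list()),
                       class = "domain_annotation"))
    }
    labs <- .domain_of(scheme, resnos)
    if (all(is.na(labs))) {
      warnf("chain %s has no residues inside any scheme interval", cc)
      return(structure(list(chain = cc, labels = character(),
                            missing_anchors = names(scheme$anchors),
                            ca_by_domain = list()),
                       class = "domain_annotation"))
    }
    labs[is.na(labs)] <- "OUT_OF_RANGE"
    names(labs) <- resnos
    anc_present <- scheme$anchors %in% at$resno[at$elety == "CA"]
    ca <- at[at$elety == "CA", , drop = FALSE]
    if (any(ca$insert != "")) {
      bad <- intersect(scheme$anchors, ca$resno[ca$insert != ""])
      if (length(bad))
        stopf("insertion code at anchor residue(s) %s of chain %s",
              paste(bad, collapse = ", "), cc)
    }
    ca_by_domain <- lapply(names(scheme$domains), function(nm) {
      d <- scheme$domains[[nm]]
      sel <- ca$resno >= d[1] & ca$resno <= d[2]
      m <- as.matrix(ca[sel, c("x", "y", "z")])
      rownames(m) <- ca$resno[sel]
      m
    })
    names(ca_by_domain) <- names(scheme$domains)
    if (!all(labs %in% c(names(scheme$domains), "OUT_OF_RANGE")))
      stopf("internal: annotation produced a label outside the scheme")
    structure(list(chain = cc, labels = labs,
                   missing_anchors = names(scheme$anchors)[!anc_present],
                   ca_by_domain = ca_by_domain),
              class = "domain_annotation")
  })
  names(out) <- chain_ids(model)
  out
}

# Calpha coordinate of one residue; errors if absent
.ca_of <- function(model, chain, resno) {
  at <- chain_atoms(model, chain)
  row <- at[at$resno == resno & at$elety == "CA", , drop = FALSE]
  if (!nrow(row))
    stopf("missing Calpha atom for residue %d of chain %s", resno, chain)
  as.numeric(row[1, c("x", "y", "z")])
}

# Calpha matrix for a residue interval (rows named by residue number)
.ca_range <- function(model, chain, from, to) {
  at <- chain_atoms(model, chain)
  sel <- at$elety == "CA" & at$resno >= from & at$resno <= to
  m <- as.matrix(at[sel, c("x", "y", "z")])
  rownames(m) <- at$resno[sel]
  m
}

# Calpha centroid of a scheme motif
.motif_centroid <- function(model, chain, scheme, motif) {
  iv <- scheme$motifs[[motif]]
  if (is.null(iv)) stopf("scheme has no motif '%s'", motif)
  m <- .ca_range(model, chain, iv[1], iv[2])
  if (!nrow(m)) stopf("no Calpha atoms in motif %s of chain %s", motif, chain)
  colMeans(m)
}
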