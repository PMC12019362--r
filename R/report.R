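# Orchestration and report writing: single-hexamer analysis (states,
# packing units, pore metrics), two-state cycle analysis, and synthetic
# fixture emission, with TSV/JSON exports carrying units in the column
# names and a provenance block echoing every threshold used.

.pkg_version <- function() as.character(utils::packageVersion("hexcycle"))

.provenance <- function(inputs, thresholds, extra = list()) {
  sums <- vapply(inputs, function(p)
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_, character(1))
  c(list(package = "hexcycle", version = .pkg_version(),
         inputs = as.list(stats::setNames(sums, inputs)),
         thresholds = thresholds), extra)
}

.write_tsv <- function(df, path) {
  utils::write.table(format(df, digits = 6, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analyse one or more hexamer models
#'
#' Runs the single-structure pipeline: nucleotide assignment and chain
#' state labels (with all supplied models jointly clustered so ATP* chains
#' are detectable), packing units with interface metrics, and pore-loop
#' metrics, and optionally writes TSV or JSON tables.
#'
#' @param paths named character vector of coordinate files; names become
#'   model labels.  Alternatively pass `models`, a named list of
#'   `structure_model` objects.
#' @param models optional list of pre-read models (overrides `paths`).
#' @param scheme a `domain_scheme` (default CpaF profile).
#' @param thresholds see [default_thresholds()].
#' @param out_dir output directory for report tables, or `NULL` to skip
#'   writing.
#' @param format `"tsv"`, `"json"` or both.
#' @return an `analysis_report`: chain-state table, per-unit metrics
#'   table, pore-metrics table and provenance.
#' @export
run_analyze <- function(paths = NULL, models = NULL, scheme = default_scheme(),
                        thresholds = default_thresholds(), out_dir = NULL,
                        format = c("tsv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  if (is.null(models)) {
    if (is.null(paths) || !length(paths)) stopf("usage: supply paths or models")
    if (is.null(names(paths)) || any(!nzchar(names(paths))))
      stopf("every input path needs a model label (names of `paths`)")
    models <- Map(function(p, l) read_structure(p, label = l), paths, names(paths))
  }
  labs <- vapply(models, function(m) m$label, character(1))
  states <- lapply(seq_along(models), function(i)
    label_chain_states(models[[i]], scheme,
                       reference = if (length(models) > 1) models[-i] else NULL,
                       thresholds = thresholds))
  chain_tab <- do.call(rbind, Map(function(st, l) cbind(model = l, st), states, labs))
  unit_list <- Map(function(m, st) {
    u <- build_packing_units(m, scheme, states = st, thresholds = thresholds)
    list(units = u, metrics = packing_unit_metrics(u, m, scheme, thresholds))
  }, models, states)
  unit_tab <- do.call(rbind, Map(function(ul, l) {
    df <- as.data.frame(ul$metrics)
    data.frame(model = l, name = df$name, nucleotide = df$nucleotide_label,
               r347_g284_A = df$r347_g284, r347_state = df$r347_state,
               r217_state = df$r217_state, r223_state = df$r223_state,
               coordinated_by_R347 = df$coordinated, stringsAsFactors = FALSE)
  }, unit_list, labs))
  pore_list <- lapply(models, function(m) pore_metrics(m, scheme, thresholds = thresholds))
  pore_tab <- do.call(rbind, Map(function(pm, l)
    data.frame(model = l, chain = pm$chains, loop_height_A = pm$loop_heights,
               height_span_asym_A = pm$height_span_asym,
               pore_diameter_A = pm$pore_diameter), pore_list, labs))
  rownames(chain_tab) <- rownames(unit_tab) <- rownames(pore_tab) <- NULL
  rep <- structure(list(chain_states = chain_tab, unit_metrics = unit_tab,
                        pore = pore_tab,
                        provenance = .provenance(
                          vapply(models, function(m) m$source_path, character(1)),
                          thresholds)),
                   class = "analysis_report")
  if (!is.null(out_dir)) .write_report(rep, out_dir, format)
  rep
}

.write_report <- function(rep, out_dir, format) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- Filter(is.data.frame, rep)
  if ("tsv" %in% format)
    for (nm in names(tabs)) .write_tsv(tabs[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  if ("json" %in% format)
    jsonlite::write_json(c(lapply(tabs, identity), list(provenance = rep$provenance)),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 8, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>\n-- chain states --\n"); print(x$chain_states)
  cat("-- packing units --\n"); print(x$unit_metrics)
  cat("-- pore metrics --\n"); print(unique(x$pore[, c("model", "height_span_asym_A", "pore_diameter_A")]))
  invisible(x)
}

#' Analyse a catalytic transition between two hexamer states
#'
#' Wraps [map_catalytic_events()] and flattens the result into an event
#' table (one row per event with per-domain clockwise rotations and anchor
#' displacements).
#'
#' @inheritParams run_analyze
#' @param viewpoint see [rotation_about_axis()].
#' @return a `cycle_report` with the `cycle_map`, the event table, and
#'   provenance.
#' @export
run_cycle <- function(paths = NULL, models = NULL, scheme = default_scheme(),
                      thresholds = default_thresholds(),
                      viewpoint = "from_positive_axis",
                      out_dir = NULL, format = c("tsv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  if (is.null(models)) {
    if (length(paths) != 2) stopf("usage: run_cycle needs exactly two labelled models")
    models <- Map(function(p, l) read_structure(p, label = l), paths, names(paths))
  }
  if (length(models) != 2) stopf("usage: run_cycle needs exactly two models")
  cm <- map_catalytic_events(models[[1]], models[[2]], scheme, thresholds, viewpoint)
  ev_tab <- if (length(cm$events))
    do.call(rbind, lapply(cm$events, function(ev)
      data.frame(kind = ev$kind, direction = ev$direction,
                 source_unit = ev$source_unit, target_unit = ev$target_unit,
                 cad_rotation_deg = ev$twist_deg[["CAD"]],
                 ntd_rotation_deg = ev$twist_deg[["NTD"]],
                 hb3_rotation_deg = ev$twist_deg[["THREE_HELIX_BUNDLE"]],
                 D116_A = ev$displacement[["D116"]],
                 C196_A = ev$displacement[["C196"]],
                 G284_A = ev$displacement[["G284"]],
                 E331_A = ev$displacement[["E331"]])))
  else data.frame()
  rep <- structure(list(cycle_map = cm, events = ev_tab,
                        register_deg_cw = cm$register_deg_cw,
                        direction_summary = cm$direction_summary,
                        provenance = .provenance(
                          vapply(models, function(m) m$source_path, character(1)),
                          thresholds, list(viewpoint = viewpoint))),
                   class = "cycle_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if ("tsv" %in% format && nrow(ev_tab))
      .write_tsv(ev_tab, file.path(out_dir, "events.tsv"))
    if ("json" %in% format)
      jsonlite::write_json(list(register_deg_cw = cm$register_deg_cw,
                                direction = cm$direction_summary,
                                events = ev_tab,
                                provenance = rep$provenance),
                           file.path(out_dir, "cycle.json"),
                           auto_unbox = TRUE, digits = 8, pretty = TRUE)
  }
  rep
}

#' @export
print.cycle_report <- function(x, ...) {
  print(x$cycle_map)
  invisible(x)
}

#' Emit synthetic fixture files with a ground-truth manifest
#'
#' @param spec a [synthetic_spec()], or for a state pair a list of the
#'   spec plus `register_shift_cw`.
#' @param out_dir output directory.
#' @param format coordinate format, `"pdb"` or `"mmcif"`.
#' @param pair generate a catalytic state pair instead of one hexamer.
#' @return paths of the written files, invisibly.
#' @export
run_synth <- function(spec, out_dir, format = c("pdb", "mmcif"), pair = FALSE) {
  format <- match.arg(format)
  ext <- if (format == "pdb") ".pdb" else ".cif"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (pair) {
    g <- generate_state_pair(spec)
    fa <- file.path(out_dir, paste0(g$model_a$label, ext))
    fb <- file.path(out_dir, paste0(g$model_b$label, ext))
    write_structure(g$model_a, fa, format)
    write_structure(g$model_b, fb, format)
    manifest <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(.truth_json(g$truth), manifest, auto_unbox = TRUE,
                         digits = 8, pretty = TRUE)
    invisible(c(fa, fb, manifest))
  } else {
    g <- generate_hexamer(spec)
    f <- file.path(out_dir, paste0(g$model$label, ext))
    write_structure(g$model, f, format)
    manifest <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(.truth_json(g$truth), manifest, auto_unbox = TRUE,
                         digits = 8, pretty = TRUE)
    invisible(c(f, manifest))
  }
}

.truth_json <- function(truth) {
  conv <- function(x) {
    if (is.data.frame(x)) x
    else if (is.list(x)) lapply(x, conv)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  conv(unclass(truth))
}
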