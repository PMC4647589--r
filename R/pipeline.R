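#' Run the full ancestral-state reconstruction pipeline
#'
#' Orchestrates: read the rooted tree, force unit branch lengths
#' (punctuational convention, on by default), read the binary character
#' matrix (TSV or NEXUS), read the clade definitions, fit the Mk1 rate per
#' character, compute marginal node proportions, and write the clade report,
#' the origins summary, per-node proportions (JSON), per-character annotated
#' Newick trees, and a run manifest (input checksums, settings, versions).
#' Outputs are deterministic for fixed inputs. Stage failures are reported
#' with the stage name.
#'
#' @param config Named list (or path to a YAML file) with fields:
#'   `tree`, `matrix`, `clades` (paths), `out_dir`, and optionally
#'   `threshold` (default 0.5), `unit_branch_lengths` (default `TRUE`),
#'   `q_min`/`q_max` (rate bounds), `root_prior` (length-2).
#' @return Invisibly, a list with the `report` (a [clade_report()]), the
#'   `origins` summary, per-character `asr` tables, and output `paths`.
#' @export
run_asr <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (f in c("tree", "matrix", "clades", "out_dir"))
    if (is.null(config[[f]])) stop("config is missing field '", f, "'")
  threshold <- config$threshold %||% 0.5
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  q_bounds <- c(config$q_min %||% 1e-8, config$q_max %||% 1e3)
  pi <- config$root_prior %||% c(0.5, 0.5)
  unit_bl <- config$unit_branch_lengths %||% TRUE

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  tree <- stage("treeio", {
    tr <- read_newick(config$tree)
    if (unit_bl) tr <- set_unit_branch_lengths(tr)
    tr
  })
  mat <- stage("matrix", read_character_matrix(config$matrix))
  clades <- stage("clades", read_clade_definitions(config$clades))
  report <- stage("mk_asr",
                  clade_report(tree, mat, clades, threshold = threshold,
                               q_bounds = q_bounds, pi = pi))
  origins <- stage("reporting", summarize_origins(report, threshold))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ann_dir <- file.path(config$out_dir, "annotated")
  dir.create(ann_dir, showWarnings = FALSE)
  paths <- list(
    report = file.path(config$out_dir, "clade_report.tsv"),
    origins = file.path(config$out_dir, "origins.tsv"),
    nodes = file.path(config$out_dir, "asr_nodes.json"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  stage("reporting", {
    write_clade_report(report, paths$report)
    utils::write.table(origins, paths$origins, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  asr_tables <- stage("mk_asr", {
    out <- list()
    for (ch in rownames(report)) {
      states <- stats::setNames(mat[tree$tip.label, ch], tree$tip.label)
      fit <- estimate_rate(tree, states, q_bounds = q_bounds, pi = pi)
      asr <- marginal_node_proportions(tree, states, fit)
      out[[ch]] <- asr
      safe <- gsub("[^A-Za-z0-9_-]", "_", ch)
      write_annotated_newick(asr, file.path(ann_dir, paste0(safe, ".nwk")))
    }
    out
  })
  stage("reporting", {
    nodes_json <- lapply(asr_tables, function(asr) {
      list(q = attr(asr, "q"), logL = attr(asr, "logL"),
           nodes = data.frame(node = asr$node,
                              p_absent = asr$p_absent,
                              p_present = asr$p_present))
    })
    jsonlite::write_json(nodes_json, paths$nodes, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    manifest <- list(
      inputs = lapply(config[c("tree", "matrix", "clades")], function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))),
      settings = list(threshold = threshold, q_bounds = q_bounds,
                      root_prior = pi, unit_branch_lengths = unit_bl),
      versions = list(fertsig = as.character(utils::packageVersion("fertsig")),
                      R = R.version.string)
    )
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })
  invisible(list(report = report, origins = origins, asr = asr_tables,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Earliest clade where each character is likely ancestrally present
#'
#' For each character class, finds the most inclusive named clade (largest
#' tip count) whose clade-report cell strictly exceeds the threshold --
#' i.e. the earliest reported origin of the class as a fertility signal --
#' or `"none"` when no clade passes.
#'
#' @param report A [clade_report()] (or [as_clade_report()]).
#' @param threshold Proportion in (0, 1); default the report's own.
#' @return Data frame with `character`, `origin_clade`,
#'   `percent_at_origin`.
#' @export
summarize_origins <- function(report, threshold = NULL) {
  if (!inherits(report, "clade_report")) stop("not a clade_report")
  threshold <- threshold %||% attr(report, "threshold")
  sizes <- attr(report, "clade_sizes")
  cells <- unclass(report)
  attributes(cells) <- attributes(cells)[c("dim", "dimnames")]
  out <- data.frame(character = rownames(cells),
                    origin_clade = "none",
                    percent_at_origin = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    hits <- which(!is.na(cells[i, ]) & cells[i, ] > 100 * threshold)
    if (length(hits)) {
      best <- hits[which.max(sizes[hits])]
      out$origin_clade[i] <- colnames(cells)[best]
      out$percent_at_origin[i] <- cells[i, best]
    }
  }
  out
}

#' Load the packaged reference clade-percentage table as a clade report
#'
#' Reads `reference_clade_percentages.tsv` (clade-level percent likelihoods
#' of ancestral presence for the 12 compound classes across seven named bee
#' clades) and attaches clade inclusiveness (tip counts) from
#' `clades_bees.yml`, so it can be fed to [summarize_origins()].
#'
#' @param threshold Likelihood threshold, default 0.5.
#' @return A `clade_report`.
#' @export
reference_clade_report <- function(threshold = 0.5) {
  tab <- utils::read.delim(fertsig_example("reference_clade_percentages.tsv"),
                           check.names = FALSE)
  cells <- as.matrix(tab[, -1, drop = FALSE])
  rownames(cells) <- tab$character
  clades <- yaml::read_yaml(fertsig_example("clades_bees.yml"))
  sizes <- vapply(clades, length, integer(1))
  as_clade_report(cells, sizes[colnames(cells)], threshold = threshold)
}

#' Path to a packaged example/fixture file
#'
#' Available fixtures: `bee_supertree_reconstructed.nwk` (a best-effort
#' 16-species composite bee phylogeny; see its documentation in the package
#' vignette -- species identities beyond those named in published clade
#' tables are plausible stand-ins, so the file is a reconstruction, not the
#' original supertree), `clades_bees.yml` (the seven named bee clades),
#' and `reference_clade_percentages.tsv` (published clade-level likelihood
#' percentages for the 12 compound classes, usable as input to
#' [summarize_origins()] via [as_clade_report()]).
#'
#' @param file File name; with no argument, lists available files.
#' @return Full path (or vector of file names).
#' @export
fertsig_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "fertsig")))
  path <- system.file("extdata", file, package = "fertsig")
  if (!nzchar(path)) stop("no packaged file named '", file, "'")
  path
}
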