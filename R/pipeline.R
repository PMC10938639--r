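#' Read and validate a pipeline run configuration
#'
#' The YAML configuration names the input files and the knobs of each
#' stage. Required: `library` (raw library CSV/SDF), `references` and
#' `scores` (score CSVs). Optional: `ml` (prediction CSV; required whenever
#' the score tables contain receptors with machine-learning models),
#' `rules` (taxonomy YAML overriding the builtin set), `commercial` (text
#' file of commercially relevant chemical ids, one per line), `id_col` /
#' `smiles_col` (library column map), `threshold` (shortlist slack,
#' default 0.10), and `som` (`rows`, `cols`, `epochs`, `n_bits`, `seed`;
#' omit to skip the map).
#'
#' @param path YAML file.
#' @return Validated configuration list (class `pfas_run_config`) with the
#'   source path attached.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("library", "references", "scores")) {
    if (is.null(cfg[[key]])) stop("config is missing '", key, "'")
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  for (key in c("library", "references", "scores", "ml", "rules",
                "commercial")) {
    cfg[[key]] <- resolve(cfg[[key]])
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop("config path for '", key, "' does not exist: ", cfg[[key]])
    }
  }
  cfg$threshold <- if (is.null(cfg$threshold)) 0.10 else cfg$threshold
  cfg$id_col <- if (is.null(cfg$id_col)) "chemical_id" else cfg$id_col
  cfg$smiles_col <- if (is.null(cfg$smiles_col)) "smiles" else cfg$smiles_col
  attr(cfg, "source") <- normalizePath(path)
  class(cfg) <- "pfas_run_config"
  cfg
}

#' Run the full screening pipeline
#'
#' Orchestrates curation, taxonomy, triage, summaries, commercial tagging
#' and (optionally) the chemical-space map, writing every artifact as CSV
#' into `out_dir` together with a JSON manifest of MD5 hashes and a
#' verbatim copy of the configuration. Re-running on identical inputs
#' produces byte-identical artifacts. Any stage failure aborts with the
#' stage name.
#'
#' @param config A [read_run_config()] object or a path to the YAML file.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "pfas_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[pfas-triage] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  artifacts <- list()
  put <- function(name, obj) {
    path <- file.path(out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    artifacts[[name]] <<- path
    path
  }

  say("curation: ", config$library)
  curated <- stage("curation", {
    raw <- parse_library(config$library, id_col = config$id_col,
                         smiles_col = config$smiles_col)
    apply_inclusion_filters(raw)
  })
  put("curated_library.csv", curated)
  put("curation_audit.csv", curation_audit(curated))
  say("curation: ", sum(curated$included), " of ", nrow(curated),
      " included")

  say("taxonomy")
  classes <- stage("taxonomy", {
    rules <- if (is.null(config$rules)) pfas_ruleset() else {
      pfas_ruleset(config$rules)
    }
    classify_pfas(curated, rules)
  })
  put("classes.csv", classes)
  put("class_distribution.csv", class_distribution(classes))

  say("triage")
  calls <- stage("triage", {
    refs <- read_scores(config$references)
    scores <- read_scores(config$scores)
    ml <- if (!is.null(config$ml)) read_ml(config$ml) else NULL
    triage_calls(scores, compute_reference_stats(refs), ml,
                 threshold = config$threshold)
  })
  put("activity_calls.csv", calls)
  summary <- summarize_counts(calls)
  put("summary_by_receptor.csv", summary$by_receptor)
  put("strength_histogram.csv", summary$strength)
  say("triage: ", sum(summary$by_receptor$n_total_active),
      " active calls across ", nrow(summary$by_receptor), " receptors")

  if (!is.null(config$commercial)) {
    say("commercial tagging")
    ids <- stage("commercial", readLines(config$commercial, warn = FALSE))
    put("commercial_calls.csv", tag_commercial(calls, ids))
  }

  if (!is.null(config$som)) {
    say("chemical-space map")
    stage("som", {
      som_cfg <- config$som
      fps <- fingerprint_library(
        curated,
        n_bits = if (is.null(som_cfg$n_bits)) 2048 else som_cfg$n_bits
      )
      model <- train_som(
        fps,
        rows = if (is.null(som_cfg$rows)) 20 else som_cfg$rows,
        cols = if (is.null(som_cfg$cols)) 20 else som_cfg$cols,
        epochs = if (is.null(som_cfg$epochs)) 50 else som_cfg$epochs,
        seed = if (is.null(som_cfg$seed)) 1L else som_cfg$seed
      )
      som_path <- file.path(out_dir, "som_model.json")
      write_som(model, som_path)
      artifacts[["som_model.json"]] <- som_path
      panels <- list()
      fp_ids <- rownames(fps)
      for (r in intersect(unique(calls$receptor), NR_RECEPTORS)) {
        have <- fp_ids %in% calls$chemical_id[calls$receptor == r]
        if (!any(have)) next
        panel <- project_activity(model, fps[have, , drop = FALSE],
                                  calls, r)
        panel$receptor <- r
        panels[[r]] <- panel
      }
      if (length(panels)) {
        put("som_panels.csv", do.call(rbind, c(panels,
                                               make.row.names = FALSE)))
      }
    })
  }

  cfg_copy <- file.path(out_dir, "run_config.yaml")
  file.copy(attr(config, "source"), cfg_copy, overwrite = TRUE)
  artifacts[["run_config.yaml"]] <- cfg_copy

  manifest <- list(
    artifacts = lapply(sort(names(artifacts)), function(nm) {
      p <- artifacts[[nm]]
      list(name = nm, md5 = unname(tools::md5sum(p)),
           bytes = file.info(p)$size)
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  artifacts[["manifest.json"]] <- manifest_path
  say("done: ", length(artifacts), " artifacts in ", out_dir)
  invisible(artifacts)
}

#' Cross-tabulate active calls against a commercial-relevance list
#'
#' @param calls Activity calls ([triage_calls()]).
#' @param commercial_ids Character vector of chemical identifiers.
#' @return The active calls whose chemical is on the list, per receptor,
#'   carrying the strength class.
#' @export
tag_commercial <- function(calls, commercial_ids) {
  hit <- calls$final_call != "inactive" &
    calls$chemical_id %in% commercial_ids
  out <- calls[hit, c("chemical_id", "receptor", "strength", "final_call"),
               drop = FALSE]
  out <- out[order(out$receptor, out$chemical_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coefficient of determination between potency and score
#'
#' Squared Pearson correlation of paired observations, for comparing
#' experimental potencies (e.g. IC50) with computed scores. Potencies are
#' used as provided; set `log10_x = TRUE` to correlate on a log scale.
#'
#' @param x Potency values.
#' @param y Scores.
#' @param log10_x Log-transform `x` first (requires positive values).
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(x, y, log10_x = FALSE) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired finite observations")
  if (log10_x) {
    if (any(x <= 0)) stop("log10 transform requires positive potencies")
    x <- log10(x)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: R-squared undefined")
  }
  stats::cor(x, y)^2
}
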