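#' Read a docking / binding-free-energy score table
#'
#' Scores are binding-favourability estimates in kcal/mol; more negative is
#' stronger. The table must have one row per (chemical, receptor) pair; use
#' [collapse_best_scores()] first if an upstream ensemble produced several
#' rows per pair.
#'
#' @param path CSV with columns `chemical_id`, `receptor`, `dock_score`,
#'   `dg_bind` (comma-separated, header row, `.` decimal).
#' @return Data frame of typed score records.
#' @export
read_scores <- function(path) {
  tab <- read_checked_csv(path, c("chemical_id", "receptor",
                                  "dock_score", "dg_bind"))
  tab$chemical_id <- as.character(tab$chemical_id)
  tab$receptor <- as.character(tab$receptor)
  check_receptors(tab$receptor, NR_RECEPTORS, path)
  for (col in c("dock_score", "dg_bind")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(val))
    if (length(bad)) {
      stop("non-numeric or non-finite ", col, " in ", path,
           " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    }
    tab[[col]] <- val
  }
  check_unique_keys(tab, path)
  tab
}

#' Read a machine-learning activity-prediction table
#'
#' Emulates the output format of per-receptor activity models:
#' binding-class receptors carry agonist / antagonist / agonist_antagonist /
#' inactive labels, effector receptors active / inactive. MR and PPARA have
#' no models and must not appear.
#'
#' @param path CSV with columns `chemical_id`, `receptor`, `label`,
#'   `in_domain`.
#' @return Data frame of typed prediction records; `in_domain` is logical.
#' @export
read_ml <- function(path) {
  tab <- read_checked_csv(path, c("chemical_id", "receptor", "label",
                                  "in_domain"))
  tab$chemical_id <- as.character(tab$chemical_id)
  tab$receptor <- as.character(tab$receptor)
  check_receptors(tab$receptor, ML_RECEPTORS, path)
  bad <- which(!tab$label %in% ML_LABELS)
  if (length(bad)) {
    stop("unknown activity label in ", path, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  tab$in_domain <- parse_logical(tab$in_domain, path)
  check_unique_keys(tab, path)
  tab
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("missing column(s) ", paste(missing, collapse = ", "),
         " in ", path)
  }
  tab
}

check_receptors <- function(receptor, allowed, path) {
  bad <- which(!receptor %in% allowed)
  if (length(bad)) {
    stop("unknown receptor '", receptor[bad[1]], "' in ", path,
         " at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(TRUE)
}

check_unique_keys <- function(tab, path) {
  key <- paste(tab$chemical_id, tab$receptor, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicate (chemical_id, receptor) pair in ", path,
         " at row(s) ", paste(utils::head(dup, 5), collapse = ", "))
  }
  invisible(TRUE)
}

parse_logical <- function(x, path) {
  out <- rep(NA, length(x))
  truthy <- c("TRUE", "true", "T", "1")
  falsy <- c("FALSE", "false", "F", "0")
  out[x %in% truthy] <- TRUE
  out[x %in% falsy] <- FALSE
  if (anyNA(out)) {
    stop("non-logical in_domain value in ", path, " at row(s) ",
         paste(utils::head(which(is.na(out)), 5), collapse = ", "))
  }
  out
}

#' Collapse ensemble score rows to the best score per (chemical, receptor)
#'
#' Utility for upstream ensembles that score a chemical against several
#' receptor conformations: keeps the most negative value of each metric.
#'
#' @param scores Score table with possibly repeated (chemical, receptor)
#'   pairs.
#' @return One row per pair with per-metric minima.
#' @export
collapse_best_scores <- function(scores) {
  agg <- stats::aggregate(
    cbind(dock_score, dg_bind) ~ chemical_id + receptor,
    data = scores, FUN = min
  )
  agg[order(agg$receptor, agg$chemical_id), , drop = FALSE]
}

#' Per-receptor reference-ligand statistics
#'
#' Computes the arithmetic mean and the best (most negative) value of the
#' docking score and of the binding free energy over the reference ligands
#' of each receptor. The mean anchors the percent-change statistic
#' ([percent_change()]); the best value anchors the shortlist rule
#' ([shortlist_scores()]).
#'
#' @param references Score table of reference ligands ([read_scores()]).
#' @return Data frame with one row per receptor: `receptor`, `n_ref`,
#'   `mean_dock`, `best_dock`, `mean_dg`, `best_dg`.
#' @examples
#' refs <- data.frame(chemical_id = c("r1", "r2", "r3"), receptor = "AR",
#'                    dock_score = c(-8, -10, -12), dg_bind = c(-40, -50, -60))
#' compute_reference_stats(refs)
#' @export
compute_reference_stats <- function(references) {
  if (nrow(references) == 0L) stop("no reference records")
  split_idx <- split(seq_len(nrow(references)), references$receptor)
  rows <- lapply(names(split_idx), function(r) {
    i <- split_idx[[r]]
    data.frame(
      receptor = r,
      n_ref = length(i),
      mean_dock = mean(references$dock_score[i]),
      best_dock = min(references$dock_score[i]),
      mean_dg = mean(references$dg_bind[i]),
      best_dg = min(references$dg_bind[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$receptor), , drop = FALSE]
}

#' Write score / prediction tables
#'
#' CSV writers matching the dialect accepted by [read_scores()] and
#' [read_ml()].
#'
#' @param tab Table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(tab, path) {
  utils::write.csv(tab[, c("chemical_id", "receptor", "dock_score",
                           "dg_bind")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
write_ml <- function(tab, path) {
  utils::write.csv(tab[, c("chemical_id", "receptor", "label",
                           "in_domain")], path, row.names = FALSE)
  invisible(path)
}
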