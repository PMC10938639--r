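#' Percent change of a score relative to the reference mean
#'
#' Computes `100 * (value - ref_mean) / ref_mean`. Both docking scores and
#' binding free energies are negative for favourable binding, so a candidate
#' that binds more strongly than the reference average (more negative score)
#' gets a positive percent change under this formula. Set `negate = TRUE`
#' for the opposite sign convention.
#'
#' @param value Score(s), kcal/mol.
#' @param ref_mean Reference-ligand mean score(s) for the same receptor and
#'   metric; must be non-zero.
#' @param negate Flip the sign convention.
#' @return Percent change(s).
#' @examples
#' percent_change(-11, -10) # +10: stronger than the reference mean
#' percent_change(-9, -10)  # -10: weaker
#' @export
percent_change <- function(value, ref_mean, negate = FALSE) {
  if (any(ref_mean == 0)) {
    stop("percent change undefined for a zero reference mean")
  }
  pc <- 100 * (value - ref_mean) / ref_mean
  if (negate) -pc else pc
}

#' Average percent change over the two score metrics
#'
#' @param pc_dock,pc_dg Percent changes for the docking score and the
#'   binding free energy.
#' @return Arithmetic mean of the two.
#' @export
average_percent_change <- function(pc_dock, pc_dg) {
  stopifnot(all(is.finite(pc_dock)), all(is.finite(pc_dg)))
  (pc_dock + pc_dg) / 2
}

#' Classify binder strength from the average percent change
#'
#' Strong if the average percent change is greater than 0, moderate if in
#' (-10, 0], weak if less than or equal to -10. The three intervals
#' partition the real line, so every finite input receives exactly one
#' class.
#'
#' @param avg_pc Average percent change(s).
#' @return Character vector in `c("strong", "moderate", "weak")`.
#' @examples
#' classify_strength(c(5, -5, -10, 0))
#' @export
classify_strength <- function(avg_pc) {
  stopifnot(all(is.finite(avg_pc)))
  ifelse(avg_pc > 0, "strong", ifelse(avg_pc > -10, "moderate", "weak"))
}

#' Reference-anchored shortlist rule
#'
#' A candidate is shortlisted when both its docking score and its binding
#' free energy lie within `threshold` (default 10%) of the best (most
#' negative) reference-ligand value for that receptor:
#' `dock <= (1 - threshold) * best_dock` and
#' `dg <= (1 - threshold) * best_dg`. With negative scores the bound is 10%
#' less favourable than the best reference, and the two criteria are
#' required conjunctively.
#'
#' @param dock_score,dg_bind Candidate scores, kcal/mol (negative).
#' @param best_dock,best_dg Best reference values for the receptor
#'   (negative; see [compute_reference_stats()]).
#' @param threshold Fractional slack relative to the best reference.
#' @return Logical vector.
#' @examples
#' shortlist_scores(-11, -55, best_dock = -12, best_dg = -60) # TRUE
#' shortlist_scores(-10, -55, best_dock = -12, best_dg = -60) # FALSE
#' @export
shortlist_scores <- function(dock_score, dg_bind, best_dock, best_dg,
                             threshold = 0.10) {
  if (any(best_dock >= 0) || any(best_dg >= 0)) {
    stop("reference best scores must be negative (binding-favourable)")
  }
  stopifnot(threshold >= 0, threshold < 1)
  dock_score <= (1 - threshold) * best_dock &
    dg_bind <= (1 - threshold) * best_dg
}

#' Consensus active call
#'
#' For the eight receptors with machine-learning models a chemical is called
#' active only when it is shortlisted *and* its predicted label is an active
#' mode (agonist, antagonist, agonist_antagonist, or active), the label
#' being carried into the call. For MR and PPARA, which have no models,
#' shortlisting alone decides. Supplying a label for MR/PPARA is a contract
#' violation; a shortlisted chemical at a machine-learning receptor must
#' have a label.
#'
#' @param shortlisted Logical vector.
#' @param ml_label Labels from [read_ml()]; `NA` where absent.
#' @param receptor Receptor per record.
#' @return Character vector of final calls: `active_agonist`,
#'   `active_antagonist`, `active_ago_ant`, `active`, or `inactive`.
#' @export
consensus_call <- function(shortlisted, ml_label, receptor) {
  n <- length(shortlisted)
  stopifnot(length(ml_label) == n, length(receptor) == n)
  bad <- receptor %in% DOCK_ONLY_RECEPTORS & !is.na(ml_label)
  if (any(bad)) {
    stop("machine-learning labels supplied for receptor(s) without models: ",
         paste(unique(receptor[bad]), collapse = ", "))
  }
  need <- receptor %in% ML_RECEPTORS & shortlisted & is.na(ml_label)
  if (any(need)) {
    stop("missing machine-learning label for shortlisted chemical(s) at ",
         paste(unique(receptor[need]), collapse = ", "))
  }
  unknown <- !is.na(ml_label) & !ml_label %in% ML_LABELS
  if (any(unknown)) stop("unknown label: ", ml_label[which(unknown)[1]])
  out <- rep("inactive", n)
  dock_only <- receptor %in% DOCK_ONLY_RECEPTORS
  out[shortlisted & dock_only] <- "active"
  gate <- shortlisted & !dock_only & ml_label %in% ACTIVEISH_LABELS
  map <- c(agonist = "active_agonist", antagonist = "active_antagonist",
           agonist_antagonist = "active_ago_ant", active = "active")
  out[gate] <- unname(map[ml_label[gate]])
  out
}

#' Triage a candidate score table into activity calls
#'
#' Runs the full per-chemical triage: percent change of each metric against
#' the receptor's reference mean, their average, the shortlist decision
#' against the best reference values, the binder-strength class (chemicals
#' failing the shortlist are reported `not_shortlisted`, never `weak`), and
#' the consensus call gated by the machine-learning predictions.
#'
#' @param scores Candidate score table ([read_scores()]).
#' @param ref_stats Per-receptor reference statistics
#'   ([compute_reference_stats()]).
#' @param ml Optional prediction table ([read_ml()]); required whenever a
#'   shortlisted chemical sits at a machine-learning receptor.
#' @param threshold Shortlist slack, default 0.10.
#' @return Data frame with one row per (chemical, receptor):
#'   `chemical_id`, `receptor`, `dock_score`, `dg_bind`, `pc_dock`, `pc_dg`,
#'   `avg_pc`, `shortlisted`, `strength`, `ml_label`, `final_call`.
#' @export
triage_calls <- function(scores, ref_stats, ml = NULL, threshold = 0.10) {
  missing_rec <- setdiff(unique(scores$receptor), ref_stats$receptor)
  if (length(missing_rec)) {
    stop("no reference statistics for receptor(s): ",
         paste(missing_rec, collapse = ", "))
  }
  i <- match(scores$receptor, ref_stats$receptor)
  pc_dock <- percent_change(scores$dock_score, ref_stats$mean_dock[i])
  pc_dg <- percent_change(scores$dg_bind, ref_stats$mean_dg[i])
  avg_pc <- average_percent_change(pc_dock, pc_dg)
  shortlisted <- shortlist_scores(scores$dock_score, scores$dg_bind,
                                  ref_stats$best_dock[i],
                                  ref_stats$best_dg[i], threshold)
  strength <- ifelse(shortlisted, classify_strength(avg_pc),
                     "not_shortlisted")
  ml_label <- rep(NA_character_, nrow(scores))
  if (!is.null(ml) && nrow(ml)) {
    j <- match(paste(scores$chemical_id, scores$receptor, sep = "\r"),
               paste(ml$chemical_id, ml$receptor, sep = "\r"))
    ml_label <- ml$label[j]
  }
  final_call <- consensus_call(shortlisted, ml_label, scores$receptor)
  data.frame(
    chemical_id = scores$chemical_id, receptor = scores$receptor,
    dock_score = scores$dock_score, dg_bind = scores$dg_bind,
    pc_dock = pc_dock, pc_dg = pc_dg, avg_pc = avg_pc,
    shortlisted = shortlisted, strength = strength, ml_label = ml_label,
    final_call = final_call, stringsAsFactors = FALSE
  )
}

#' Per-receptor summary of activity calls
#'
#' Aggregates triage calls into a per-receptor table of predicted actives
#' partitioned by call type (the per-receptor total is the row sum of the
#' label columns), plus a binder-strength histogram over the active calls.
#'
#' @param calls Activity calls ([triage_calls()]).
#' @param receptors Receptors to report (rows appear even when all-zero).
#' @return List with elements `by_receptor` (receptor, n_ago_ant,
#'   n_antagonist, n_agonist, n_active, n_total_active) and `strength`
#'   (strength, n over the active calls).
#' @export
summarize_counts <- function(calls,
                             receptors = sort(unique(calls$receptor))) {
  if (nrow(calls) == 0L && length(receptors) == 0L) {
    receptors <- character(0)
  }
  rows <- lapply(receptors, function(r) {
    cc <- calls$final_call[calls$receptor == r]
    data.frame(
      receptor = r,
      n_ago_ant = sum(cc == "active_ago_ant"),
      n_antagonist = sum(cc == "active_antagonist"),
      n_agonist = sum(cc == "active_agonist"),
      n_active = sum(cc == "active"),
      n_total_active = sum(cc != "inactive"),
      stringsAsFactors = FALSE
    )
  })
  by_receptor <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(receptor = character(0), n_ago_ant = integer(0),
               n_antagonist = integer(0), n_agonist = integer(0),
               n_active = integer(0), n_total_active = integer(0))
  }
  active <- calls[calls$final_call != "inactive", , drop = FALSE]
  strength <- data.frame(
    strength = c("strong", "moderate", "weak"),
    n = vapply(c("strong", "moderate", "weak"),
               function(s) sum(active$strength == s), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(by_receptor = by_receptor, strength = strength)
}
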