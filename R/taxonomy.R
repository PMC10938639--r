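#' Load a PFAS classification ruleset
#'
#' Rules are data, not code: each rule has a unique `rule_id`, a unique
#' numeric `priority` (lower fires first), a `primary` and `secondary` class
#' and a conjunction of SMARTS patterns (`all_of`, optionally `none_of`).
#' The builtin ruleset (shipped as
#' `inst/extdata/pfas_class_rules.yaml`) encodes the commonly used PFAS
#' scheme: side-chain aromatics take precedence over acid heads, followed by
#' the perfluoroalkyl acids (PFCAs/PFSAs), the perfluoroalkane sulfonamide
#' (FASA) family, the fluorotelomers, perfluoroalkane sulfonyl fluorides
#' (PASF), and a catch-all for other aliphatics.
#'
#' A user file passed via `path` is merged over the builtin set: a rule
#' whose `rule_id` matches a builtin rule replaces it, new rules are added.
#' Pass `base = NULL` to load the user file alone.
#'
#' @param path Optional YAML file of rules.
#' @param base Ruleset to merge into; defaults to the builtin set.
#' @return A `pfas_ruleset`: data frame ordered by priority with columns
#'   `rule_id`, `priority`, `primary`, `secondary`, and list-columns
#'   `all_of`, `none_of`.
#' @export
pfas_ruleset <- function(path = NULL, base = "builtin") {
  rules <- list()
  if (identical(base, "builtin")) {
    builtin <- system.file("extdata", "pfas_class_rules.yaml",
                           package = "pfastriage", mustWork = TRUE)
    rules <- yaml::read_yaml(builtin)$rules
  } else if (!is.null(base)) {
    stopifnot(inherits(base, "pfas_ruleset"))
    rules <- ruleset_to_list(base)
  }
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)$rules
    if (is.null(user)) stop("no 'rules' entry in ", path)
    ids <- vapply(rules, `[[`, "", "rule_id")
    for (r in user) {
      hit <- match(r$rule_id, ids)
      if (is.na(hit)) {
        rules <- c(rules, list(r))
        ids <- c(ids, r$rule_id)
      } else {
        rules[[hit]] <- r
      }
    }
  }
  build_ruleset(rules)
}

ruleset_to_list <- function(ruleset) {
  lapply(seq_len(nrow(ruleset)), function(i) {
    list(rule_id = ruleset$rule_id[i], priority = ruleset$priority[i],
         primary = ruleset$primary[i], secondary = ruleset$secondary[i],
         all_of = ruleset$all_of[[i]], none_of = ruleset$none_of[[i]])
  })
}

build_ruleset <- function(rules) {
  if (length(rules) == 0L) stop("empty ruleset")
  out <- data.frame(
    rule_id = vapply(rules, function(r) as.character(r$rule_id), ""),
    priority = vapply(rules, function(r) as.numeric(r$priority), 0),
    primary = vapply(rules, function(r) as.character(r$primary), ""),
    secondary = vapply(rules, function(r) as.character(r$secondary), ""),
    stringsAsFactors = FALSE
  )
  out$all_of <- lapply(rules, function(r) {
    as.character(if (is.null(r$all_of)) character(0) else unlist(r$all_of))
  })
  out$none_of <- lapply(rules, function(r) {
    as.character(if (is.null(r$none_of)) character(0) else unlist(r$none_of))
  })
  if (anyDuplicated(out$rule_id)) stop("duplicate rule_id in ruleset")
  if (anyDuplicated(out$priority)) {
    stop("duplicate rule priority in ruleset")
  }
  probe <- ob_parse_one("OC(=O)C(F)(F)F")
  for (p in unique(unlist(c(out$all_of, out$none_of)))) {
    ok <- tryCatch({
      ob_smarts_count(list(probe), p)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("SMARTS pattern does not parse: '", p, "'")
  }
  out <- out[order(out$priority), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pfas_ruleset", class(out))
  out
}

#' Assign PFAS taxonomy classes
#'
#' Classifies each chemical by the first matching rule in priority order;
#' the catch-all rule guarantees every parseable chemical receives exactly
#' one (primary, secondary) pair. Classification is per molecule and
#' therefore independent of library order.
#'
#' @param x A curated library data frame (uses `canonical_smiles` for
#'   included records, with `source_id` as identifier) or a character vector
#'   of SMILES (optionally named with identifiers).
#' @param ruleset A [pfas_ruleset()]; defaults to the builtin rules.
#' @return Data frame with columns `chemical_id`, `primary_class`,
#'   `secondary_class`, `rule_id`.
#' @examples
#' classify_pfas(c(PFOA = "OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F"))
#' @export
classify_pfas <- function(x, ruleset = pfas_ruleset()) {
  if (is.data.frame(x)) {
    keep <- if ("included" %in% names(x)) x$included else TRUE
    x <- x[keep, , drop = FALSE]
    smiles <- if ("canonical_smiles" %in% names(x)) {
      x$canonical_smiles
    } else {
      x$smiles
    }
    ids <- x$source_id
  } else {
    smiles <- as.character(x)
    ids <- if (!is.null(names(x))) names(x) else {
      sprintf("CHEM%04d", seq_along(x))
    }
  }
  if (length(smiles) == 0L) {
    return(data.frame(chemical_id = character(0),
                      primary_class = character(0),
                      secondary_class = character(0),
                      rule_id = character(0), stringsAsFactors = FALSE))
  }
  mols <- ob_parse(smiles)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    stop("unparseable SMILES for: ",
         paste(utils::head(ids[bad], 5), collapse = ", "))
  }
  patterns <- unique(unlist(c(ruleset$all_of, ruleset$none_of)))
  match_mat <- if (length(patterns)) {
    m <- vapply(patterns, function(p) ob_smarts_matches(mols, p),
                logical(length(mols)))
    matrix(m, nrow = length(mols),
           dimnames = list(NULL, patterns))
  } else {
    matrix(logical(0), nrow = length(mols), ncol = 0)
  }
  assigned <- rep(NA_integer_, length(mols))
  for (k in seq_len(nrow(ruleset))) {
    need <- ruleset$all_of[[k]]
    veto <- ruleset$none_of[[k]]
    hit <- rep(TRUE, length(mols))
    for (p in need) hit <- hit & match_mat[, p]
    for (p in veto) hit <- hit & !match_mat[, p]
    take <- is.na(assigned) & hit
    assigned[take] <- k
  }
  if (anyNA(assigned)) {
    stop("ruleset has no catch-all rule; ", sum(is.na(assigned)),
         " chemical(s) unclassified")
  }
  data.frame(
    chemical_id = ids,
    primary_class = ruleset$primary[assigned],
    secondary_class = ruleset$secondary[assigned],
    rule_id = ruleset$rule_id[assigned],
    stringsAsFactors = FALSE
  )
}

#' Class distribution of a set of assignments
#'
#' @param assignments Output of [classify_pfas()].
#' @return Data frame of counts per (primary, secondary) class, ordered by
#'   decreasing count; counts sum to the number of classified chemicals.
#' @export
class_distribution <- function(assignments) {
  if (nrow(assignments) == 0L) {
    return(data.frame(primary_class = character(0),
                      secondary_class = character(0), n = integer(0)))
  }
  agg <- stats::aggregate(
    list(n = assignments$chemical_id),
    by = list(primary_class = assignments$primary_class,
              secondary_class = assignments$secondary_class),
    FUN = length
  )
  agg <- agg[order(-agg$n, agg$primary_class, agg$secondary_class), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg
}
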