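#' Read a raw chemical library from CSV or SDF
#'
#' Produces one raw entry per row (CSV) or molecule record (SDF), preserving
#' input order. Entries are never dropped at this stage: empty or invalid
#' SMILES are carried through and flagged later by
#' [apply_inclusion_filters()].
#'
#' @param path Path to a `.csv` or `.sdf` file.
#' @param format `"auto"` (by extension), `"csv"` or `"sdf"`.
#' @param id_col,smiles_col CSV column names holding the identifier and the
#'   SMILES string.
#' @param name_col Optional CSV column with a display name.
#' @param id_prop For SDF input, the data-block property holding the
#'   identifier; defaults to the molecule title.
#' @return A data frame with columns `source_id`, `smiles`, `name`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(dtxsid = c("A", "B"), smiles = c("OC(=O)C(F)(F)F", "CCCC")),
#'           f, row.names = FALSE)
#' parse_library(f, id_col = "dtxsid", smiles_col = "smiles")
#' @export
parse_library <- function(path, format = c("auto", "csv", "sdf"),
                          id_col = "chemical_id", smiles_col = "smiles",
                          name_col = NULL, id_prop = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("library file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "csv"
  }
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
    for (col in c(id_col, smiles_col)) {
      if (!col %in% names(tab)) {
        stop("column '", col, "' not found in ", path)
      }
    }
    out <- data.frame(
      source_id = tab[[id_col]],
      smiles = tab[[smiles_col]],
      name = if (!is.null(name_col) && name_col %in% names(tab)) {
        tab[[name_col]]
      } else {
        NA_character_
      },
      stringsAsFactors = FALSE
    )
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    n <- length(sdf)
    ids <- ChemmineR::sdfid(sdf)
    if (!is.null(id_prop)) {
      blocks <- ChemmineR::datablock(sdf)
      ids <- vapply(blocks, function(b) {
        if (id_prop %in% names(b)) unname(b[[id_prop]]) else NA_character_
      }, character(1))
    }
    smi <- as.character(
      suppressWarnings(ChemmineR::sdf2smiles(sdf))
    )
    out <- data.frame(source_id = ids, smiles = unname(smi),
                      name = NA_character_, stringsAsFactors = FALSE)
  }
  if (any(!nzchar(out$source_id) | is.na(out$source_id))) {
    stop("empty identifiers in ", path)
  }
  rownames(out) <- NULL
  out
}

#' Count fluorine atoms in a molecule
#'
#' Counts every fluorine atom regardless of environment (aliphatic,
#' aromatic, ionic).
#'
#' @param smiles Character vector of SMILES strings.
#' @return Integer vector of fluorine counts.
#' @examples
#' count_fluorines(c("OC(=O)C(F)(F)F", "CCCC"))
#' @export
count_fluorines <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    mol <- ob_parse_one(s)
    if (is.null(mol)) stop("unparseable SMILES: '", s, "'")
    ob_smarts_count(list(mol), "[#9]")
  }, integer(1), USE.NAMES = FALSE)
}

#' Test for a perfluorinated unit
#'
#' A molecule is considered to contain a perfluorinated unit if at least one
#' saturated carbon bears two or more fluorines (a CF2 or CF3 group). The
#' pattern is configurable; see [PERFLUORO_UNIT_SMARTS].
#'
#' @param smiles Character vector of SMILES strings.
#' @param smarts Substructure pattern defining the unit.
#' @return Logical vector.
#' @examples
#' has_perfluorinated_unit(c("OC(=O)C(F)(F)F", "FCC(F)CF"))
#' @export
has_perfluorinated_unit <- function(smiles, smarts = PERFLUORO_UNIT_SMARTS) {
  vapply(as.character(smiles), function(s) {
    mol <- ob_parse_one(s)
    if (is.null(mol)) stop("unparseable SMILES: '", s, "'")
    ob_smarts_count(list(mol), smarts) > 0L
  }, logical(1), USE.NAMES = FALSE)
}

#' Canonical structure key for deduplication
#'
#' The key is the InChIKey of the largest covalent fragment (salts and
#' counterions are dropped first); when no InChIKey can be produced the
#' canonical SMILES of that fragment is used, prefixed `"CAN:"`.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of keys; `NA` for unparseable input.
#' @export
structure_key <- function(smiles) {
  smiles <- as.character(smiles)
  can <- ob_convert_batch(smiles, "CAN")
  if (is.null(can)) {
    can <- vapply(smiles, ob_canonical_smiles, character(1),
                  USE.NAMES = FALSE)
  }
  can[!is.na(can) & !nzchar(can)] <- NA_character_
  structure_key_from_canonical(can)
}

# Keys from already-canonical SMILES (NA entries propagate).
structure_key_from_canonical <- function(can) {
  frag <- vapply(can, largest_fragment_of, character(1), USE.NAMES = FALSE)
  key <- rep(NA_character_, length(frag))
  ok <- !is.na(frag)
  if (any(ok)) {
    ik <- ob_convert_batch(frag[ok], "INCHIKEY")
    if (is.null(ik)) {
      ik <- vapply(frag[ok], ob_inchikey, character(1), USE.NAMES = FALSE)
    }
    miss <- is.na(ik) | !nzchar(ik)
    miss[is.na(miss)] <- TRUE
    ik[miss] <- paste0("CAN:", frag[ok][miss])
    key[ok] <- ik
  }
  key
}

#' Apply the PFAS inclusion filters to a raw library
#'
#' Every input entry yields exactly one curated record; nothing is silently
#' dropped. Filters are applied in a fixed order so that each excluded entry
#' carries a single deterministic reason:
#' parseability, then presence of a perfluorinated unit, then total fluorine
#' count (>= `min_fluorines`), then deduplication on the structure key
#' (first occurrence in input order wins).
#'
#' @param entries Data frame with columns `source_id` and `smiles`
#'   (as returned by [parse_library()]), or a character vector of SMILES.
#' @param min_fluorines Minimum total fluorine count for inclusion.
#' @param perfluoro_smarts Pattern defining the perfluorinated unit.
#' @return A data frame of curated records with columns `source_id`,
#'   `smiles`, `canonical_smiles`, `structure_key`, `n_fluorine`,
#'   `has_perfluoro_unit`, `included`, `exclusion_reason`. The audit table of
#'   counts is attached as attribute `"audit"` and also available via
#'   [curation_audit()].
#' @examples
#' recs <- apply_inclusion_filters(c("OC(=O)C(F)(F)F", "CCCC", "OC(=O)C(F)(F)F"))
#' recs$exclusion_reason
#' @export
apply_inclusion_filters <- function(entries, min_fluorines = 3L,
                                    perfluoro_smarts = PERFLUORO_UNIT_SMARTS) {
  if (is.character(entries)) {
    entries <- data.frame(
      source_id = sprintf("ENTRY%04d", seq_along(entries)),
      smiles = entries, stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("source_id", "smiles") %in% names(entries)))
  n <- nrow(entries)
  if (n == 0L) {
    rec <- data.frame(
      source_id = character(0), smiles = character(0),
      canonical_smiles = character(0), structure_key = character(0),
      n_fluorine = integer(0), has_perfluoro_unit = logical(0),
      included = logical(0), exclusion_reason = character(0),
      stringsAsFactors = FALSE
    )
    attr(rec, "audit") <- curation_audit(rec)
    return(rec)
  }
  rec <- data.frame(
    source_id = as.character(entries$source_id),
    smiles = as.character(entries$smiles),
    canonical_smiles = NA_character_,
    structure_key = NA_character_,
    n_fluorine = NA_integer_,
    has_perfluoro_unit = NA,
    included = FALSE,
    exclusion_reason = "unparseable",
    stringsAsFactors = FALSE
  )
  mols <- ob_parse(rec$smiles)
  ok <- !vapply(mols, is.null, logical(1))
  if (any(ok)) {
    okmols <- mols[ok]
    rec$n_fluorine[ok] <- ob_smarts_count(okmols, "[#9]")
    rec$has_perfluoro_unit[ok] <- ob_smarts_matches(okmols, perfluoro_smarts)
    can <- ob_convert_batch(rec$smiles[ok], "CAN")
    if (is.null(can)) {
      can <- vapply(rec$smiles[ok], ob_canonical_smiles, character(1),
                    USE.NAMES = FALSE)
    }
    rec$canonical_smiles[ok] <- can
    rec$structure_key[ok] <- structure_key_from_canonical(can)
    rec$exclusion_reason[ok] <- ifelse(
      !rec$has_perfluoro_unit[ok], "no_perfluoro_unit",
      ifelse(rec$n_fluorine[ok] < min_fluorines, "too_few_fluorines", "none")
    )
  }
  rec <- deduplicate(rec)
  rec$included <- rec$exclusion_reason == "none"
  attr(rec, "audit") <- curation_audit(rec)
  rec
}

#' Flag duplicate structures, keeping the first occurrence
#'
#' Within each group of records sharing a structure key, only the first (in
#' input order) among those that passed the earlier filters keeps
#' `exclusion_reason = "none"`; the rest are marked `"duplicate"`.
#'
#' @param records Curated records (see [apply_inclusion_filters()]).
#' @return The records with duplicate flags set and `included` refreshed.
#' @export
deduplicate <- function(records) {
  eligible <- records$exclusion_reason %in% c("none", "duplicate")
  reason <- records$exclusion_reason
  reason[eligible] <- "none"
  idx <- which(eligible)
  if (length(idx) > 1L) {
    dup <- duplicated(records$structure_key[idx])
    reason[idx[dup]] <- "duplicate"
  }
  records$exclusion_reason <- reason
  records$included <- records$exclusion_reason == "none"
  records
}

#' Audit table for a curated library
#'
#' @param records Curated records.
#' @return Data frame with one row per exclusion reason (including
#'   `"none"`, i.e. the included chemicals) and the record count; counts sum
#'   to the library size.
#' @export
curation_audit <- function(records) {
  counts <- vapply(EXCLUSION_REASONS,
                   function(r) sum(records$exclusion_reason == r),
                   integer(1))
  data.frame(reason = EXCLUSION_REASONS, n = unname(counts),
             stringsAsFactors = FALSE)
}

#' Write a curated library (and optionally its audit table) to CSV
#'
#' @param records Curated records.
#' @param path Output CSV path.
#' @param audit_path Optional path for the audit CSV.
#' @return `path`, invisibly.
#' @export
write_curated <- function(records, path, audit_path = NULL) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  if (!is.null(audit_path)) {
    utils::write.csv(curation_audit(records), audit_path, row.names = FALSE)
  }
  invisible(path)
}
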