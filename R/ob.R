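# Thin wrappers around the OpenBabel bindings (ChemmineOB). All molecule
# handling in the package funnels through these so parse failures surface as
# NULL / NA rather than uncaught errors, and so every caller shares one
# definition of "parseable".

# Parse one SMILES string; NULL if empty, syntactically invalid, or not a
# single molecule record.
ob_parse_one <- function(smiles) {
  if (length(smiles) != 1L || is.na(smiles) || !nzchar(trimws(smiles))) {
    return(NULL)
  }
  mols <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL
  )
  if (is.null(mols) || length(mols) != 1L) return(NULL)
  mols[[1L]]
}

# Parse a vector of SMILES; list with NULL entries where parsing failed.
ob_parse <- function(smiles) {
  lapply(as.character(smiles), ob_parse_one)
}

# Count unique matches of a SMARTS pattern on already-parsed molecules.
# `mols` is a list of OBMol references (no NULLs).
ob_smarts_count <- function(mols, smarts) {
  if (length(mols) == 0L) return(integer(0))
  as.integer(ChemmineOB::smartsSearch_OB(mols, smarts))
}

ob_smarts_matches <- function(mols, smarts) {
  ob_smarts_count(mols, smarts) > 0L
}

# Canonical SMILES for one input SMILES; NA on failure.
ob_canonical_smiles <- function(smiles) {
  mol <- ob_parse_one(smiles)
  if (is.null(mol)) return(NA_character_)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", smiles)),
    error = function(e) ""
  )
  out <- strsplit(trimws(out), "[ \t\n]")[[1L]][1L]
  if (length(out) == 0L || is.na(out) || !nzchar(out)) NA_character_ else out
}

ob_inchikey <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "INCHIKEY", smiles)),
    error = function(e) ""
  )
  out <- trimws(out)
  if (!nzchar(out)) NA_character_ else out
}

ob_heavy_atom_count <- function(smiles) {
  mol <- ob_parse_one(smiles)
  if (is.null(mol)) return(NA_integer_)
  ob_smarts_count(list(mol), "[!#1]")
}

# Batched format conversion: one output line per input SMILES, titles
# stripped. Returns NULL when the line count does not match (a caller then
# falls back to per-molecule conversion).
ob_convert_batch <- function(smiles, to) {
  if (length(smiles) == 0L) return(character(0))
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", to, paste(smiles, collapse = "\n")
    )),
    error = function(e) NULL
  )
  if (is.null(out)) return(NULL)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1L]]
  if (length(lines) != length(smiles)) return(NULL)
  trimws(sub("\t.*$", "", lines))
}

# Largest fragment of an already-canonical SMILES (heavy-atom counts are
# only computed for the rare multi-component inputs).
largest_fragment_of <- function(canonical) {
  if (is.na(canonical) || !grepl(".", canonical, fixed = TRUE)) {
    return(canonical)
  }
  parts <- strsplit(canonical, ".", fixed = TRUE)[[1L]]
  sizes <- vapply(parts, ob_heavy_atom_count, integer(1), USE.NAMES = FALSE)
  sizes[is.na(sizes)] <- -1L
  parts[which.max(sizes)]
}

# Largest covalent fragment of a (possibly multi-component) SMILES, chosen
# by heavy-atom count with ties going to the first component of the
# canonical form. Salts and counterions are dropped before keying.
ob_largest_fragment <- function(smiles) {
  can <- ob_canonical_smiles(smiles)
  if (is.na(can)) return(NA_character_)
  parts <- strsplit(can, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) return(parts)
  sizes <- vapply(parts, ob_heavy_atom_count, integer(1), USE.NAMES = FALSE)
  sizes[is.na(sizes)] <- -1L
  parts[which.max(sizes)]
}
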