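#' Morgan (extended-connectivity) fingerprints for a library
#'
#' Computes circular substructure fingerprints of the given radius (radius 2
#' corresponds to ECFP4) and folds them to a fixed length. Identical
#' molecules always yield identical fingerprints; unparseable molecules are
#' skipped with a warning and listed in the `"skipped"` attribute.
#'
#' @param x Curated library data frame (included records) or character
#'   vector of SMILES, optionally named with identifiers.
#' @param radius Circular neighbourhood radius; `2` gives ECFP4.
#' @param n_bits Folded fingerprint length.
#' @return 0/1 integer matrix, one row per molecule, rownames set to the
#'   identifiers; attributes `radius` and `n_bits`.
#' @export
fingerprint_library <- function(x, radius = 2, n_bits = 2048) {
  stopifnot(radius %in% 0:5, n_bits >= 8)
  if (is.data.frame(x)) {
    keep <- if ("included" %in% names(x)) x$included else TRUE
    x <- x[keep, , drop = FALSE]
    smiles <- if ("canonical_smiles" %in% names(x)) x$canonical_smiles else x$smiles
    ids <- x$source_id
  } else {
    smiles <- as.character(x)
    ids <- if (!is.null(names(x))) names(x) else {
      sprintf("CHEM%04d", seq_along(x))
    }
  }
  mols <- ob_parse(smiles)
  bad <- vapply(mols, is.null, logical(1))
  skipped <- ids[bad]
  if (any(bad)) {
    warning("skipping ", sum(bad), " unparseable molecule(s): ",
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  mols <- mols[!bad]
  ids <- ids[!bad]
  if (length(mols) == 0L) stop("no parseable molecules to fingerprint")
  raw <- ChemmineOB::fingerprint_OB(mols, paste0("ECFP", 2 * radius))
  raw <- matrix(as.integer(raw != 0), nrow = length(mols))
  folded <- matrix(0L, nrow = nrow(raw), ncol = n_bits)
  for (j in seq_len(ncol(raw))) {
    k <- ((j - 1L) %% n_bits) + 1L
    folded[, k] <- as.integer(folded[, k] | raw[, j])
  }
  rownames(folded) <- ids
  attr(folded, "radius") <- radius
  attr(folded, "n_bits") <- n_bits
  structure(folded, skipped = skipped)
}

#' Tanimoto similarity of two binary fingerprints
#'
#' @param a,b 0/1 vectors of equal length.
#' @return `|a & b| / |a | b|`; defined as 1 when both are empty.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  a <- as.logical(a)
  b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Train a batch-mode Kohonen self-organizing map
#'
#' Batch training: each epoch assigns every observation to its best-matching
#' unit (BMU, minimal Euclidean distance to the codebook vector, ties broken
#' by row-major unit order), then replaces every codebook vector by the
#' Gaussian-neighbourhood-weighted mean of the assigned observations. The
#' neighbourhood radius (the Gaussian sigma, in grid units) decays linearly
#' from `max(rows, cols)/2` to 1 over the epochs. Codebooks are initialized
#' from a seeded uniform draw on `[0, 1]`, so training is fully
#' deterministic given the seed, and (for 0/1 data) independent of input
#' row order. The quantization error after every epoch is recorded in
#' `qe_history`.
#'
#' Binary fingerprints are embedded as 0/1 reals; the map lives in ordinary
#' Euclidean space.
#'
#' @param X Numeric matrix, one observation per row (e.g. the output of
#'   [fingerprint_library()]).
#' @param rows,cols Grid dimensions (each at least 2).
#' @param epochs Number of batch epochs (at least 1).
#' @param seed Integer seed for codebook initialization.
#' @return A `som_model`: list with `codebook` (units x features, row-major
#'   unit order), `grid` (unit, row, col), `rows`, `cols`, `topology`,
#'   `epochs`, `radius_init`, `radius_final`, `seed`, `qe_history`.
#' @export
train_som <- function(X, rows = 20, cols = 20, epochs = 50, seed = 1) {
  X <- as.matrix(X)
  if (rows < 2 || cols < 2) stop("grid must be at least 2x2")
  if (epochs < 1) stop("epochs must be >= 1")
  n <- nrow(X)
  m <- rows * cols
  if (n < m) {
    warning("fewer observations (", n, ") than map units (", m, ")")
  }
  grid <- data.frame(
    unit = seq_len(m),
    row = rep(seq_len(rows), each = cols),
    col = rep(seq_len(cols), times = rows)
  )
  grid_d2 <- as.matrix(stats::dist(grid[, c("row", "col")]))^2
  r0 <- max(rows, cols) / 2
  set.seed(seed)
  W <- matrix(stats::runif(m * ncol(X)), m, ncol(X))
  x2 <- rowSums(X^2)
  qe <- numeric(epochs)
  for (e in seq_len(epochs)) {
    sigma <- if (epochs == 1) 1 else r0 + (1 - r0) * (e - 1) / (epochs - 1)
    bmu <- bmu_index(X, W, x2)
    H <- exp(-grid_d2 / (2 * sigma^2))
    A <- matrix(0, n, m)
    A[cbind(seq_len(n), bmu)] <- 1
    S <- crossprod(A, X)
    cnt <- colSums(A)
    num <- H %*% S
    den <- as.vector(H %*% cnt)
    upd <- den > 1e-12
    W[upd, ] <- num[upd, , drop = FALSE] / den[upd]
    qe[e] <- mean(sqrt(pmax(min_dist2(X, W, x2), 0)))
  }
  structure(
    list(codebook = W, grid = grid, rows = rows, cols = cols,
         topology = "rectangular", epochs = epochs,
         radius_init = r0, radius_final = 1, seed = seed,
         qe_history = qe),
    class = "som_model"
  )
}

# Squared Euclidean distances to the nearest codebook vector.
min_dist2 <- function(X, W, x2 = rowSums(X^2)) {
  D2 <- outer(x2, rowSums(W^2), "+") - 2 * tcrossprod(X, W)
  apply(D2, 1, min)
}

# BMU indices (row-major unit order; ties to the first, i.e. lowest index).
bmu_index <- function(X, W, x2 = rowSums(X^2)) {
  D2 <- outer(x2, rowSums(W^2), "+") - 2 * tcrossprod(X, W)
  max.col(-D2, ties.method = "first")
}

#' @export
print.som_model <- function(x, ...) {
  cat("Batch self-organizing map:", x$rows, "x", x$cols, x$topology,
      "grid,", ncol(x$codebook), "features\n")
  cat("epochs:", x$epochs, " radius:", x$radius_init, "->",
      x$radius_final, " seed:", x$seed, "\n")
  cat("final quantization error:",
      format(x$qe_history[length(x$qe_history)], digits = 6), "\n")
  invisible(x)
}

#' Best-matching unit of one or more vectors
#'
#' Exhaustive argmin of Euclidean distance over all map units; ties are
#' broken toward the lower row-major unit index.
#'
#' @param model A [train_som()] model.
#' @param x Vector, or matrix with one query per row, of codebook width.
#' @return Data frame with columns `unit`, `row`, `col` (one row per query).
#' @export
best_matching_unit <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$codebook)) {
    stop("fingerprint length ", ncol(x), " does not match codebook width ",
         ncol(model$codebook))
  }
  u <- bmu_index(x, model$codebook)
  data.frame(unit = u, row = model$grid$row[u], col = model$grid$col[u])
}

#' Quantization error of a map on a data set
#'
#' @param model A [train_som()] model.
#' @param X Matrix of observations (codebook width).
#' @return Mean Euclidean distance from each observation to its BMU.
#' @export
quantization_error <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty input")
  if (ncol(X) != ncol(model$codebook)) stop("feature width mismatch")
  mean(sqrt(pmax(min_dist2(X, model$codebook), 0)))
}

#' Project activity calls onto a trained map
#'
#' Maps every fingerprinted chemical to its BMU and labels each unit with
#' the modal final call of the chemicals it received (one panel per
#' receptor). Label ties resolve to `"inactive"` as the conservative
#' default; units receiving no chemicals are reported with `NA` label and
#' `n = 0` (empty, not inactive).
#'
#' @param model A [train_som()] model.
#' @param fps Fingerprint matrix with chemical identifiers as rownames.
#' @param calls Activity calls ([triage_calls()]).
#' @param receptor Receptor whose panel to build.
#' @return Data frame with one row per unit: `row`, `col`, `n`, `label`.
#' @export
project_activity <- function(model, fps, calls, receptor) {
  cc <- calls[calls$receptor == receptor, , drop = FALSE]
  ids <- rownames(fps)
  j <- match(ids, cc$chemical_id)
  if (anyNA(j)) {
    stop("no ", receptor, " call for: ",
         paste(utils::head(ids[is.na(j)], 5), collapse = ", "))
  }
  label <- cc$final_call[j]
  unit <- best_matching_unit(model, fps)$unit
  out <- model$grid
  out$n <- 0L
  out$label <- NA_character_
  for (u in unique(unit)) {
    lab <- label[unit == u]
    counts <- sort(table(lab), decreasing = TRUE)
    top <- names(counts)[counts == counts[1]]
    out$label[u] <- if (length(top) > 1L) "inactive" else top
    out$n[u] <- length(lab)
  }
  out[, c("row", "col", "n", "label")]
}

#' Serialize / restore a SOM model as JSON
#'
#' @param model A [train_som()] model.
#' @param path Output (input) JSON path.
#' @return `path` invisibly; `read_som()` returns the model.
#' @export
write_som <- function(model, path) {
  # codebook entries as %.17g strings: doubles survive the text round-trip
  # bit-exactly, so BMU ties resolve identically after reload
  cb <- matrix(sprintf("%.17g", model$codebook), nrow(model$codebook))
  payload <- list(
    rows = model$rows, cols = model$cols, topology = model$topology,
    epochs = model$epochs, radius_init = model$radius_init,
    radius_final = model$radius_final, seed = model$seed,
    qe_history = model$qe_history, codebook = cb
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_som
#' @export
read_som <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$codebook <- matrix(as.numeric(p$codebook), nrow(p$codebook))
  grid <- data.frame(
    unit = seq_len(p$rows * p$cols),
    row = rep(seq_len(p$rows), each = p$cols),
    col = rep(seq_len(p$cols), times = p$rows)
  )
  structure(
    list(codebook = p$codebook, grid = grid, rows = p$rows, cols = p$cols,
         topology = p$topology, epochs = p$epochs,
         radius_init = p$radius_init, radius_final = p$radius_final,
         seed = p$seed, qe_history = p$qe_history),
    class = "som_model"
  )
}
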