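# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small synthetic library plus its curated records (seed fixed).
small_library <- function() {
  cached("small_library", function() {
    cfg <- synth_config(seed = 42L, n_chemicals = 80L,
                        decoy_fraction = 0.25)
    lib <- generate_pfas_library(cfg)
    rec <- suppressWarnings(apply_inclusion_filters(lib$entries))
    list(cfg = cfg, entries = lib$entries, truth = lib$truth, rec = rec)
  })
}

# Small planted score tables across all ten receptors.
small_scores <- function() {
  cached("small_scores", function() {
    cfg <- synth_config(seed = 42L, n_chemicals = 60L)
    st <- generate_score_tables(cfg, sprintf("CHEM%03d", 1:60))
    st$stats <- compute_reference_stats(st$references)
    st$ml <- generate_ml_labels(st$truth, ml_error_rate = 0, seed = 42L)
    st
  })
}

# Brute-force BMU oracle: naive double loop, independent of the package's
# vectorized distance path.
naive_bmu <- function(codebook, query) {
  best <- 1L
  best_d <- Inf
  for (u in seq_len(nrow(codebook))) {
    d <- 0
    for (j in seq_len(ncol(codebook))) {
      d <- d + (codebook[u, j] - query[j])^2
    }
    if (d < best_d) {
      best_d <- d
      best <- u
    }
  }
  best
}

# Three well-separated binary clusters with light bit noise.
clustered_fps <- function(n_per = 60, bits = 512, seed = 5) {
  set.seed(seed)
  proto <- matrix(stats::rbinom(3 * bits, 1, 0.5), 3, bits)
  X <- proto[rep(1:3, each = n_per), ]
  flip <- matrix(stats::rbinom(length(X), 1, 0.01), nrow(X))
  list(X = abs(X - flip), cluster = rep(1:3, each = n_per))
}

# Write a one-residue / one-atom-ligand complex at a chosen separation.
write_pair_complex <- function(res_element, res_name, lig_element, dist,
                               resname = "LEU") {
  path <- tempfile(fileext = ".pdb")
  generate_toy_complex(
    residues = list(list(
      chain = "A", resno = 1L, resname = resname,
      atoms = data.frame(name = res_name, element = res_element,
                         x = 0, y = 0, z = 0)
    )),
    ligand = list(atoms = data.frame(name = "L1", element = lig_element,
                                     x = dist, y = 0, z = 0)),
    path = path
  )
  path
}

# Materialize synthetic fixtures plus a pipeline config in a directory.
write_pipeline_fixture <- function(dir, seed = 3L, n = 100L,
                                   receptors = NR_RECEPTORS,
                                   with_ml = TRUE, som = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- synth_config(seed = seed, n_chemicals = n, decoy_fraction = 0.2,
                      receptors = receptors)
  lib <- generate_pfas_library(cfg)
  utils::write.csv(lib$entries, file.path(dir, "library.csv"),
                   row.names = FALSE)
  ids <- lib$truth$source_id[lib$truth$expect_included]
  st <- generate_score_tables(cfg, ids)
  write_scores(st$references, file.path(dir, "refs.csv"))
  write_scores(st$candidates, file.path(dir, "scores.csv"))
  lines <- c("library: library.csv", "id_col: source_id",
             "smiles_col: smiles", "references: refs.csv",
             "scores: scores.csv")
  if (with_ml) {
    write_ml(generate_ml_labels(st$truth, 0, seed = seed),
             file.path(dir, "ml.csv"))
    lines <- c(lines, "ml: ml.csv")
  }
  writeLines(utils::head(ids, 5), file.path(dir, "commercial.txt"))
  lines <- c(lines, "commercial: commercial.txt")
  if (som) {
    lines <- c(lines, "som:", "  rows: 5", "  cols: 5", "  epochs: 8",
               "  n_bits: 256", "  seed: 1")
  }
  writeLines(lines, file.path(dir, "run.yaml"))
  list(config = file.path(dir, "run.yaml"), truth = lib$truth,
       score_truth = st$truth)
}

read_bytes <- function(path) readBin(path, "raw", file.info(path)$size)
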