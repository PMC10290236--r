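# Shared fixtures (built once per test run) and small PDB-text builders.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_native <- function(seed = 3L) {
  cached(paste0("native", seed),
         make_native_complex(fixture_spec(n_residues_a = 14L,
                                          n_residues_b = 10L, seed = seed)))
}

small_features <- function(seed = 3L, config = feature_config()) {
  cached(paste0("feats", seed), {
    nat <- small_native(seed)
    featurize_complex(nat$chains$A, nat$chains$B, config)
  })
}

tiny_config <- function(seed = 2L, mode = "sequential") {
  model_config(d_model = 5L, n_heads = 2L, n_layers = 2L, d_k = 3L,
               d_v = 4L, d_inner = 6L, dropout = 0, seed = seed,
               exchange_mode = mode)
}

# Fixed-width PDB ATOM line (atom names of <= 3 characters).
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1.00, alt = " ", type = "ATOM  ",
                          element = substr(name, 1L, 1L)) {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resn, chain, resno, x, y, z, occ, 0, element)
}

# A minimal chain of alanines with well-separated, non-collinear backbones.
toy_pdb_text <- function(n = 3L, chain = "A", resn = rep("ALA", n),
                         x0 = 0, resno0 = 1L) {
  lines <- character(0)
  serial <- 1L
  for (i in seq_len(n)) {
    x <- x0 + 4 * (i - 1L)
    resno <- resno0 + i - 1L
    lines <- c(lines,
      pdb_atom_line(serial, "N", resn[i], chain, resno, x - 1.2, 0.2, 0),
      pdb_atom_line(serial + 1L, "CA", resn[i], chain, resno, x, 0, 0.3),
      pdb_atom_line(serial + 2L, "C", resn[i], chain, resno, x + 1.2, 0.4, 0),
      pdb_atom_line(serial + 3L, "CB", resn[i], chain, resno, x, 1.5, 1.0))
    serial <- serial + 4L
  }
  c(lines, "END")
}

# Manually built chain from CA positions (N/C offset so frames are valid).
chain_from_ca <- function(ca, chain_id = "A", aa = NULL) {
  n <- nrow(ca)
  aa <- aa %||% rep("ALA", n)
  residues <- lapply(seq_len(n), function(i) {
    bb <- rbind(N = ca[i, ] + c(-1.2, 0.2, 0),
                CA = ca[i, ],
                C = ca[i, ] + c(1.2, 0.2, 0.3))
    sc <- matrix(ca[i, ] + c(0, 1.5, 0.2), 1L, 3L,
                 dimnames = list("CB", NULL))
    if (aa[i] == "GLY") sc <- matrix(numeric(0), 0L, 3L)
    graphdock:::new_residue(aa[i], i - 1L, as.character(i), bb, sc)
  })
  graphdock:::chain_structure(chain_id, residues)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_rotation <- function() graphdock:::random_rotation()

random_scored_set <- function(n, seed, tie_prob = 0.3) {
  graphdock:::with_seed(seed, {
    score <- round(stats::runif(n), if (stats::runif(1) < tie_prob) 1L else 6L)
    data.frame(decoy_id = sprintf("d%03d", sample.int(n)),
               target_id = sample(c("t1", "t2"), n, replace = TRUE),
               score = score,
               label = stats::rbinom(n, 1L, 0.4))
  })
}
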