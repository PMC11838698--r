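# Programmatic fixtures shared across test files.

tiny_spec <- function(seed = 7L, ...) {
  synthetic_spec(n_drugs = 40L, n_targets = 16L, n_pairs = 400L,
                 seq_length = 40L, fp_bits = 64L, seed = seed, ...)
}

tiny_model <- function(feats, ...) {
  init_model(model_config(n_heads = 2L, d = 16L, drug_depth = 1L,
                          target_depth = 1L, seed = 3L, ...),
             n_bits = feats$n_bits, embed_dim = feats$embed_dim)
}

tiny_features <- function(ds = generate_synthetic(tiny_spec())) {
  rec <- dataset_records(ds)
  list(ds = ds, feats = assemble_features(rec$drugs, rec$targets))
}

# Minimal synthetic PDB: an alpha-carbon-only chain along the x axis plus a
# one-atom ligand at a controllable position. Purely synthetic coordinates.
write_test_pdb <- function(path, n_res = 10, lig_xyz = c(3, 2, 0),
                           spacing = 3.8) {
  resnames <- rep(c("ALA", "GLY", "SER", "LEU", "VAL"), length.out = n_res)
  lines <- character(0)
  for (i in seq_len(n_res)) {
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      i, resnames[i], i, (i - 1) * spacing, 0, 0))
  }
  lines <- c(lines, sprintf(
    "HETATM%5d  C1  LIG A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    n_res + 1L, 900L, lig_xyz[1], lig_xyz[2], lig_xyz[3]))
  # a water that must be ignored
  lines <- c(lines, sprintf(
    "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f  1.00  0.00           O",
    n_res + 2L, 901L, 0, 50, 0))
  writeLines(c(lines, "END"), path)
  path
}

# family-structured sequences for homology-split tests: `fam` families of
# near-identical members, <5% cross-family k-mer identity w.h.p.
family_sequences <- function(fam = 6, members = 3, len = 60, seed = 11) {
  set.seed(seed)
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  out <- character(0)
  for (f in seq_len(fam)) {
    base <- sample(aa, len, replace = TRUE)
    for (m in seq_len(members)) {
      s <- base
      s[sample(len, 1)] <- sample(aa, 1)   # one point substitution per member
      out[sprintf("F%02dM%d", f, m)] <- paste(s, collapse = "")
    }
  }
  out
}
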