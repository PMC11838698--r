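# Protein featurization: records, a pluggable per-residue embedding-provider
# registry, and a deterministic built-in "toy" provider.
#
# Real deployments plug a protein language model (SaProt / ProtBert / ESM2
# style) in through register_provider(); the package never bundles learned
# weights. The toy provider is a seeded fixed random projection of each
# residue's one-hot identity concatenated with its k-mer context window, so
# embeddings are context-sensitive but require no training.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y","X")

.providers <- new.env(parent = emptyenv())

#' Create a drug record
#'
#' Couples an identifier and SMILES with the frozen drug featurization
#' f(D): a Morgan fingerprint bit vector. A precomputed fingerprint (e.g. a
#' planted synthetic bit vector) may be supplied instead of being derived
#' from the SMILES.
#'
#' @param drug_id identifier (opaque string)
#' @param smiles SMILES string; may be the sentinel "*" when `fingerprint`
#'   is supplied directly
#' @param n_bits,radius fingerprint parameters (defaults 2048 / 2)
#' @param fingerprint optional precomputed 0/1 vector of length `n_bits`
#' @return an object of class `drug_record`
#' @export
drug_record <- function(drug_id, smiles, n_bits = 2048L, radius = 2L,
                        fingerprint = NULL) {
  if (is.null(fingerprint)) {
    fingerprint <- morgan_fingerprint(smiles, n_bits = n_bits, radius = radius)
  } else {
    fingerprint <- as.integer(fingerprint)
    if (length(fingerprint) != n_bits)
      stop_dti(sprintf("fingerprint length %d != n_bits %d",
                       length(fingerprint), n_bits), "dti_config_error")
    if (!all(fingerprint %in% c(0L, 1L)))
      stop_dti("fingerprint must be a 0/1 vector", "dti_config_error")
  }
  structure(list(drug_id = as.character(drug_id), smiles = smiles,
                 fingerprint = fingerprint, n_bits = as.integer(n_bits),
                 radius = as.integer(radius)),
            class = "drug_record")
}

#' Create a target (protein) record
#'
#' Sequences are uppercased and closed over the 20 canonical residues plus
#' 'X': any non-canonical letter maps to 'X'. Sequences longer than
#' `max_length` are truncated from the C-terminus with a warning. Structure
#' tokens, when given, are an opaque per-residue string of equal length
#' passed through to providers.
#'
#' @param target_id identifier
#' @param sequence amino-acid string
#' @param structure_tokens optional per-residue token string, same length
#' @param coordinates optional L x 3 matrix of representative-atom positions (Angstrom)
#' @param max_length truncation cap (default 2048 residues)
#' @return an object of class `target_record`
#' @export
target_record <- function(target_id, sequence, structure_tokens = NULL,
                          coordinates = NULL, max_length = 2048L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop_dti("sequence must be a non-empty string", "dti_input_error")
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  chars[!chars %in% AA_ALPHABET] <- "X"
  if (length(chars) > max_length) {
    warning(sprintf("target '%s': sequence truncated from %d to %d residues",
                    target_id, length(chars), max_length))
    chars <- chars[seq_len(max_length)]
    if (!is.null(structure_tokens))
      structure_tokens <- substr(structure_tokens, 1L, max_length)
    if (!is.null(coordinates)) coordinates <- coordinates[seq_len(max_length), , drop = FALSE]
  }
  sequence <- paste(chars, collapse = "")
  if (!is.null(structure_tokens) && nchar(structure_tokens) != nchar(sequence))
    stop_dti(sprintf("structure_tokens length %d != sequence length %d",
                     nchar(structure_tokens), nchar(sequence)), "dti_input_error")
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    if (nrow(coordinates) != nchar(sequence) || ncol(coordinates) != 3L)
      stop_dti("coordinates must be an L x 3 matrix", "dti_input_error")
  }
  structure(list(target_id = as.character(target_id), sequence = sequence,
                 structure_tokens = structure_tokens, coordinates = coordinates),
            class = "target_record")
}

#' Register a per-residue embedding provider
#'
#' A provider is a function `(sequence, structure_tokens) -> L x E matrix`.
#' Its reported embedding width is validated against a probe sequence on
#' first use. Registering an existing name is an error (see
#' [unregister_provider()]).
#'
#' @param name provider name
#' @param fn callable `(sequence, structure_tokens = NULL)` returning an
#'   L x E numeric matrix
#' @param embed_dim the width E the provider reports
#' @return the provider name, invisibly
#' @export
register_provider <- function(name, fn, embed_dim) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_dti("provider name must be a non-empty string", "dti_config_error")
  if (exists(name, envir = .providers, inherits = FALSE))
    stop_dti(sprintf("provider '%s' is already registered", name), "dti_config_error")
  if (!is.function(fn)) stop_dti("provider fn must be a function", "dti_config_error")
  if (!is_scalar_number(embed_dim) || embed_dim <= 0)
    stop_dti("embed_dim must be a positive integer", "dti_config_error")
  assign(name, list(fn = fn, embed_dim = as.integer(embed_dim), validated = FALSE),
         envir = .providers)
  invisible(name)
}

#' Remove a registered provider
#' @param name provider name
#' @export
unregister_provider <- function(name) {
  if (exists(name, envir = .providers, inherits = FALSE))
    rm(list = name, envir = .providers)
  invisible(name)
}

#' List registered embedding providers
#' @return character vector of provider names
#' @export
list_providers <- function() ls(envir = .providers)

get_provider <- function(name) {
  if (!exists(name, envir = .providers, inherits = FALSE))
    stop_dti(sprintf("unknown provider '%s'; registered providers: %s",
                     name, paste(list_providers(), collapse = ", ")),
             "dti_config_error")
  get(name, envir = .providers, inherits = FALSE)
}

validate_provider <- function(name) {
  p <- get_provider(name)
  if (p$validated) return(invisible(TRUE))
  probe <- "ACDEFGHIKL"
  out <- p$fn(probe, NULL)
  if (!is.matrix(out) || !is.numeric(out))
    stop_dti(sprintf("provider '%s' did not return a numeric matrix", name),
             "dti_provider_error")
  if (nrow(out) != nchar(probe))
    stop_dti(sprintf(
      "provider '%s' returned %d rows for a %d-residue probe sequence",
      name, nrow(out), nchar(probe)), "dti_provider_error")
  if (ncol(out) != p$embed_dim)
    stop_dti(sprintf("provider '%s' returned width %d, declared %d",
                     name, ncol(out), p$embed_dim), "dti_provider_error")
  p$validated <- TRUE
  assign(name, p, envir = .providers)
  invisible(TRUE)
}

#' Construct the built-in deterministic toy embedding provider
#'
#' Each residue's feature is the one-hot of its identity concatenated with
#' one-hots of every position in its k-mer context window (out-of-range
#' slots are zero). Features are mapped through a fixed random projection
#' drawn once from `seed`, so the same (seed, sequence) always yields a
#' bitwise-identical matrix. With k = 1 the embedding of a residue depends
#' only on its identity.
#'
#' @param embed_dim embedding width E (default 64)
#' @param k context window size, odd (default 3)
#' @param seed projection seed (default 0)
#' @return a provider function suitable for [register_provider()]
#' @export
make_toy_provider <- function(embed_dim = 64L, k = 3L, seed = 0L) {
  if (k %% 2 == 0) stop_dti("context window k must be odd", "dti_config_error")
  na <- length(AA_ALPHABET)
  nf <- na * (k + 1L)
  proj <- with_seed(seed, matrix(rnorm(nf * embed_dim, sd = 1 / sqrt(nf)),
                                 nrow = nf, ncol = embed_dim))
  half <- k %/% 2L
  function(sequence, structure_tokens = NULL) {
    chars <- strsplit(toupper(sequence), "")[[1]]
    chars[!chars %in% AA_ALPHABET] <- "X"
    L <- length(chars)
    code <- match(chars, AA_ALPHABET)
    feat <- matrix(0, nrow = L, ncol = nf)
    feat[cbind(seq_len(L), code)] <- 1
    for (s in seq_len(k)) {
      off <- s - 1L - half
      pos <- seq_len(L) + off
      ok <- pos >= 1L & pos <= L
      feat[cbind(which(ok), na * s + code[pos[ok]])] <- 1
    }
    feat %*% proj
  }
}

ensure_default_providers <- function() {
  if (!exists("toy", envir = .providers, inherits = FALSE))
    register_provider("toy", make_toy_provider(), embed_dim = 64L)
}

.onLoad <- function(libname, pkgname) {
  ensure_default_providers()
}

#' Compute per-residue embeddings for a target
#'
#' Applies a registered embedding provider to a target's sequence (and
#' structure tokens when present), producing the L x E matrix g(T) that the
#' attention-pooling layer consumes.
#'
#' @param target a [target_record()] or a plain sequence string
#' @param provider provider name (default "toy")
#' @return a `residue_embedding` object: the L x E matrix with attributes
#'   `target_id` and `provider_name`
#' @export
embed_residues <- function(target, provider = "toy") {
  ensure_default_providers()
  if (is.character(target)) target <- target_record("(unnamed)", target)
  if (!inherits(target, "target_record"))
    stop_dti("target must be a target_record or sequence string", "dti_input_error")
  if (!nzchar(target$sequence))
    stop_dti("cannot embed an empty sequence", "dti_input_error")
  validate_provider(provider)
  p <- get_provider(provider)
  values <- p$fn(target$sequence, target$structure_tokens)
  if (nrow(values) != nchar(target$sequence))
    stop_dti(sprintf("provider '%s' returned %d rows for %d residues",
                     provider, nrow(values), nchar(target$sequence)),
             "dti_provider_error")
  if (any(!is.finite(values)))
    stop_dti(sprintf("provider '%s' returned non-finite values", provider),
             "dti_provider_error")
  structure(values, target_id = target$target_id, provider_name = provider,
            class = c("residue_embedding", "matrix", "array"))
}

#' Persist residue-embedding matrices
#'
#' A named-array container keyed by target_id, so expensive featurizations
#' (e.g. from an external protein language model) can be computed once and
#' reloaded.
#'
#' @param embeddings list of `residue_embedding` matrices (see
#'   [embed_residues()])
#' @param path output file path
#' @export
write_residue_embeddings <- function(embeddings, path) {
  ids <- vapply(embeddings, function(e) attr(e, "target_id"), "")
  if (anyDuplicated(ids))
    stop_dti("duplicate target ids in embedding list", "dti_input_error")
  arrays <- lapply(embeddings, function(e)
    list(values = unclass(e), provider_name = attr(e, "provider_name")))
  names(arrays) <- ids
  saveRDS(list(format = "dtiscreen_residue_embeddings", format_version = 1L,
               arrays = arrays), path, version = 2)
  invisible(path)
}

#' Read residue embeddings written by [write_residue_embeddings()]
#' @param path input file path
#' @return named list of `residue_embedding` matrices keyed by target_id
#' @export
read_residue_embeddings <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop_dti(sprintf("cannot read embeddings '%s': %s", path,
                     conditionMessage(e)), "dti_integrity_error"))
  if (!identical(obj$format, "dtiscreen_residue_embeddings"))
    stop_dti(sprintf("'%s' is not a residue-embedding store", path),
             "dti_integrity_error")
  out <- lapply(names(obj$arrays), function(id)
    structure(obj$arrays[[id]]$values, target_id = id,
              provider_name = obj$arrays[[id]]$provider_name,
              class = c("residue_embedding", "matrix", "array")))
  names(out) <- names(obj$arrays)
  out
}
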