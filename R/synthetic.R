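# Download-free synthetic datasets with the statistical structure the
# co-embedding model assumes: drug and target latent vectors on a shared
# sphere drive the labels (Bernoulli of sigma(alpha* . cos) or noisy dot
# products), drug observables are binarized noisy linear readouts of the
# drug latent (fingerprint-like bit vectors), and each target's sequence
# carries its archetype's signature motif at a recorded position, so a
# context-sensitive encoder plus attention pooling can recover the archetype
# and attention should localize on the motif.

#' Synthetic dataset specification
#'
#' Defaults describe the package's reference world: 500 drugs, 200 targets
#' drawn from K = 8 orthonormal latent archetypes (jitter 0.05) in an
#' 8-dimensional latent space, 20000 labelled pairs with generative scale
#' alpha* = 10, 256-bit fingerprints with pre-binarization noise sd 0.25,
#' length-100 sequences with a 6-residue signature motif.
#'
#' @param n_drugs,n_targets entity counts
#' @param latent_dim latent width d*
#' @param alpha_star generative scale applied to the cosine in bernoulli mode
#' @param n_archetypes number of target archetypes K (K <= latent_dim)
#' @param motif_length signature motif length m
#' @param seq_length target sequence length L (> motif_length)
#' @param n_pairs number of labelled drug-target pairs
#' @param label_mode "bernoulli" (binary Y) or "affinity" (continuous pK)
#' @param noise_sd affinity-mode Gaussian noise sd (default 0.1)
#' @param fp_bits fingerprint readout width (default 256)
#' @param fp_noise_sd pre-binarization readout noise sd (default 0.25)
#' @param archetype_jitter sd of the jitter around a target's archetype latent
#' @param emit_smiles if TRUE drugs also get simple real SMILES strings (for
#'   exercising [morgan_fingerprint()] end-to-end); planted fingerprints are
#'   used for modelling either way
#' @param seed master seed; all randomness flows from it via named substreams
#' @return an object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_drugs = 500L, n_targets = 200L, latent_dim = 8L,
                           alpha_star = 10, n_archetypes = 8L,
                           motif_length = 6L, seq_length = 100L,
                           n_pairs = 20000L,
                           label_mode = c("bernoulli", "affinity"),
                           noise_sd = 0.1, fp_bits = 256L, fp_noise_sd = 0.25,
                           archetype_jitter = 0.05, emit_smiles = FALSE,
                           seed = 0L) {
  label_mode <- match.arg(label_mode)
  if (any(c(n_drugs, n_targets, latent_dim, n_archetypes, motif_length,
            seq_length, n_pairs, fp_bits) < 1))
    stop_dti("all counts must be positive", "dti_config_error")
  if (motif_length >= seq_length)
    stop_dti("motif_length must be smaller than seq_length", "dti_config_error")
  if (n_archetypes > latent_dim)
    stop_dti("n_archetypes must not exceed latent_dim (archetypes are orthonormal)",
             "dti_config_error")
  if (n_archetypes > 20^motif_length)
    stop_dti("more archetypes than distinct signature motifs", "dti_config_error")
  structure(list(n_drugs = as.integer(n_drugs), n_targets = as.integer(n_targets),
                 latent_dim = as.integer(latent_dim), alpha_star = alpha_star,
                 n_archetypes = as.integer(n_archetypes),
                 motif_length = as.integer(motif_length),
                 seq_length = as.integer(seq_length), n_pairs = as.integer(n_pairs),
                 label_mode = label_mode, noise_sd = noise_sd,
                 fp_bits = as.integer(fp_bits), fp_noise_sd = fp_noise_sd,
                 archetype_jitter = archetype_jitter,
                 emit_smiles = isTRUE(emit_smiles), seed = as.integer(seed)),
            class = "synthetic_spec")
}

AA20 <- AA_ALPHABET[1:20]

unit_rows <- function(m) m / sqrt(rowSums(m^2))

synth_target_batch <- function(spec, truth, n, ids, seed_stream) {
  with_seed(seed_stream, {
    arch_of <- sample.int(spec$n_archetypes, n, replace = TRUE)
    lat <- truth$archetypes[arch_of, , drop = FALSE] +
      spec$archetype_jitter * matrix(rnorm(n * spec$latent_dim), n)
    lat <- unit_rows(lat)
    motif_pos <- sample.int(spec$seq_length - spec$motif_length + 1L, n,
                            replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      chars <- sample(AA20, spec$seq_length, replace = TRUE)
      chars[motif_pos[i]:(motif_pos[i] + spec$motif_length - 1L)] <-
        strsplit(truth$signatures[arch_of[i]], "")[[1]]
      paste(chars, collapse = "")
    }, "")
    list(ids = ids, sequences = seqs, latents = lat, archetype = arch_of,
         motif_pos = motif_pos)
  })
}

#' Generate a synthetic DTI dataset
#'
#' @param spec a [synthetic_spec()]
#' @return an object of class `synthetic_dataset`: `drugs` (ids, smiles,
#'   fingerprint matrix), `targets` (ids, sequences), `interactions`
#'   (drug_id, target_id, label or pK, source), `truth` (latents, archetypes,
#'   signature motifs, motif positions) and the spec itself
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- list()
  truth$archetypes <- with_seed(derive_seed(spec$seed, "archetypes"), {
    t(qr.Q(qr(matrix(rnorm(spec$latent_dim^2), spec$latent_dim)))[
      , seq_len(spec$n_archetypes), drop = FALSE])
  })
  truth$signatures <- with_seed(derive_seed(spec$seed, "signatures"), {
    sigs <- character(0)
    while (length(sigs) < spec$n_archetypes) {
      cand <- paste(sample(AA20, spec$motif_length, replace = TRUE), collapse = "")
      if (!cand %in% sigs) sigs <- c(sigs, cand)
    }
    sigs
  })

  drug_ids <- sprintf("D%04d", seq_len(spec$n_drugs))
  dr <- with_seed(derive_seed(spec$seed, "drugs"), {
    lat <- unit_rows(matrix(rnorm(spec$n_drugs * spec$latent_dim), spec$n_drugs))
    A <- matrix(rnorm(spec$fp_bits * spec$latent_dim), spec$fp_bits)
    readout <- lat %*% t(A) +
      spec$fp_noise_sd * matrix(rnorm(spec$n_drugs * spec$fp_bits), spec$n_drugs)
    fp <- (readout > 0) * 1L
    smiles <- if (spec$emit_smiles) {
      frags <- c("C", "CC", "CCO", "CCN", "CCC", "C(=O)O", "c1ccccc1", "CO")
      vapply(seq_len(spec$n_drugs), function(i)
        paste(sample(frags, 3, replace = TRUE), collapse = ""), "")
    } else rep("*", spec$n_drugs)
    list(lat = lat, fp = fp, smiles = smiles, readout_matrix = A)
  })
  rownames(dr$fp) <- drug_ids

  target_ids <- sprintf("T%04d", seq_len(spec$n_targets))
  tg <- synth_target_batch(spec, truth, spec$n_targets, target_ids,
                           derive_seed(spec$seed, "targets"))

  inter <- with_seed(derive_seed(spec$seed, "labels"), {
    n_univ <- spec$n_drugs * spec$n_targets
    n_pairs <- min(spec$n_pairs, n_univ)
    lin <- sample.int(n_univ, n_pairs)
    di <- (lin - 1L) %/% spec$n_targets + 1L
    ti <- (lin - 1L) %% spec$n_targets + 1L
    cosv <- rowSums(dr$lat[di, , drop = FALSE] * tg$latents[ti, , drop = FALSE])
    if (spec$label_mode == "bernoulli") {
      p <- plogis(spec$alpha_star * cosv)
      data.frame(drug_id = drug_ids[di], target_id = target_ids[ti],
                 label = rbinom(n_pairs, 1, p), source = "measured",
                 planted_cos = cosv, stringsAsFactors = FALSE)
    } else {
      pk <- cosv + rnorm(n_pairs, sd = spec$noise_sd)
      data.frame(drug_id = drug_ids[di], target_id = target_ids[ti],
                 pK = pk, source = "measured", planted_cos = cosv,
                 stringsAsFactors = FALSE)
    }
  })

  truth$drug_latents <- dr$lat
  truth$target_latents <- tg$latents
  truth$target_archetype <- tg$archetype
  truth$motif_pos <- tg$motif_pos

  structure(list(
    spec = spec,
    drugs = list(ids = drug_ids, smiles = dr$smiles, fingerprints = dr$fp),
    targets = list(ids = target_ids, sequences = tg$sequences),
    interactions = inter,
    truth = truth
  ), class = "synthetic_dataset")
}

#' Generate additional held-out targets from an existing synthetic world
#'
#' Draws fresh targets from the same archetypes and signature motifs as the
#' dataset, for held-out evaluation (e.g. the attention-localization check).
#'
#' @param dataset a `synthetic_dataset`
#' @param n number of new targets
#' @param seed RNG seed
#' @return list with `ids`, `sequences`, `latents`, `archetype`, `motif_pos`
#' @export
generate_heldout_targets <- function(dataset, n, seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  ids <- sprintf("H%04d", seq_len(n))
  synth_target_batch(dataset$spec, dataset$truth, n, ids,
                     derive_seed(seed, "heldout_targets"))
}

#' Convert a synthetic dataset to model-ready records
#'
#' @param dataset a `synthetic_dataset`
#' @return list of `drugs` ([drug_record()]s) and `targets`
#'   ([target_record()]s)
#' @export
dataset_records <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  drugs <- lapply(seq_along(dataset$drugs$ids), function(i)
    drug_record(dataset$drugs$ids[i], dataset$drugs$smiles[i],
                n_bits = ncol(dataset$drugs$fingerprints),
                fingerprint = dataset$drugs$fingerprints[i, ]))
  targets <- lapply(seq_along(dataset$targets$ids), function(i)
    target_record(dataset$targets$ids[i], dataset$targets$sequences[i]))
  list(drugs = drugs, targets = targets)
}

fmt_num <- function(x) sprintf("%.17g", x)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic dataset to a directory
#'
#' Emits plain-text files: `drugs.tsv` (drug_id, smiles -- synthetic drugs
#' carry the sentinel "*"), `fingerprints.tsv` (drug_id + 0/1 bit string,
#' flagged synthetic), `targets.fasta`, `interactions.tsv`, a `spec.txt`
#' key-value config, and a `truth/` sidecar with latents (full 17-digit
#' precision, so the round trip is exact), archetypes, signatures and motif
#' positions.
#'
#' @param dataset a `synthetic_dataset`
#' @param dir output directory
#' @param overwrite allow writing into an existing non-empty directory
#' @return `dir`, invisibly
#' @export
write_dataset <- function(dataset, dir, overwrite = FALSE) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (dir.exists(dir) && length(dir(dir)) && !overwrite)
    stop_dti(sprintf("directory '%s' is not empty (use overwrite = TRUE)", dir),
             "dti_io_error")
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)

  write_tsv(data.frame(drug_id = dataset$drugs$ids, smiles = dataset$drugs$smiles,
                       synthetic = TRUE), file.path(dir, "drugs.tsv"))
  write_tsv(data.frame(drug_id = dataset$drugs$ids,
                       fingerprint = apply(dataset$drugs$fingerprints, 1L,
                                           paste, collapse = "")),
            file.path(dir, "fingerprints.tsv"))
  writeLines(as.vector(rbind(paste0(">", dataset$targets$ids),
                             dataset$targets$sequences)),
             file.path(dir, "targets.fasta"))
  inter <- dataset$interactions
  inter$planted_cos <- fmt_num(inter$planted_cos)
  if ("pK" %in% names(inter)) inter$pK <- fmt_num(inter$pK)
  write_tsv(inter, file.path(dir, "interactions.tsv"))
  write_config(unclass(dataset$spec), file.path(dir, "spec.txt"))

  lat <- function(m) as.data.frame(apply(m, 2L, fmt_num))
  write_tsv(cbind(data.frame(drug_id = dataset$drugs$ids),
                  lat(dataset$truth$drug_latents)),
            file.path(dir, "truth", "drug_latents.tsv"))
  write_tsv(cbind(data.frame(target_id = dataset$targets$ids),
                  lat(dataset$truth$target_latents)),
            file.path(dir, "truth", "target_latents.tsv"))
  write_tsv(cbind(data.frame(archetype = seq_len(nrow(dataset$truth$archetypes)),
                             signature = dataset$truth$signatures),
                  lat(dataset$truth$archetypes)),
            file.path(dir, "truth", "archetypes.tsv"))
  write_tsv(data.frame(target_id = dataset$targets$ids,
                       archetype = dataset$truth$target_archetype,
                       motif_pos = dataset$truth$motif_pos),
            file.path(dir, "truth", "targets_meta.tsv"))
  invisible(dir)
}

read_tsv <- function(path) utils::read.table(path, sep = "\t", header = TRUE,
                                             stringsAsFactors = FALSE,
                                             colClasses = NA)

#' Read a dataset written by [write_dataset()]
#' @param dir dataset directory
#' @return a `synthetic_dataset`
#' @export
read_dataset <- function(dir) {
  spec_kv <- read_config(file.path(dir, "spec.txt"))
  spec <- synthetic_spec(
    n_drugs = as.integer(spec_kv$n_drugs), n_targets = as.integer(spec_kv$n_targets),
    latent_dim = as.integer(spec_kv$latent_dim),
    alpha_star = as.numeric(spec_kv$alpha_star),
    n_archetypes = as.integer(spec_kv$n_archetypes),
    motif_length = as.integer(spec_kv$motif_length),
    seq_length = as.integer(spec_kv$seq_length),
    n_pairs = as.integer(spec_kv$n_pairs), label_mode = spec_kv$label_mode,
    noise_sd = as.numeric(spec_kv$noise_sd), fp_bits = as.integer(spec_kv$fp_bits),
    fp_noise_sd = as.numeric(spec_kv$fp_noise_sd),
    archetype_jitter = as.numeric(spec_kv$archetype_jitter),
    emit_smiles = as.logical(spec_kv$emit_smiles), seed = as.integer(spec_kv$seed))

  drugs_df <- read_tsv(file.path(dir, "drugs.tsv"))
  fps <- utils::read.table(file.path(dir, "fingerprints.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  fp <- do.call(rbind, lapply(strsplit(as.character(fps$fingerprint), ""),
                              as.integer))
  rownames(fp) <- fps$drug_id
  fasta <- readLines(file.path(dir, "targets.fasta"))
  hdr <- grepl("^>", fasta)
  target_ids <- sub("^>", "", fasta[hdr])
  seqs <- fasta[!hdr]
  inter <- read_tsv(file.path(dir, "interactions.tsv"))
  inter$planted_cos <- as.numeric(inter$planted_cos)
  if ("pK" %in% names(inter)) inter$pK <- as.numeric(inter$pK)

  num_mat <- function(df, drop_cols) {
    m <- as.matrix(df[, setdiff(names(df), drop_cols), drop = FALSE])
    matrix(as.numeric(m), nrow = nrow(m))
  }
  dl <- read_tsv(file.path(dir, "truth", "drug_latents.tsv"))
  tl <- read_tsv(file.path(dir, "truth", "target_latents.tsv"))
  ar <- read_tsv(file.path(dir, "truth", "archetypes.tsv"))
  meta <- read_tsv(file.path(dir, "truth", "targets_meta.tsv"))

  truth <- list(archetypes = num_mat(ar, c("archetype", "signature")),
                signatures = as.character(ar$signature),
                drug_latents = num_mat(dl, "drug_id"),
                target_latents = num_mat(tl, "target_id"),
                target_archetype = meta$archetype, motif_pos = meta$motif_pos)

  structure(list(spec = spec,
                 drugs = list(ids = as.character(drugs_df$drug_id),
                              smiles = as.character(drugs_df$smiles),
                              fingerprints = fp),
                 targets = list(ids = target_ids, sequences = seqs),
                 interactions = inter, truth = truth),
            class = "synthetic_dataset")
}
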