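# Interpretability pipeline: identify ligand-binding residues from a bound
# structure by a heavy-atom distance criterion, compare per-head attention on
# binding vs non-binding residues, and export per-residue attention onto a
# PDB temperature-factor column for viewer coloring.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")

#' Read a single-chain protein-ligand PDB structure
#'
#' Minimal fixed-column reader: protein residues from ATOM records of one
#' chain, the ligand from non-water HETATM records. Hydrogens are dropped;
#' author residue numbering is preserved in the mapping table and residues
#' are indexed 0-based in file order.
#'
#' @param path PDB file
#' @param chain chain identifier; default: the first protein chain seen
#' @param target_id identifier for the structure (default: file name)
#' @return an object of class `bound_structure`
#' @export
read_pdb_structure <- function(path, chain = NULL, target_id = NULL) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  atom <- trimws(rec) %in% c("ATOM", "HETATM")
  lines <- lines[atom]
  if (!length(lines)) stop_dti(sprintf("no atoms in '%s'", path), "dti_io_error")
  f <- function(a, b) trimws(substr(lines, a, b))
  tab <- data.frame(
    record = trimws(substr(lines, 1, 6)),
    name = f(13, 16), altloc = f(17, 17), resname = f(18, 20),
    chain = f(22, 22), resseq = as.integer(f(23, 26)), icode = f(27, 27),
    x = as.numeric(f(31, 38)), y = as.numeric(f(39, 46)), z = as.numeric(f(47, 54)),
    element = f(77, 78), stringsAsFactors = FALSE)
  tab$element[tab$element == ""] <- substr(gsub("[0-9]", "", tab$name), 1, 1)[tab$element == ""]
  tab <- tab[tab$element != "H" & tab$resname != "HOH", ]
  tab <- tab[tab$altloc %in% c("", "A"), ]
  if (any(!is.finite(tab$x) | !is.finite(tab$y) | !is.finite(tab$z)))
    stop_dti(sprintf("non-finite coordinates in '%s'", path), "dti_io_error")

  prot <- tab[tab$record == "ATOM" & tab$resname %in% names(AA3TO1), ]
  if (!nrow(prot)) stop_dti(sprintf("no protein residues in '%s'", path), "dti_io_error")
  chain <- chain %||% prot$chain[1L]
  prot <- prot[prot$chain == chain, ]
  lig <- tab[tab$record == "HETATM", ]

  key <- paste(prot$resseq, prot$icode)
  res_keys <- unique(key)
  res_index <- match(key, res_keys) - 1L          # 0-based residue index
  first <- !duplicated(key)
  mapping <- data.frame(index0 = seq_along(res_keys) - 1L,
                        resseq = prot$resseq[first], icode = prot$icode[first],
                        resname = prot$resname[first], stringsAsFactors = FALSE)
  sequence <- paste(AA3TO1[mapping$resname], collapse = "")
  structure(list(target_id = target_id %||% basename(path), chain = chain,
                 sequence = sequence, mapping = mapping,
                 protein_atoms = cbind(prot[, c("x", "y", "z")], index0 = res_index,
                                       name = prot$name, resname = prot$resname),
                 ligand_atoms = lig[, c("x", "y", "z", "name", "resname")]),
            class = "bound_structure")
}

#' Ligand-binding residues by heavy-atom distance
#'
#' A residue binds if any of its heavy atoms lies within `cutoff` Angstrom of
#' any ligand heavy atom (standard contact criterion; monotone in the cutoff).
#'
#' @param structure a `bound_structure`
#' @param cutoff distance cutoff in Angstrom (default 4.5)
#' @return sorted 0-based residue index vector
#' @export
binding_residues <- function(structure, cutoff = 4.5) {
  stopifnot(inherits(structure, "bound_structure"))
  if (!is_scalar_number(cutoff) || cutoff <= 0)
    stop_dti("cutoff must be a positive distance", "dti_config_error")
  lig <- as.matrix(structure$ligand_atoms[, c("x", "y", "z")])
  if (!nrow(lig)) stop_dti("structure has no ligand heavy atoms", "dti_input_error")
  pa <- as.matrix(structure$protein_atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(pa^2), rowSums(lig^2), "+") - 2 * pa %*% t(lig)
  close_atom <- apply(d2 <= cutoff^2 + 1e-9, 1L, any)
  sort(unique(structure$protein_atoms$index0[close_atom]))
}

#' Attention enrichment on binding vs non-binding residues
#'
#' Per head, the arithmetic mean attention weight over the binding set and
#' over its complement, and their ratio (an all-background head with zero
#' binding mass gives ratio 0; a head with zero non-binding mass reports the
#' `Inf` sentinel).
#'
#' @param attention H x L attention matrix (rows sum to 1), e.g. from
#'   [attention_pool()]
#' @param binding 0-based residue indices; must be a non-empty proper subset
#' @return an `enrichment_report`: data.frame with `head`, `binding_mean`,
#'   `nonbinding_mean`, `ratio`, plus attributes `binding_mass` per head
#' @export
attention_enrichment <- function(attention, binding) {
  A <- as.matrix(attention)
  L <- ncol(A)
  binding <- sort(unique(as.integer(binding)))
  if (length(binding) == 0L || length(binding) >= L)
    stop_dti("binding set must be a non-empty proper subset of residues",
             "dti_input_error")
  if (any(binding < 0L) || any(binding >= L))
    stop_dti(sprintf("binding indices must lie in [0, %d)", L), "dti_input_error")
  bcols <- binding + 1L
  bm <- rowMeans(A[, bcols, drop = FALSE])
  nm <- rowMeans(A[, -bcols, drop = FALSE])
  ratio <- ifelse(nm == 0, Inf, bm / nm)
  rep_df <- data.frame(head = seq_len(nrow(A)), binding_mean = bm,
                       nonbinding_mean = nm, ratio = ratio)
  attr(rep_df, "binding_mass") <- rowSums(A[, bcols, drop = FALSE])
  attr(rep_df, "n_binding") <- length(binding)
  attr(rep_df, "n_residues") <- L
  class(rep_df) <- c("enrichment_report", "data.frame")
  rep_df
}

#' Write a structure with attention in the temperature-factor column
#'
#' Per-residue attention of the chosen head is min-max rescaled to 0-100 and
#' written into the B-factor field of every protein atom (ligand atoms carry
#' 0), so standard viewers can color by attention.
#'
#' @param structure a `bound_structure`
#' @param attention H x L attention matrix; L must equal the residue count
#' @param head 1-based head index
#' @param path output PDB path
#' @return `path`, invisibly
#' @export
export_attention_structure <- function(structure, attention, head, path) {
  stopifnot(inherits(structure, "bound_structure"))
  A <- as.matrix(attention)
  if (head < 1L || head > nrow(A))
    stop_dti(sprintf("head %d out of range 1..%d", head, nrow(A)), "dti_config_error")
  L <- nchar(structure$sequence)
  if (ncol(A) != L)
    stop_dti(sprintf("attention has %d residues, structure has %d", ncol(A), L),
             "dti_input_error")
  w <- A[head, ]
  rng <- range(w)
  b <- if (diff(rng) == 0) rep(50, L) else 100 * (w - rng[1]) / diff(rng)
  pa <- structure$protein_atoms
  lines <- character(nrow(pa) + nrow(structure$ligand_atoms))
  n <- 0L
  for (i in seq_len(nrow(pa))) {
    n <- n + 1L
    m <- structure$mapping[pa$index0[i] + 1L, ]
    lines[n] <- sprintf("ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
                        n, substr(pa$name[i], 1, 4), m$resname, structure$chain,
                        m$resseq, ifelse(m$icode == "", " ", m$icode),
                        pa$x[i], pa$y[i], pa$z[i], 1.0, b[pa$index0[i] + 1L])
  }
  la <- structure$ligand_atoms
  for (i in seq_len(nrow(la))) {
    n <- n + 1L
    lines[n] <- sprintf("HETATM%5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
                        n, substr(la$name[i], 1, 4), substr(la$resname[i], 1, 3),
                        structure$chain, 9999L, " ",
                        la$x[i], la$y[i], la$z[i], 1.0, 0)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Mean motif-vs-background attention ratio on synthetic targets
#'
#' The controlled analogue of comparing attention on binding vs non-binding
#' residues: for each target, each head's mean attention on the planted motif
#' window is divided by its mean attention elsewhere, and ratios are averaged
#' over heads and targets.
#'
#' @param model a trained `dti_model`
#' @param sequences character vector of target sequences
#' @param motif_pos 1-based motif start positions, parallel to `sequences`
#' @param motif_length motif length
#' @param provider embedding provider name
#' @return list with `mean_ratio` and the per-target data.frame `per_target`
#' @export
motif_attention_ratio <- function(model, sequences, motif_pos, motif_length,
                                  provider = "toy") {
  stopifnot(length(sequences) == length(motif_pos))
  ratios <- numeric(length(sequences))
  for (i in seq_along(sequences)) {
    emb <- embed_residues(target_record(sprintf("t%d", i), sequences[i]),
                          provider = provider)
    att <- attention_pool(emb, model)$attention
    binding <- (motif_pos[i] - 1L):(motif_pos[i] + motif_length - 2L)
    er <- attention_enrichment(att, binding)
    ratios[i] <- mean(er$ratio)
  }
  list(mean_ratio = mean(ratios),
       per_target = data.frame(target = seq_along(sequences), ratio = ratios))
}
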