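# External-format I/O: .smi drug lists and delimited drug tables, FASTA
# targets (via Biostrings), interaction TSVs, plain-text key-value configs,
# embedding stores and scored-screen TSVs.

#' Read drugs from a .smi file or a delimited table
#'
#' `.smi`: one SMILES per line, optionally followed by whitespace and an id
#' (ids default to `drug_<line>`). Any other extension is read as a
#' tab-separated table that must carry `smiles` and `drug_id` columns.
#'
#' @param path input file
#' @return data.frame with `drug_id`, `smiles`
#' @export
read_drugs <- function(path) {
  if (!file.exists(path)) stop_dti(sprintf("no such file: '%s'", path), "dti_io_error")
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "[ \t]+")
    data.frame(
      drug_id = vapply(seq_along(parts), function(i)
        if (length(parts[[i]]) > 1L) parts[[i]][2L] else sprintf("drug_%d", i), ""),
      smiles = vapply(parts, `[[`, "", 1L),
      stringsAsFactors = FALSE)
  } else {
    tab <- read_tsv(path)
    need <- c("drug_id", "smiles")
    if (!all(need %in% names(tab)))
      stop_dti(sprintf("'%s' must have columns: %s", path,
                       paste(need, collapse = ", ")), "dti_io_error")
    tab[, need]
  }
}

#' Read targets from a FASTA file
#'
#' Record ids become target ids; sequences are sanitized through
#' [target_record()] (non-canonical residues map to 'X').
#'
#' @param path FASTA file
#' @param max_length truncation cap passed to [target_record()]
#' @return list of [target_record()] objects
#' @export
read_fasta_targets <- function(path, max_length = 2048L) {
  if (!file.exists(path)) stop_dti(sprintf("no such file: '%s'", path), "dti_io_error")
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop_dti(sprintf("no FASTA records in '%s'", path), "dti_io_error")
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, "", 1L)
  lapply(seq_along(set), function(i)
    target_record(ids[i], as.character(set[[i]]), max_length = max_length))
}

#' Read an interaction table
#'
#' Tab-separated with header `drug_id target_id label` (0/1), `drug_id
#' target_id pK`, or `drug_id target_id kd` (converted through
#' [label_from_kd()]).
#'
#' @param path TSV file
#' @param kd_threshold threshold used when a `kd` column is present
#' @return data.frame with `drug_id`, `target_id` and `label` or `pK`
#' @export
read_interactions <- function(path, kd_threshold = 30) {
  tab <- read_tsv(path)
  if (!all(c("drug_id", "target_id") %in% names(tab)))
    stop_dti(sprintf("'%s' must have drug_id and target_id columns", path),
             "dti_io_error")
  if ("kd" %in% names(tab) && !"label" %in% names(tab)) {
    tab$label <- label_from_kd(tab$kd, kd_threshold)
  }
  if (!any(c("label", "pK") %in% names(tab)))
    stop_dti(sprintf("'%s' needs a label, pK or kd column", path), "dti_io_error")
  tab$drug_id <- as.character(tab$drug_id)
  tab$target_id <- as.character(tab$target_id)
  tab
}

#' Write an interaction table
#' @param interactions data.frame with `drug_id`, `target_id`, `label`/`pK`
#' @param path output TSV path
#' @export
write_interactions <- function(interactions, path) {
  write_tsv(interactions, path)
  invisible(path)
}

#' Write a plain-text key = value config file
#' @param config named list of scalar values
#' @param path output path
#' @export
write_config <- function(config, path) {
  keys <- names(config)
  vals <- vapply(config, function(v) {
    if (is.numeric(v)) fmt_num(v) else as.character(v)
  }, "")
  writeLines(paste(keys, vals, sep = " = "), path)
  invisible(path)
}

#' Read a key = value config file written by [write_config()]
#' @param path input path
#' @return named list of character values (caller coerces types)
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_dti(sprintf("no such file: '%s'", path), "dti_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  out <- lapply(kv, function(m) trimws(m[3L]))
  names(out) <- vapply(kv, function(m) trimws(m[2L]), "")
  out
}

#' Persist an embedding store
#'
#' A named-array container keyed by entity id: the co-embedding matrices of
#' [embed_entities()] plus the producing model's fingerprint, for building
#' indexes and screens later.
#'
#' @param embeddings output of [embed_entities()]
#' @param path output path
#' @export
write_embedding_store <- function(embeddings, path) {
  saveRDS(c(list(format = "dtiscreen_embeddings", format_version = 1L),
            embeddings), path, version = 2)
  invisible(path)
}

#' Read an embedding store written by [write_embedding_store()]
#' @param path input path
#' @return list with `Zd`, `Zt`, `fingerprint`
#' @export
read_embedding_store <- function(path) {
  obj <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop_dti(sprintf("cannot read embeddings '%s': %s", path, conditionMessage(e)),
             "dti_integrity_error"))
  if (!identical(obj$format, "dtiscreen_embeddings"))
    stop_dti(sprintf("'%s' is not an embedding store", path), "dti_integrity_error")
  obj$format <- NULL; obj$format_version <- NULL
  obj
}

#' Write a scored screen as TSV (`item_id  score  label`)
#' @param screen a [ranked_screen()]
#' @param path output path
#' @export
write_scored_screen <- function(screen, path) {
  stopifnot(inherits(screen, "ranked_screen"))
  write_tsv(data.frame(item_id = screen$ids, score = fmt_num(screen$scores),
                       label = screen$labels), path)
  invisible(path)
}

#' Read a scored screen TSV written by [write_scored_screen()]
#' @param path input path
#' @return a [ranked_screen()]
#' @export
read_scored_screen <- function(path) {
  tab <- read_tsv(path)
  need <- c("item_id", "score", "label")
  if (!all(need %in% names(tab)))
    stop_dti(sprintf("'%s' must have columns: %s", path, paste(need, collapse = ", ")),
             "dti_io_error")
  ranked_screen(as.numeric(tab$score), as.integer(tab$label),
                as.character(tab$item_id))
}
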