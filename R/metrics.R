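# Virtual-screening and classification metrics: AUROC (Mann-Whitney form,
# ties count 1/2), AUPR (threshold-block step summation), BEDROC (RIE-based
# with exact min/max normalization) and enrichment factors at a top fraction.
#
# Every function accepts either (scores, labels) vectors or a ranked_screen
# object. Ties are broken by descending score then stable input order where a
# hard ordering is needed (BEDROC ranks, EF top slice); AUROC and AUPR handle
# ties analytically.

#' Construct a ranked screen
#'
#' @param scores numeric scores, higher = more likely active
#' @param labels 0/1 activity labels
#' @param ids optional item identifiers
#' @return an object of class `ranked_screen`
#' @export
ranked_screen <- function(scores, labels, ids = NULL) {
  if (length(scores) != length(labels))
    stop_dti(sprintf("length mismatch: %d scores vs %d labels",
                     length(scores), length(labels)), "dti_input_error")
  if (!all(labels %in% c(0, 1)))
    stop_dti("labels must be 0 or 1", "dti_input_error")
  if (any(!is.finite(scores)))
    stop_dti("scores must be finite", "dti_input_error")
  ids <- ids %||% as.character(seq_along(scores))
  structure(list(ids = as.character(ids), scores = as.numeric(scores),
                 labels = as.integer(labels)), class = "ranked_screen")
}

unpack_screen <- function(scores, labels) {
  if (inherits(scores, "ranked_screen")) {
    list(scores = scores$scores, labels = scores$labels)
  } else {
    s <- ranked_screen(scores, labels)
    list(scores = s$scores, labels = s$labels)
  }
}

require_both_classes <- function(labels, what) {
  if (sum(labels) == 0L || sum(labels) == length(labels))
    stop_dti(sprintf("%s requires at least one positive and one negative", what),
             "dti_input_error")
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic: the probability that
#' a random positive outscores a random negative, with ties contributing 1/2.
#'
#' @param scores scores (or a [ranked_screen()])
#' @param labels 0/1 labels (omit when passing a ranked_screen)
#' @return AUROC in [0, 1]
#' @export
auroc <- function(scores, labels = NULL) {
  s <- unpack_screen(scores, labels)
  require_both_classes(s$labels, "AUROC")
  n_pos <- sum(s$labels)
  n_neg <- length(s$labels) - n_pos
  r <- rank(s$scores, ties.method = "average")
  (sum(r[s$labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over recall increments at each distinct score
#' threshold (no trapezoids): tied scores move precision and recall as one
#' block, so an all-tied screen scores exactly its prevalence.
#'
#' @param scores scores (or a [ranked_screen()])
#' @param labels 0/1 labels
#' @return AUPR in (0, 1]
#' @export
auprc <- function(scores, labels = NULL) {
  s <- unpack_screen(scores, labels)
  n_pos <- sum(s$labels)
  if (n_pos == 0L) stop_dti("AUPR requires at least one positive", "dti_input_error")
  o <- order(-s$scores)
  sc <- s$scores[o]; y <- s$labels[o]
  block_end <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- cumsum(y)[block_end]
  nseen <- seq_along(y)[block_end]
  dtp <- diff(c(0, tp))
  sum(dtp * tp / nseen) / n_pos
}

#' Boltzmann-enhanced discrimination of ROC (BEDROC)
#'
#' The robust initial enhancement RIE (mean over actives of exp(-alpha r/N),
#' normalized by its expectation under a uniform ranking) mapped affinely by
#' the minimum and maximum RIE attainable for the given N and number of
#' actives, so the worst possible ranking scores 0 and the best scores 1.
#' Larger alpha puts more weight on early ranks; the early-recognition
#' convention is alpha = 85 (roughly the top 2% of the list early), but any
#' positive alpha -- including 0.85 -- can be requested.
#'
#' @param scores scores (or a [ranked_screen()])
#' @param labels 0/1 labels
#' @param alpha positive early-recognition parameter (default 85)
#' @return BEDROC in [0, 1]
#' @export
bedroc <- function(scores, labels = NULL, alpha = 85.0) {
  if (!is_scalar_number(alpha) || alpha <= 0)
    stop_dti("alpha must be a positive number", "dti_config_error")
  s <- unpack_screen(scores, labels)
  require_both_classes(s$labels, "BEDROC")
  N <- length(s$labels)
  n <- sum(s$labels)
  o <- order(-s$scores)               # stable: ties by input order
  ranks <- which(s$labels[o] == 1L)
  rie <- function(r) sum(exp(-alpha * r / N)) / (n * (1 - exp(-alpha)) /
                                                   (N * (exp(alpha / N) - 1)))
  val <- rie(ranks)
  lo <- rie((N - n + 1):N)
  hi <- rie(1:n)
  (val - lo) / (hi - lo)
}

#' Enrichment factor at a top fraction
#'
#' Concentration of actives in the top `ceiling(fraction * N)` items relative
#' to the whole screen; ties broken by descending score then stable input
#' order. Bounded above by both 1/fraction and N/n_actives.
#'
#' @param scores scores (or a [ranked_screen()])
#' @param labels 0/1 labels
#' @param fraction top fraction of the ranked list, in (0, 1)
#' @return non-negative enrichment factor
#' @export
enrichment_factor <- function(scores, labels = NULL, fraction = 0.01) {
  if (!is_scalar_number(fraction) || fraction <= 0 || fraction >= 1)
    stop_dti("fraction must lie strictly between 0 and 1", "dti_config_error")
  s <- unpack_screen(scores, labels)
  N <- length(s$labels)
  n <- sum(s$labels)
  if (n == 0L) stop_dti("EF requires at least one positive", "dti_input_error")
  k <- ceiling(fraction * N)
  o <- order(-s$scores)
  hits <- sum(s$labels[o][seq_len(k)])
  (hits / k) / (n / N)
}

#' Standard evaluation report for a scored screen
#'
#' @param scores scores (or a [ranked_screen()])
#' @param labels 0/1 labels
#' @param bedroc_alpha BEDROC alpha (default 85)
#' @param ef_fractions EF top fractions (default 0.5%, 1%, 5%)
#' @return named list of metric values
#' @export
evaluate_screen <- function(scores, labels = NULL, bedroc_alpha = 85.0,
                            ef_fractions = c(0.005, 0.01, 0.05)) {
  s <- unpack_screen(scores, labels)
  out <- list(
    n = length(s$labels),
    n_actives = sum(s$labels),
    auroc = auroc(s$scores, s$labels),
    aupr = auprc(s$scores, s$labels),
    bedroc = bedroc(s$scores, s$labels, alpha = bedroc_alpha),
    bedroc_alpha = bedroc_alpha
  )
  for (f in ef_fractions)
    out[[sprintf("ef_%g", 100 * f)]] <- enrichment_factor(s$scores, s$labels, f)
  out
}
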