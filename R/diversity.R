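#' Community member proportions
#'
#' @param ids member organism ids.
#' @param p proportions, all >= 0, summing to 1 within 1e-9.
#' @return named numeric vector of class `community_proportions`.
#' @export
community_proportions <- function(ids, p) {
  if (length(ids) != length(p)) .stopf("ids and proportions differ in length")
  if (any(p < 0)) .stopf("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) .stopf("proportions must sum to 1 (got %.10f)", sum(p))
  structure(setNames(as.numeric(p), ids), class = "community_proportions")
}

#' Shannon diversity index
#'
#' `H = -sum(p * ln p)` over members with positive proportion; 0 for a
#' single-member community, `ln(richness)` for an even one.
#'
#' @param p proportions (a [community_proportions()] or plain vector
#'   summing to 1).
#' @return non-negative value.
#' @export
shannon_index <- function(p) {
  p <- as.numeric(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Community richness
#'
#' Number of members with positive proportion.
#'
#' @param p proportions.
#' @return integer count.
#' @export
richness <- function(p) {
  sum(as.numeric(p) > 0)
}

#' Abundance-weighted composite similarity score
#'
#' `sum_i sum_j (1 - score_ij) * min(p_i, p_j)` over ordered pairs (i, j both
#' run over all members), the diagonal contributing 0: each pair's sketch
#' dissimilarity weighted by the abundance of its less-abundant member,
#' counted once per ordered pair. 0 when all pairwise scores are 1 or when
#' the community collapses to one member.
#'
#' @param sim_matrix symmetric similarity matrix in \[0, 1\] (kind
#'   `"jaccard"`), member ids as dimnames.
#' @param p a [community_proportions()] over the same member ids.
#' @return non-negative value.
#' @export
composite_score <- function(sim_matrix, p) {
  ids <- names(p)
  if (is.null(ids) || !setequal(ids, rownames(sim_matrix)))
    .stopf("composite_score: matrix and proportions must share member ids")
  kind <- attr(sim_matrix, "kind")
  if (!is.null(kind) && kind != "jaccard")
    .stopf("composite_score expects a jaccard-kind similarity matrix")
  m <- sim_matrix[ids, ids]
  pv <- as.numeric(p)
  total <- 0
  n <- length(pv)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    total <- total + (1 - m[i, j]) * min(pv[i], pv[j])
  }
  total
}
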