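# Voxel-wise majority-vote fusion of segmentation masks (the consensus
# contour, "ConSeg").

#' Consensus vote specification
#'
#' @param n_voters number of input masks.
#' @param vote_threshold minimum inclusive number of votes; defaults to a
#'   strict majority, `floor(n/2) + 1` (3 of 4).
#' @return a `consensus_spec` list.
#' @export
consensus_spec <- function(n_voters, vote_threshold = NULL) {
  n_voters <- as.integer(n_voters)
  if (is.null(vote_threshold))
    vote_threshold <- n_voters %/% 2L + 1L
  vote_threshold <- as.integer(vote_threshold)
  if (vote_threshold < 1L || vote_threshold > n_voters)
    stop("consensus_spec: vote_threshold must be in [1, n_voters]")
  list(n_voters = n_voters, vote_threshold = vote_threshold)
}

#' Majority-vote fusion of binary masks
#'
#' A voxel belongs to the consensus iff it is set in at least
#' `spec$vote_threshold` of the input masks. The output always lies between
#' the intersection and the union of the inputs and is invariant to their
#' order.
#'
#' @param masks list of >= 2 congruent `binary_mask` objects.
#' @param spec a [consensus_spec()]; defaults to a strict majority over
#'   `length(masks)` voters.
#' @return a `binary_mask`.
#' @export
majority_vote <- function(masks, spec = NULL) {
  if (length(masks) < 2L) stop("majority_vote: need at least 2 masks")
  for (i in seq_along(masks)[-1])
    stop_if_incongruent(masks[[1]], masks[[i]], "vote masks")
  if (is.null(spec)) spec <- consensus_spec(length(masks))
  if (spec$n_voters != length(masks))
    stop("majority_vote: spec$n_voters does not match the number of masks")
  votes <- Reduce(`+`, lapply(masks, function(m) m$data + 0L))
  binary_mask(votes >= spec$vote_threshold, masks[[1]]$spacing)
}

#' Consensus-contour segmentation (ConSeg)
#'
#' Runs the four individual methods with [run_all()], fuses them by
#' majority vote, and keeps the largest connected component. If the
#' consensus at the requested threshold is empty, the threshold is lowered
#' by one and the result flagged.
#'
#' @inheritParams segment_41max
#' @param params,seed forwarded to [run_all()].
#' @param vote_threshold minimum votes; default strict majority.
#' @param results optional precomputed output of [run_all()] to fuse
#'   (avoids rerunning the individual methods).
#' @return a `segmentation_result` with method tag `"ConSeg"`.
#' @export
conseg <- function(image, init, params = list(), seed = 1L,
                   vote_threshold = NULL, results = NULL) {
  if (is.null(results)) results <- run_all(image, init, params, seed)
  masks <- lapply(results, function(r) r$mask)
  spec <- consensus_spec(length(masks), vote_threshold)
  fused <- majority_vote(masks, spec)
  flagged <- FALSE
  while (!any(fused$data) && spec$vote_threshold > 1L) {
    flagged <- TRUE
    spec <- consensus_spec(length(masks), spec$vote_threshold - 1L)
    fused <- majority_vote(masks, spec)
  }
  if (!any(fused$data)) stop("conseg: consensus is empty at every threshold")
  res <- postprocess_lcc(fused$data, init)
  new_segmentation_result("ConSeg", res,
                          list(vote_threshold = spec$vote_threshold,
                               n_voters = spec$n_voters, flagged = flagged,
                               voters = names(results)))
}
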