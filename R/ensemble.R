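#' Stack per-model predictions for one image
#'
#' Holds each model's binary vote and probability map for every pixel, the
#' input to plurality fusion. Probabilities are kept for tie-breaking when an
#' even number of models splits evenly.
#'
#' @param probabilities `H x W x M` array of per-model foreground
#'   probabilities in `[0, 1]` (one slab per model).
#' @param threshold binarisation threshold defining the votes
#'   (vote = probability strictly greater than threshold).
#' @param model_ids optional character vector of `M` model names.
#' @return an object of class `"vote_panel"`.
#' @export
vote_panel <- function(probabilities, threshold = 0.5, model_ids = NULL) {
  if (is.matrix(probabilities))
    probabilities <- array(probabilities, dim = c(dim(probabilities), 1L))
  d <- dim(probabilities)
  if (length(d) != 3L || d[3L] < 1L)
    stop_config("probabilities must be an H x W x M array with M >= 1")
  if (any(probabilities < 0 | probabilities > 1))
    stop_config("probabilities must lie in [0, 1]")
  if (is.null(model_ids)) model_ids <- paste0("model_", seq_len(d[3L]))
  if (length(model_ids) != d[3L])
    stop_config("model_ids must name all ", d[3L], " models")
  structure(list(probabilities = probabilities,
                 binary_votes = (probabilities > threshold) * 1,
                 threshold = threshold, model_ids = model_ids),
            class = "vote_panel")
}

#' Fuse a vote panel by per-pixel plurality
#'
#' Each pixel takes the label with the most votes. With two labels plurality
#' reduces to majority; on an exact tie (even model counts only) the pixel is
#' foreground iff the mean probability across models strictly exceeds 0.5.
#'
#' @param panel a [vote_panel()].
#' @return binary `H x W` fused mask.
#' @export
majority_vote <- function(panel) {
  if (!inherits(panel, "vote_panel")) stop_config("panel must be a vote_panel")
  v <- panel$binary_votes
  M <- dim(v)[3L]
  ones <- apply(v, c(1L, 2L), sum)
  fused <- (2 * ones > M) * 1
  ties <- 2 * ones == M
  if (any(ties)) {
    meanp <- apply(panel$probabilities, c(1L, 2L), mean)
    fused[ties] <- (meanp[ties] > 0.5) * 1
  }
  fused
}

#' Ensemble prediction for one image
#'
#' Runs every model forward on the image, stacks the probability maps into a
#' [vote_panel()], and fuses with [majority_vote()]. Fusion is symmetric in
#' model order and never overrides a unanimous pixel.
#'
#' @param models list of `"segnet"` or `"segnet_fit"` objects.
#' @param image `H x W` intensity matrix.
#' @param threshold vote binarisation threshold.
#' @return binary `H x W` fused mask.
#' @export
ensemble_predict <- function(models, image, threshold = 0.5) {
  if (!length(models)) stop_config("need at least one model")
  probs <- vector("list", length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (inherits(m, "segnet_fit")) m <- m$model
    probs[[i]] <- tryCatch(forward(m, image), error = function(e)
      stop_config("model ", i, " (", m$spec$family,
                  ") cannot process this image: ", conditionMessage(e)))
  }
  d <- dim(probs[[1L]])
  arr <- array(unlist(probs, use.names = FALSE),
               dim = c(d[1L], d[2L], length(models)))
  majority_vote(vote_panel(arr, threshold = threshold))
}
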