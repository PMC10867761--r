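# Inter-grader segmentation agreement.

#' Dice coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, the pixel-overlap agreement between
#' two segmentations of the same image. Two empty masks return 1 (perfect
#' vacuous agreement) with a warning, since an all-empty comparison almost
#' always indicates an input problem.
#'
#' @param a,b [binary_mask()] objects (or logical matrices) of identical
#'   shape.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  pa <- if (inherits(a, "binary_mask")) a$pixels else a != 0
  pb <- if (inherits(b, "binary_mask")) b$pixels else b != 0
  if (!identical(dim(pa), dim(pb)))
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dim(pa), collapse = "x"), paste(dim(pb), collapse = "x")))
  na <- sum(pa); nb <- sum(pb)
  if (na + nb == 0) {
    warning("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(pa & pb) / (na + nb)
}

#' Pairwise Dice coefficients across graders
#'
#' One result per unordered grader pair (`k` graders give `k(k-1)/2` rows),
#' e.g. all 6 combinations of 4 graders.
#'
#' @param masks list of [binary_mask()] objects of one image, same shape.
#' @param graders character vector of grader labels (defaults to list
#'   names, else `grader1..k`).
#' @param image_id image identifier (defaults to the first mask's).
#' @return data frame with columns `image_id`, `grader_a`, `grader_b`,
#'   `dice`.
#' @export
pairwise_dice <- function(masks, graders = NULL, image_id = NULL) {
  k <- length(masks)
  if (k < 2) stop("need at least 2 masks for pairwise agreement")
  if (is.null(graders)) {
    graders <- names(masks)
    if (is.null(graders) || any(graders == ""))
      graders <- sprintf("grader%d", seq_len(k))
  }
  stopifnot(length(graders) == k)
  if (is.null(image_id)) {
    image_id <- if (inherits(masks[[1]], "binary_mask")) masks[[1]]$image_id else "image"
  }
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    image_id = image_id,
    grader_a = graders[pairs[1, ]],
    grader_b = graders[pairs[2, ]],
    dice = apply(pairs, 2, function(p) dice_coefficient(masks[[p[1]]], masks[[p[2]]])),
    stringsAsFactors = FALSE)
  out
}
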