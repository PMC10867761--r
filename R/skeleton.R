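# Skeletonization: Zhang-Suen parallel thinning followed by a sequential
# simple-point cleanup. The cleanup removes the 2-px staircase leftovers the
# parallel pass is known to produce, so the result is a minimal 8-connected
# unit-width skeleton and a fixed point of the whole operation.
#
# Implementation note: the image is padded by one background ring and all
# neighbourhood tests are done with linear-index arithmetic on the current
# foreground set only; vessel masks are sparse (a few percent foreground),
# which makes this an order of magnitude faster than whole-matrix shifts.

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  r_dst <- seq_len(nr); r_src <- r_dst + dr
  ok_r <- r_src >= 1 & r_src <= nr
  c_dst <- seq_len(nc); c_src <- c_dst + dc
  ok_c <- c_src >= 1 & c_src <= nc
  out[r_dst[ok_r], c_dst[ok_c]] <- m[r_src[ok_r], c_src[ok_c]]
  out
}

neighbor_count <- function(m) {
  shift_mat(m, -1, 0) + shift_mat(m, -1, 1) + shift_mat(m, 0, 1) +
    shift_mat(m, 1, 1) + shift_mat(m, 1, 0) + shift_mat(m, 1, -1) +
    shift_mat(m, 0, -1) + shift_mat(m, -1, -1)
}

pad_mask <- function(img) {
  p <- matrix(FALSE, nrow(img) + 2, ncol(img) + 2)
  p[2:(nrow(img) + 1), 2:(ncol(img) + 1)] <- img
  p
}

unpad_mask <- function(p) p[2:(nrow(p) - 1), 2:(ncol(p) - 1)]

# linear-index offsets of the 8-ring in N, NE, E, SE, S, SW, W, NW order
ring_offsets <- function(nrp) c(-1, nrp - 1, nrp, nrp + 1, 1, -nrp + 1, -nrp, -nrp - 1)

ring_lookup <- function(p, idx, offs) {
  lapply(offs, function(o) p[idx + o])
}

# Hilditch crossing number from the 8-ring values (vectorized); 1 <=> the
# pixel is 8-simple (deletable without changing local connectivity).
crossing_number_vec <- function(P) {
  (!P[[1]] & (P[[2]] | P[[3]])) + (!P[[3]] & (P[[4]] | P[[5]])) +
    (!P[[5]] & (P[[6]] | P[[7]])) + (!P[[7]] & (P[[8]] | P[[1]]))
}

# Sequential pass deleting simple non-endpoint pixels until fixpoint.
# Candidates are found vectorized; each is re-verified locally right before
# deletion since earlier deletions in the same sweep may apply.
simple_point_cleanup_padded <- function(p, nrp) {
  offs <- ring_offsets(nrp)
  repeat {
    idx <- which(p)
    if (length(idx) == 0) break
    P <- ring_lookup(p, idx, offs)
    B <- Reduce(`+`, P)
    cand <- idx[B >= 2 & crossing_number_vec(P) == 1]
    removed <- FALSE
    for (i in cand) {
      ring <- p[i + offs]
      if (sum(ring) < 2) next
      x <- (!ring[1] & (ring[2] | ring[3])) + (!ring[3] & (ring[4] | ring[5])) +
        (!ring[5] & (ring[6] | ring[7])) + (!ring[7] & (ring[8] | ring[1]))
      if (x == 1) { p[i] <- FALSE; removed <- TRUE }
    }
    if (!removed) break
  }
  p
}

#' Skeletonize a binary vessel mask
#'
#' Topology-preserving morphological thinning (Zhang--Suen two-subiteration
#' scheme) with a sequential simple-point cleanup pass, yielding a minimal
#' unit-width 8-connected skeleton. The operation is idempotent: applying
#' it to its own output changes nothing, because both stages run to a fixed
#' point.
#'
#' @param mask a [binary_mask()], `skeleton_mask` or logical matrix.
#' @return A `skeleton_mask`: list with `pixels` (logical matrix, same shape
#'   as the input) and `image_id`.
#' @export
skeletonize_mask <- function(mask) {
  if (inherits(mask, c("skeleton_mask", "binary_mask"))) {
    img <- mask$pixels; image_id <- mask$image_id
  } else {
    img <- mask != 0; image_id <- "image"
  }
  p <- pad_mask(img)
  nrp <- nrow(p)
  offs <- ring_offsets(nrp)
  cand_mark <- matrix(FALSE, nrow(p), ncol(p))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      idx <- which(p)
      if (length(idx) == 0) break
      P <- ring_lookup(p, idx, offs)          # N NE E SE S SW W NW
      B <- Reduce(`+`, P)
      ring9 <- c(P, P[1])
      A <- 0L
      for (k in 1:8) A <- A + (!ring9[[k]] & ring9[[k + 1]])
      # Zhang-Suen: P2 P4 P6 P8 = N E S W = P[[1]] P[[3]] P[[5]] P[[7]]
      del <- B >= 2 & B <= 6 & A == 1
      if (pass == 1) {
        del <- del & !(P[[1]] & P[[3]] & P[[5]]) & !(P[[3]] & P[[5]] & P[[7]])
      } else {
        del <- del & !(P[[1]] & P[[3]] & P[[7]]) & !(P[[1]] & P[[5]] & P[[7]])
      }
      if (!any(del)) next
      # Topology-safe commit. Raw parallel deletion can erase a 2-px-wide
      # diagonal stage wholesale (every pixel deletable at once), amputating
      # vessel tips. Mutually non-adjacent candidates are safe to delete in
      # parallel (each is 8-simple, A == 1); adjacent ones are committed
      # sequentially with a local simple-point recheck.
      cand <- idx[del]
      cand_mark[cand] <- TRUE
      n_adj <- Reduce(`+`, ring_lookup(cand_mark, cand, offs))
      cand_mark[cand] <- FALSE
      free <- cand[n_adj == 0]
      if (length(free) > 0) { p[free] <- FALSE; changed <- TRUE }
      for (i in cand[n_adj > 0]) {
        ring <- p[i + offs]
        if (sum(ring) < 2) next
        x <- (!ring[1] & (ring[2] | ring[3])) + (!ring[3] & (ring[4] | ring[5])) +
          (!ring[5] & (ring[6] | ring[7])) + (!ring[7] & (ring[8] | ring[1]))
        if (x == 1) { p[i] <- FALSE; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  p <- simple_point_cleanup_padded(p, nrp)
  structure(list(pixels = unpad_mask(p), image_id = image_id),
            class = "skeleton_mask")
}

#' @export
print.skeleton_mask <- function(x, ...) {
  cat(sprintf("<skeleton_mask> %s: %d x %d, %d skeleton px\n",
              x$image_id, nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}
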