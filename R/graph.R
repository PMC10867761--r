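# Vessel graph construction and decomposition into segments.
#
# All matrix coordinates are 1-based R indices internally; optic-disc
# centers arrive 0-based (file convention) and are shifted by +1 on use.

node_classes <- c("isolated", "endpoint", "slab", "branch")

classify_degree <- function(deg) {
  ifelse(deg == 0, "isolated", ifelse(deg == 1, "endpoint",
         ifelse(deg == 2, "slab", "branch")))
}

#' Build the pixel-adjacency vessel graph of a skeleton
#'
#' Every skeleton pixel becomes a node; edges are exactly the 8-adjacencies
#' between skeleton pixels. Node class follows degree: 0 isolated,
#' 1 endpoint, 2 slab, >= 3 branch.
#'
#' @param skeleton a `skeleton_mask` from [skeletonize_mask()] (or a logical
#'   matrix).
#' @return A `vessel_graph`: list with `nodes` (data frame `row`, `col`,
#'   `degree`, `class`), `edges` (2-column integer matrix of node indices),
#'   `dim` and `image_id`.
#' @export
build_vessel_graph <- function(skeleton) {
  if (inherits(skeleton, "skeleton_mask")) {
    img <- skeleton$pixels; image_id <- skeleton$image_id
  } else {
    img <- skeleton != 0; image_id <- "image"
  }
  idx <- which(img)
  nr <- nrow(img)
  node_id <- integer(length(img))
  node_id[idx] <- seq_along(idx)
  rc <- arrayInd(idx, dim(img))
  deg <- neighbor_count(img)[idx]
  # undirected edges once each: pair with E, S, SE, SW neighbours
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  ee <- list()
  for (o in offs) {
    r2 <- rc[, 1] + o[1]; c2 <- rc[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= nrow(img) & c2 >= 1 & c2 <= ncol(img)
    ok[ok] <- img[cbind(r2[ok], c2[ok])]
    if (any(ok))
      ee[[length(ee) + 1]] <- cbind(node_id[idx[ok]],
                                    node_id[(c2[ok] - 1) * nr + r2[ok]])
  }
  edges <- if (length(ee)) do.call(rbind, ee) else matrix(integer(0), 0, 2)
  nodes <- data.frame(row = rc[, 1], col = rc[, 2], degree = deg,
                      class = classify_degree(deg), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, dim = dim(img),
                 image_id = image_id),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  tab <- table(factor(x$nodes$class, levels = node_classes))
  cat(sprintf("<vessel_graph> %s: %d nodes (%s), %d edges\n", x$image_id,
              nrow(x$nodes),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

graph_to_matrix <- function(graph) {
  img <- matrix(FALSE, graph$dim[1], graph$dim[2])
  if (nrow(graph$nodes) > 0)
    img[cbind(graph$nodes$row, graph$nodes$col)] <- TRUE
  img
}

#' Remove the optic-disc region from a vessel graph
#'
#' Deletes all nodes within `radius_px` (Euclidean) of the disc center and
#' recomputes degrees and classes. The disc is the confluence hub of the
#' retinal vasculature, where junction geometry is degenerate; excluding it
#' keeps segment decomposition well defined. Radius 0 is the identity.
#'
#' @param graph a `vessel_graph`.
#' @param disc a one-row disc-center data frame ([disc_center()]), 0-based
#'   coordinates.
#' @param radius_px exclusion radius in pixels (>= 0).
#' @return A `vessel_graph`.
#' @export
exclude_disc_region <- function(graph, disc, radius_px) {
  stopifnot(inherits(graph, "vessel_graph"), radius_px >= 0)
  if (radius_px == 0 || nrow(graph$nodes) == 0) return(graph)
  dr <- graph$nodes$row - (disc$row + 1)
  dc <- graph$nodes$col - (disc$col + 1)
  keep <- (dr * dr + dc * dc) > radius_px^2
  img <- matrix(FALSE, graph$dim[1], graph$dim[2])
  img[cbind(graph$nodes$row[keep], graph$nodes$col[keep])] <- TRUE
  g <- build_vessel_graph(img)
  g$image_id <- graph$image_id
  g
}

neighbors_of <- function(img, r, c) {
  # row-major order over the 3x3 neighbourhood, centre excluded
  out <- matrix(0L, 0, 2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nrow(img) && cc >= 1 && cc <= ncol(img) && img[rr, cc])
      out <- rbind(out, c(rr, cc))
  }
  out
}

step_sum <- function(chain) {
  if (nrow(chain) < 2) return(0)
  sum(sqrt(rowSums((chain[-1, , drop = FALSE] - chain[-nrow(chain), , drop = FALSE])^2)))
}

# Iteratively remove terminal spurs (endpoint-to-junction twigs) shorter
# than spur_length_px; thinning of wide vessels sprouts such twigs at
# boundary irregularities and junctions.
prune_spurs <- function(img, spur_length_px) {
  if (spur_length_px <= 0) return(img)
  repeat {
    deg <- neighbor_count(img)
    ends <- which(img & deg == 1)
    if (length(ends) == 0) break
    rcs <- arrayInd(ends, dim(img))
    rcs <- rcs[order(rcs[, 1], rcs[, 2]), , drop = FALSE]
    changed <- FALSE
    for (k in seq_len(nrow(rcs))) {
      r <- rcs[k, 1]; c <- rcs[k, 2]
      if (!img[r, c]) next
      nb <- neighbors_of(img, r, c)
      if (nrow(nb) != 1) next  # degree changed during this sweep
      chain <- rbind(c(r, c))
      prev <- c(r, c); cur <- nb[1, ]
      is_spur <- FALSE
      repeat {
        nb2 <- neighbors_of(img, cur[1], cur[2])
        nb2 <- nb2[!(nb2[, 1] == prev[1] & nb2[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nb2) >= 2) { is_spur <- TRUE; break }     # cur is a junction
        chain <- rbind(chain, cur)
        if (nrow(nb2) == 0) break                          # isolated path, not a spur
        if (step_sum(rbind(chain, nb2[1, ])) >= spur_length_px) break
        prev <- cur; cur <- nb2[1, ]
      }
      if (is_spur && step_sum(rbind(chain, cur)) < spur_length_px) {
        img[chain] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

# Estimate the mean vessel stroke width from mask area and skeleton length,
# correcting for the rounded caps and end-shortening of terminal tips
# (stadium model: area = arc * w + n_tips * (1/2 + pi/8) * w^2).
estimate_stroke_width <- function(mask_px, skel_img) {
  area <- sum(mask_px)
  deg <- neighbor_count(skel_img)
  n_orth <- sum(skel_img & shift_mat(skel_img, 0, 1)) + sum(skel_img & shift_mat(skel_img, 1, 0))
  n_diag <- sum(skel_img & shift_mat(skel_img, 1, 1)) + sum(skel_img & shift_mat(skel_img, 1, -1))
  arc <- n_orth + sqrt(2) * n_diag
  if (arc <= 0) return(1)
  n_tips <- sum(skel_img & deg == 1)
  k <- n_tips * (0.5 + pi / 8)
  if (k <= 0) return(area / arc)
  (-arc + sqrt(arc^2 + 4 * k * area)) / (2 * k)
}

# Length of the in-mask run along a ray from `p0` in direction `d`.
ray_run <- function(mask_px, p0, d, cap) {
  s_exit <- 0
  for (s in seq(0.25, cap, by = 0.25)) {
    q <- round(p0 + d * s)
    if (q[1] < 1 || q[1] > nrow(mask_px) || q[2] < 1 || q[2] > ncol(mask_px) ||
        !mask_px[q[1], q[2]]) break
    s_exit <- s
  }
  s_exit
}

# Extend a chain end outward along its local tangent to the source-mask
# boundary, compensating the end-shortening of morphological thinning
# (thinning retracts vessel tips by about half the stroke width). The chain
# is extended to the mask exit point minus the stroke radius, i.e. to the
# estimated true centerline endpoint.
#
# When the tangent ray exits the mask almost immediately (run shorter than
# the stroke radius) the tip was amputated obliquely -- parallel thinning
# can wipe out a 2-px-wide diagonal cap stage wholesale -- so a small cone
# of directions is searched and the longest in-mask ray is used instead.
extend_tip <- function(chain, mask_px, radius) {
  n <- nrow(chain)
  k <- min(12, n - 1)
  d <- chain[n, ] - chain[n - k, ]
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) return(chain)
  d <- d / nd
  cap <- 6 * radius + 8
  s_exit <- ray_run(mask_px, chain[n, ], d, cap)
  # An amputated tip leaves a clearly longer in-mask run off the tangent
  # direction; the +3 px margin keeps ordinary (straight or curved) tips on
  # the tangent ray, whose run ends at the cap regardless of cone angle.
  s_best <- s_exit
  for (ang in c(-40, -30, -20, -10, 10, 20, 30, 40) * pi / 180) {
    d2 <- c(cos(ang) * d[1] - sin(ang) * d[2],
            sin(ang) * d[1] + cos(ang) * d[2])
    s2 <- ray_run(mask_px, chain[n, ], d2, cap)
    if (s2 > s_best && s2 > s_exit + 3) { s_best <- s2; d <- d2 }
  }
  s_exit <- s_best
  ext <- max(0, s_exit + 0.125 - radius)
  if (ext >= 0.25) {
    ss <- seq(0.25, ext, by = 0.25)
    chain <- rbind(chain, t(vapply(ss, function(s) chain[n, ] + d * s, numeric(2))))
  }
  chain
}

#' Decompose a vessel graph into ordered vessel segments
#'
#' Maximal slab-pixel chains between terminal nodes (endpoints and branch
#' pixels) become segments. Terminal spurs shorter than `spur_length_px` are
#' pruned first (iteratively, to a fixed point); segments whose arc length
#' falls below `min_length_px` are discarded. Each chain is oriented
#' proximal-to-distal: its first point is the end nearer the optic disc.
#'
#' When the source mask is supplied, free vessel tips (endpoint-terminated
#' chain ends) are extended along their local tangent to the mask boundary
#' minus the estimated stroke radius, compensating the tip retraction
#' inherent to thinning.
#'
#' @param graph a `vessel_graph` (possibly disc-excluded).
#' @param disc optional disc center ([disc_center()]) used to orient chains.
#' @param min_length_px minimum segment arc length in pixels (default 20).
#' @param spur_length_px spur-pruning threshold in pixels (default 10).
#' @param mask optional source [binary_mask()] enabling tip extension.
#' @param tip_extension logical; extend free tips when `mask` is given.
#' @return A list of `vessel_segment` objects: `segment_id`, `chain`
#'   (n x 2 matrix of (row, col)), `arc_length_px`, `chord_length_px`,
#'   `n_points`, and the terminal classes `from_class`/`to_class`.
#' @export
extract_segments <- function(graph, disc = NULL, min_length_px = 20,
                             spur_length_px = 10, mask = NULL,
                             tip_extension = TRUE) {
  stopifnot(inherits(graph, "vessel_graph"))
  img <- graph_to_matrix(graph)
  img <- prune_spurs(img, spur_length_px)
  # pruning can leave a redundant pixel at the attachment site (a simple
  # point bridging the main chain); remove such leftovers before tracing
  img <- unpad_mask(simple_point_cleanup_padded(pad_mask(img), nrow(img) + 2))
  deg <- neighbor_count(img) * img
  term <- img & (deg == 1 | deg >= 3)
  visited <- matrix(FALSE, nrow(img), ncol(img))
  tidx <- which(term)
  if (length(tidx) == 0) return(list())
  trc <- arrayInd(tidx, dim(img))
  trc <- trc[order(trc[, 1], trc[, 2]), , drop = FALSE]
  chains <- list()
  for (k in seq_len(nrow(trc))) {
    t0 <- trc[k, ]
    for (nb in seq_len(nrow(nb_all <- neighbors_of(img, t0[1], t0[2])))) {
      n0 <- nb_all[nb, ]
      if (deg[n0[1], n0[2]] != 2 || visited[n0[1], n0[2]]) next
      chain <- rbind(t0, n0)
      visited[n0[1], n0[2]] <- TRUE
      prev <- t0; cur <- n0
      repeat {
        nb2 <- neighbors_of(img, cur[1], cur[2])
        nb2 <- nb2[!(nb2[, 1] == prev[1] & nb2[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nb2) == 0) break
        nxt <- nb2[1, ]
        chain <- rbind(chain, nxt)
        if (deg[nxt[1], nxt[2]] != 2) break
        visited[nxt[1], nxt[2]] <- TRUE
        prev <- cur; cur <- nxt
      }
      chains[[length(chains) + 1]] <- chain
    }
  }
  if (length(chains) == 0) return(list())

  mask_px <- if (!is.null(mask)) {
    if (inherits(mask, "binary_mask")) mask$pixels else mask != 0
  } else NULL
  radius <- if (!is.null(mask_px)) estimate_stroke_width(mask_px, img) / 2 else NA_real_

  segments <- list()
  for (chain in chains) {
    n <- nrow(chain)
    cls_a <- classify_degree(deg[chain[1, 1], chain[1, 2]])
    cls_b <- classify_degree(deg[chain[n, 1], chain[n, 2]])
    chain <- unname(chain * 1.0)
    if (!is.null(mask_px) && tip_extension) {
      if (cls_b == "endpoint") chain <- extend_tip(chain, mask_px, radius)
      if (cls_a == "endpoint") {
        chain <- extend_tip(chain[rev(seq_len(nrow(chain))), , drop = FALSE], mask_px, radius)
        chain <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]
      }
    }
    arc <- step_sum(chain)
    if (arc < min_length_px) next
    # orient proximal (nearer disc) -> distal
    from_class <- cls_a; to_class <- cls_b
    if (!is.null(disc)) {
      d1 <- sum((chain[1, ] - c(disc$row + 1, disc$col + 1))^2)
      d2 <- sum((chain[nrow(chain), ] - c(disc$row + 1, disc$col + 1))^2)
      if (d2 < d1) {
        chain <- chain[rev(seq_len(nrow(chain))), , drop = FALSE]
        from_class <- cls_b; to_class <- cls_a
      }
    }
    chord <- sqrt(sum((chain[nrow(chain), ] - chain[1, ])^2))
    segments[[length(segments) + 1]] <- structure(
      list(segment_id = NA_character_, chain = chain, arc_length_px = arc,
           chord_length_px = chord, n_points = nrow(chain),
           from_class = from_class, to_class = to_class),
      class = "vessel_segment")
  }
  for (i in seq_along(segments)) segments[[i]]$segment_id <- sprintf("seg_%03d", i)
  segments
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("<vessel_segment> %s: %d px, arc %.1f px, chord %.1f px\n",
              x$segment_id, x$n_points, x$arc_length_px, x$chord_length_px))
  invisible(x)
}
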