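# Neovascularization (NV) and vaso-obliteration (VO) area ratios.
#
# The pathology masks themselves come from an external segmentation system
# (or manual annotation); this module only turns them into area fractions
# and records expert overrides with full provenance.

#' Area ratio of a pathology mask
#'
#' Fraction of the reference region covered by the pathology mask:
#' `|pathology intersect denominator| / |denominator|`. With no denominator
#' mask the whole image is the reference region (the flat-mount crop is the
#' operative area); supplying a retina-region mask refines it.
#'
#' @param pathology a [binary_mask()] (or logical matrix) of NV or VO area.
#' @param denominator optional reference-region [binary_mask()] of the same
#'   shape; `NULL` means the whole image.
#' @return Numeric scalar in `[0, 1]`.
#' @export
area_ratio <- function(pathology, denominator = NULL) {
  pp <- if (inherits(pathology, "binary_mask")) pathology$pixels else pathology != 0
  if (is.null(denominator)) {
    return(sum(pp) / length(pp))
  }
  dd <- if (inherits(denominator, "binary_mask")) denominator$pixels else denominator != 0
  if (!identical(dim(pp), dim(dd)))
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dim(pp), collapse = "x"), paste(dim(dd), collapse = "x")))
  if (sum(dd) == 0) stop("denominator mask is empty")
  sum(pp & dd) / sum(dd)
}

#' NV/VO ratio record for one image
#'
#' @param image_id image identifier.
#' @param nv_ratio,vo_ratio area ratios in `[0, 1]` (NA when not measured).
#' @return A `pathology_ratios` object.
#' @export
pathology_ratios <- function(image_id, nv_ratio = NA_real_, vo_ratio = NA_real_) {
  for (v in c(nv_ratio, vo_ratio))
    if (!is.na(v) && (v < 0 || v > 1)) stop("ratios must lie in [0, 1]")
  structure(list(image_id = as.character(image_id),
                 nv_ratio = nv_ratio, vo_ratio = vo_ratio,
                 overridden = c(nv = FALSE, vo = FALSE),
                 overrides = list()),
            class = "pathology_ratios")
}

#' Apply an expert override to an NV or VO ratio
#'
#' Automated VO estimates are occasionally wrong (e.g. lighter pigmentation
#' read as avascular area in healthy retinas); expert graders then adjust
#' the ratio. The original value, replacement and stated reason are all
#' retained in the record's provenance.
#'
#' @param ratios a [pathology_ratios()] record.
#' @param override_value replacement value in `[0, 1]`.
#' @param which `"nv"` or `"vo"`.
#' @param reason non-empty character scalar justifying the override.
#' @return The updated `pathology_ratios` object.
#' @export
apply_override <- function(ratios, override_value, which = c("nv", "vo"), reason) {
  stopifnot(inherits(ratios, "pathology_ratios"))
  which <- match.arg(which)
  if (is.na(override_value) || override_value < 0 || override_value > 1)
    stop("override value must lie in [0, 1]")
  if (missing(reason) || !is.character(reason) || length(reason) != 1 || !nzchar(trimws(reason)))
    stop("a non-empty override reason is required")
  field <- paste0(which, "_ratio")
  ratios$overrides[[length(ratios$overrides) + 1]] <- list(
    which = which, original = ratios[[field]], value = override_value,
    reason = reason)
  ratios[[field]] <- override_value
  ratios$overridden[which] <- TRUE
  ratios
}

#' @export
print.pathology_ratios <- function(x, ...) {
  mark <- function(w) if (x$overridden[w]) "*" else ""
  cat(sprintf("<pathology_ratios> %s: NV %.3f%s, VO %.3f%s\n", x$image_id,
              x$nv_ratio, mark("nv"), x$vo_ratio, mark("vo")))
  if (length(x$overrides) > 0)
    for (o in x$overrides)
      cat(sprintf("  override %s: %.3f -> %.3f (%s)\n", toupper(o$which),
                  o$original, o$value, o$reason))
  invisible(x)
}
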