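# End-to-end runs over directories of masks.

list_mask_files <- function(dir) {
  files <- list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  stats::setNames(files, tools::file_path_sans_ext(basename(files)))
}

as_disc_table <- function(disc_centers, xy_order = FALSE) {
  if (is.character(disc_centers)) load_disc_centers(disc_centers, xy_order = xy_order)
  else disc_centers
}

disc_for <- function(discs, id) {
  i <- match(id, discs$image_id)
  if (is.na(i)) NULL else discs[i, , drop = FALSE]
}

#' Run the tortuosity pipeline over a directory of masks
#'
#' Processes every PNG/TIFF mask in `mask_dir`, pairing each with its
#' optic-disc record by `image_id` (file name without extension). Images
#' that fail are reported by name; the remaining images are still
#' processed.
#'
#' @param mask_dir directory of binary mask files.
#' @param disc_centers path to a disc-center CSV/JSON, or a data frame from
#'   [load_disc_centers()].
#' @param config a [tortuosity_config()].
#' @param out_dir optional output directory; when given,
#'   `tortuosity_per_image.csv` and `tortuosity_per_segment.csv` are
#'   written there.
#' @param xy_order passed to [load_disc_centers()] when `disc_centers` is a
#'   path.
#' @return List with `results` (per-image data frame: `image_id`,
#'   `n_segments`, `cti`, `ic`, `oc`, `config_hash`), `segments`
#'   (per-segment data frame) and `errors` (data frame of failed images,
#'   zero rows on full success).
#' @export
run_tortuosity <- function(mask_dir, disc_centers, config = tortuosity_config(),
                           out_dir = NULL, xy_order = FALSE) {
  files <- list_mask_files(mask_dir)
  if (length(files) == 0) stop(sprintf("no mask files found in %s", mask_dir))
  discs <- as_disc_table(disc_centers, xy_order)
  missing_disc <- setdiff(names(files), discs$image_id)
  if (length(missing_disc) > 0)
    stop(sprintf("no disc-center record for image(s): %s",
                 paste(missing_disc, collapse = ", ")))
  rows <- list(); segs <- list(); errs <- list()
  h <- config_hash(config)
  for (id in names(files)) {
    res <- tryCatch({
      mask <- load_mask(files[[id]], image_id = id)
      measure_tortuosity(mask, disc = disc_for(discs, id), config = config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[id]] <- data.frame(image_id = id, file = files[[id]],
                               error = conditionMessage(res),
                               stringsAsFactors = FALSE)
    } else {
      rows[[id]] <- data.frame(image_id = id, n_segments = res$n_segments,
                               cti = res$cti, ic = res$ic, oc = res$oc,
                               config_hash = h, stringsAsFactors = FALSE)
      segs[[id]] <- segment_table(res)
    }
  }
  out <- list(results = if (length(rows)) do.call(rbind, rows) else
                data.frame(image_id = character(0)),
              segments = if (length(segs)) do.call(rbind, segs) else
                data.frame(image_id = character(0)),
              errors = if (length(errs)) do.call(rbind, errs) else
                data.frame(image_id = character(0), file = character(0),
                           error = character(0)))
  rownames(out$results) <- rownames(out$segments) <- rownames(out$errors) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (nrow(out$results)) write_results_table(out$results,
        file.path(out_dir, "tortuosity_per_image.csv"))
    if (nrow(out$segments)) write_results_table(out$segments,
        file.path(out_dir, "tortuosity_per_segment.csv"))
    if (nrow(out$errors)) write_results_table(out$errors,
        file.path(out_dir, "errors.csv"))
  }
  out
}

ratio_for_dir <- function(dir, id, denominator = NULL) {
  if (is.null(dir)) return(NA_real_)
  files <- list_mask_files(dir)
  if (!id %in% names(files)) return(NA_real_)
  area_ratio(load_mask(files[[id]], image_id = id), denominator)
}

#' Run the full quantification experiment
#'
#' Tortuosity for every mask, NV/VO area ratios where pathology masks are
#' provided, optional expert overrides, then group comparisons (with
#' significance stars) of each available metric across conditions, within
#' each timepoint.
#'
#' @param mask_dir directory of vessel masks.
#' @param disc_centers disc-center CSV/JSON path or data frame.
#' @param group_table path to a grouping CSV (`image_id,condition`,
#'   optional `timepoint`) or an equivalent data frame.
#' @param nv_dir,vo_dir optional directories of NV / VO pathology masks
#'   (file names matching image ids). Missing masks leave the ratio `NA`.
#' @param overrides optional path to an overrides CSV
#'   (`image_id,which,value,reason` with `which` in nv/vo) or an equivalent
#'   data frame.
#' @param config a [tortuosity_config()].
#' @param out_dir optional output directory for `experiment_results.csv`
#'   and `comparisons.csv`.
#' @return List with `results` (tidy per-image data frame), `comparisons`
#'   (per metric x timepoint, with `p_value` and `stars`), and `errors`.
#' @export
run_full_experiment <- function(mask_dir, disc_centers, group_table,
                                nv_dir = NULL, vo_dir = NULL, overrides = NULL,
                                config = tortuosity_config(), out_dir = NULL) {
  groups <- if (is.character(group_table)) load_group_table(group_table) else group_table
  tort <- run_tortuosity(mask_dir, disc_centers, config = config)
  ids <- tort$results$image_id
  not_grouped <- setdiff(ids, groups$image_id)
  no_mask <- setdiff(groups$image_id, c(ids, tort$errors$image_id))
  if (length(not_grouped) > 0 || length(no_mask) > 0)
    stop(sprintf("image-id mismatch between masks and group table%s%s",
                 if (length(not_grouped)) paste0("; ungrouped masks: ",
                     paste(not_grouped, collapse = ", ")) else "",
                 if (length(no_mask)) paste0("; grouped ids without mask: ",
                     paste(no_mask, collapse = ", ")) else ""))
  ov <- if (is.character(overrides)) utils::read.csv(overrides, stringsAsFactors = FALSE)
        else overrides
  ratios <- lapply(ids, function(id) {
    pr <- pathology_ratios(id, nv_ratio = ratio_for_dir(nv_dir, id),
                           vo_ratio = ratio_for_dir(vo_dir, id))
    if (!is.null(ov)) {
      sel <- ov[ov$image_id == id, , drop = FALSE]
      for (k in seq_len(nrow(sel)))
        pr <- apply_override(pr, sel$value[k], which = tolower(sel$which[k]),
                             reason = sel$reason[k])
    }
    pr
  })
  res <- tort$results
  res$nv_ratio <- vapply(ratios, function(r) r$nv_ratio, numeric(1))
  res$vo_ratio <- vapply(ratios, function(r) r$vo_ratio, numeric(1))
  res$nv_overridden <- vapply(ratios, function(r) r$overridden["nv"], logical(1))
  res$vo_overridden <- vapply(ratios, function(r) r$overridden["vo"], logical(1))
  res <- merge(res, groups, by = "image_id", sort = TRUE)
  if (!"timepoint" %in% names(res)) res$timepoint <- NA

  comparisons <- list()
  for (tp in unique(res$timepoint)) {
    sub <- res[is.na(res$timepoint) & is.na(tp) |
               (!is.na(res$timepoint) & !is.na(tp) & res$timepoint == tp), ]
    if (length(unique(sub$condition)) < 2) next
    for (metric in c("cti", "ic", "oc", "nv_ratio", "vo_ratio")) {
      v <- sub[[metric]]
      keep <- !is.na(v)
      if (sum(keep) == 0) next
      cmp <- tryCatch(compare_groups(v[keep], sub$condition[keep], metric = metric),
                      error = function(e) NULL)
      if (is.null(cmp)) next
      comparisons[[length(comparisons) + 1]] <- data.frame(
        timepoint = tp, metric = metric, test = cmp$test,
        statistic = cmp$statistic, p_value = cmp$p_value, stars = cmp$stars,
        groups = paste(sprintf("%s: %.4g+/-%.3g (n=%d)", cmp$groups$label,
                               cmp$groups$mean, cmp$groups$sd, cmp$groups$n),
                       collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame(timepoint = character(0), metric = character(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_table(res, file.path(out_dir, "experiment_results.csv"))
    if (nrow(comparisons))
      write_results_table(comparisons, file.path(out_dir, "comparisons.csv"))
  }
  list(results = res, comparisons = comparisons, errors = tort$errors)
}
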