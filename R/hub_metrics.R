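# Subject-level mapping of tau positivity patterns to the scaled hub map:
# the tau hub ratio, tau epicenters, and epicenter hub-ness.

align_to_hub <- function(pos, hub) {
  if (is.null(names(pos)) || is.null(names(hub)))
    stop("positivity vector and hub map must carry ROI ids as names",
         call. = FALSE)
  if (!setequal(names(pos), names(hub)))
    stop("positivity and hub map cover different ROI sets", call. = FALSE)
  pos[names(hub)]
}

#' Tau hub ratio
#'
#' Maps a subject's tau positivity pattern onto the scaled hub map: the
#' positivity-weighted mean of the hub map,
#' \deqn{\mathrm{ratio} = \frac{\sum_i p_i \, h_i}{\sum_i p_i},}
#' where \eqn{p_i} is the ROI's tau positivity and \eqn{h_i \in [-1, 1]} its
#' scaled hub value. Dividing by total positivity adjusts for global tau
#' burden, so the ratio reflects the deposition *pattern* (positive =
#' hub-weighted, negative = non-hub-weighted), not its severity, and is
#' invariant to rescaling the positivity vector.
#'
#' @param pos named nonnegative per-ROI positivity vector.
#' @param hub named scaled hub map (group-level or subject-level).
#' @return scalar in \[-1, 1\].
#' @export
tau_hub_ratio <- function(pos, hub) {
  pos <- align_to_hub(pos, hub)
  if (any(pos < 0)) stop("negative positivity values", call. = FALSE)
  tot <- sum(pos)
  if (tot <= 0)
    stop("no suprathreshold tau signal (all-zero positivity)", call. = FALSE)
  sum(pos * hub) / tot
}

#' Tau epicenters of a positivity pattern
#'
#' The fraction of ROIs (default 10%) with the highest baseline tau
#' positivity for a subject. The count is `ceiling(fraction * n_roi)`; ties
#' at the boundary are broken deterministically by ROI-id order.
#'
#' @param pos named nonnegative per-ROI positivity vector.
#' @param fraction fraction of ROIs to select (default 0.10).
#' @return character vector of epicenter ROI ids.
#' @export
epicenters <- function(pos, fraction = 0.10) {
  if (is.null(names(pos))) stop("positivity vector must be named", call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  if (sum(pos) <= 0)
    stop("no suprathreshold tau signal (all-zero positivity)", call. = FALSE)
  k <- ceiling(fraction * length(pos))
  ord <- order(-pos, names(pos))  # ties -> lowest ROI id first
  names(pos)[ord[seq_len(k)]]
}

#' Mean connectivity-based distance of an epicenter set
#'
#' Epicenter hub-ness: the mean of the per-ROI mean connectivity-based
#' distances over the epicenter ROIs. Lower values mean the epicenters sit
#' in more globally connected (hub-like) cortex.
#'
#' @param epi character vector of epicenter ROI ids.
#' @param mean_distance named per-ROI mean distance vector from
#'   [weighted_degree()].
#' @return scalar mean distance.
#' @export
epicenter_distance <- function(epi, mean_distance) {
  if (!length(epi)) stop("empty epicenter set", call. = FALSE)
  miss <- setdiff(epi, names(mean_distance))
  if (length(miss))
    stop("epicenter ROI(s) not in distance vector: ",
         paste(miss, collapse = ", "), call. = FALSE)
  mean(mean_distance[epi])
}

#' Per-subject hub metrics from a positivity matrix
#'
#' Computes, for every subject: the tau hub ratio, global tau (mean
#' positivity), the epicenter ROI set, and epicenter hub-ness. Subjects with
#' all-zero positivity (no suprathreshold tau anywhere) get `NA` metrics and
#' are listed in the `zero_subjects` attribute rather than erroring the
#' whole cohort.
#'
#' @param baseline_pos subject x ROI baseline positivity matrix.
#' @param hub named scaled hub map.
#' @param mean_distance named per-ROI mean distance vector.
#' @param fraction epicenter fraction (default 0.10).
#' @return data frame keyed by `subject_id` with `tau_hub_ratio`,
#'   `global_tau`, `epicenter_distance`; epicenter sets in the
#'   `"epicenters"` attribute (long data frame of subject_id, roi_id).
#' @export
subject_hub_metrics <- function(baseline_pos, hub, mean_distance,
                                fraction = 0.10) {
  subs <- rownames(baseline_pos)
  out <- data.frame(subject_id = subs,
                    tau_hub_ratio = NA_real_,
                    global_tau = rowMeans(baseline_pos),
                    epicenter_distance = NA_real_,
                    stringsAsFactors = FALSE)
  epi_rows <- list()
  zero <- character()
  for (i in seq_along(subs)) {
    p <- baseline_pos[i, ]
    if (sum(p) <= 0) { zero <- c(zero, subs[i]); next }
    out$tau_hub_ratio[i] <- tau_hub_ratio(p, hub)
    epi <- epicenters(p, fraction)
    out$epicenter_distance[i] <- epicenter_distance(epi, mean_distance)
    epi_rows[[subs[i]]] <- data.frame(subject_id = subs[i], roi_id = epi,
                                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "epicenters") <- do.call(rbind, c(epi_rows, list(make.row.names = FALSE)))
  attr(out, "zero_subjects") <- zero
  out
}
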