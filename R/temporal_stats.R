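# Temporal characterization of saliency maps: per-time-point density of
# top-salient cells, earth mover's distance to the uniform density, and
# Wilcoxon rank tests for group comparisons.

#' Temporal density of top-salient cells
#'
#' For each time point, counts the components whose cells fall in the
#' top-`p` fraction of the saliency map (signed selection, same rule as
#' the retain-and-retrain masks).  The counts always sum to
#' `round(p * C * T)`.
#'
#' @param saliency A `saliency_map` (see [assemble_subject_saliency()])
#'   or a plain `C x T` importance matrix.
#' @param p Top fraction (default 0.05).
#' @return A `temporal_density`: list with `counts` (length-`T` integer
#'   vector) and `normalized` (probability vector summing to 1).
#' @export
temporal_density <- function(saliency, p = 0.05) {
  mask <- select_top_fraction(saliency, p)
  counts <- colSums(mask)
  structure(list(counts = as.integer(counts),
                 normalized = counts / sum(counts)),
            class = "temporal_density")
}

#' Earth mover's distance to the uniform temporal density
#'
#' 1-D optimal-transport distance between the normalized density and the
#' uniform distribution on the `T` time points `{0, ..., T-1}`, computed
#' in index units as the sum of absolute CDF differences (the closed form
#' of 1-D EMD with unit ground distance).  0 iff the density is exactly
#' uniform; a point mass at `t = 0` gives `(T - 1) / 2`.
#'
#' @param density A `temporal_density`, or a nonnegative numeric vector
#'   of counts/weights over time points.
#' @return Nonnegative scalar distance (index units).
#' @export
emd_to_uniform <- function(density) {
  w <- if (inherits(density, "temporal_density")) density$counts
       else as.numeric(density)
  if (any(w < 0)) stop("negative mass in density")
  tot <- sum(w)
  if (tot == 0) stop("zero total mass")
  Tn <- length(w)
  sum(abs(cumsum(w / tot) - cumsum(rep(1 / Tn, Tn))))
}

#' Wilcoxon rank test for saliency-derived statistics
#'
#' Unpaired groups use the rank-sum (Mann-Whitney) form; paired samples
#' (e.g. matched AUC cells of the with/without-pretraining regimes) use
#' the signed-rank form.  Two-sided p-values.
#'
#' @param group_a,group_b Numeric vectors; equal length required when
#'   `paired = TRUE`; each group needs `n >= 5` when unpaired.
#' @param paired Use the signed-rank form.
#' @return List with `statistic` and `p_value`.
#' @export
wilcoxon_rank <- function(group_a, group_b, paired = FALSE) {
  if (paired && length(group_a) != length(group_b)) {
    stop("paired test requires equal lengths")
  }
  if (!paired && (length(group_a) < 5L || length(group_b) < 5L)) {
    stop("unpaired test requires n >= 5 per group")
  }
  if (paired && all(group_a == group_b)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1))
  }
  if (!paired && all(c(group_a, group_b) == c(group_a, group_b)[1L])) {
    warning("all values tied; p = 1")
    return(list(statistic = NA_real_, p_value = 1))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, paired = paired,
                       alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Per-subject EMD table for a cohort of saliency maps
#'
#' Convenience wrapper: computes [temporal_density()] and
#' [emd_to_uniform()] for each saliency map and tabulates them with
#' group labels.
#'
#' @param maps List of `saliency_map` objects (or `C x T` matrices).
#' @param groups Vector of group labels, one per map.
#' @param p Top fraction for the densities.
#' @return data.frame with `subject_id, group, emd`.
#' @export
emd_table <- function(maps, groups, p = 0.05) {
  stopifnot(length(maps) == length(groups))
  data.frame(
    subject_id = vapply(seq_along(maps), function(i) {
      m <- maps[[i]]
      if (inherits(m, "saliency_map") && nzchar(m$subject_id)) m$subject_id
      else as.character(i)
    }, ""),
    group = groups,
    emd = vapply(maps, function(m) emd_to_uniform(temporal_density(m, p)),
                 numeric(1)))
}
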