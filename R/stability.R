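#' Normalize tile counts to spike-in levels
#'
#' Divides every tile's count by the summed spike-in counts of its sample
#' (all spike species summed first), then drops the spike rows. Because the
#' spikes are added at fixed amounts per sample, this cancels per-sample
#' scale differences (extraction efficiency, depth).
#'
#' @param counts Feature x sample matrix containing the spike rows.
#' @param spike_ids Row names of the spike-in species.
#' @return Tile x sample matrix of spike-normalized levels.
#' @export
spike_normalize <- function(counts, spike_ids) {
  counts <- as.matrix(counts)
  missing <- setdiff(spike_ids, rownames(counts))
  if (length(missing) > 0) stop("spike rows absent: ", paste(missing, collapse = ", "))
  spike_tot <- colSums(counts[spike_ids, , drop = FALSE])
  bad <- which(!(spike_tot > 0))
  if (length(bad) > 0) {
    stop("zero spike-in total in sample(s): ",
         paste(colnames(counts)[bad], collapse = ", "))
  }
  tiles <- setdiff(rownames(counts), spike_ids)
  sweep(counts[tiles, , drop = FALSE], 2, spike_tot, `/`)
}

#' Fit a log-linear decay model for one tile
#'
#' Ordinary least squares of `log_base(level)` on time. By default levels
#' are first expressed relative to the geometric mean of the t = 0 samples,
#' which makes the intercept ~0 and the half-life equal to the time to reach
#' 50% of the initial level. Non-positive levels are dropped with a warning.
#'
#' @param timepoints Hours; at least two distinct values with positive levels.
#' @param levels Normalized expression, same length.
#' @param base Log base (default 2, so the slope is in halvings per hour).
#' @param t0_normalize Divide by the t = 0 level before fitting (default TRUE;
#'   requires a 0 timepoint).
#' @return A `decay_fit` list: `intercept`, `slope`, `r_squared`,
#'   `half_life`, `n_points`; or NULL if fewer than 2 usable points remain.
#' @export
fit_decay <- function(timepoints, levels, base = 2, t0_normalize = TRUE) {
  stopifnot(length(timepoints) == length(levels))
  ok <- is.finite(levels) & levels > 0 & is.finite(timepoints)
  if (any(!ok)) warning(sum(!ok), " non-positive/missing level(s) dropped")
  t <- timepoints[ok]; y <- levels[ok]
  if (length(unique(t)) < 2L) return(NULL)
  logy <- log(y, base)
  if (t0_normalize) {
    if (!any(t == 0)) stop("t0_normalize = TRUE requires a 0 timepoint")
    logy <- logy - mean(logy[t == 0])
  }
  fit <- lm(logy ~ t)
  ss_tot <- sum((logy - mean(logy))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_
  out <- list(intercept = unname(fit$coefficients[1]),
              slope = unname(fit$coefficients[2]),
              r_squared = r2, n_points = length(y), base = base)
  out$half_life <- half_life(out, base = base)
  structure(out, class = "decay_fit")
}

#' Half-life from a decay fit
#'
#' Computed as `(log_base(0.5) - intercept) / slope`: the time at which the
#' fitted line crosses 50% of the (t = 0) level. Undefined — returned as
#' `NA` — when the slope is non-negative or the result is non-positive.
#'
#' @param fit A `decay_fit` (or any list with `intercept` and `slope`).
#' @param base Log base of the fit (default 2).
#' @return Half-life in hours, or `NA_real_`.
#' @export
half_life <- function(fit, base = 2) {
  if (is.null(fit) || !is.finite(fit$slope) || fit$slope >= 0) return(NA_real_)
  hl <- (log(0.5, base) - fit$intercept) / fit$slope
  if (!is.finite(hl) || hl <= 0) NA_real_ else hl
}

#' Per-tile decay fits over a normalized count matrix
#'
#' @param norm_counts Tile x sample matrix (e.g. from [spike_normalize]).
#' @param samples Data frame with `sample_id` and `timepoint` (hours);
#'   replicates are fitted jointly as repeated observations per timepoint.
#' @param base,t0_normalize Passed to [fit_decay].
#' @return data.table with `tile_id`, `intercept`, `slope`, `r_squared`,
#'   `half_life`, `n_points`.
#' @export
fit_decay_matrix <- function(norm_counts, samples, base = 2,
                             t0_normalize = TRUE) {
  samples <- as.data.table(samples)
  stopifnot(all(c("sample_id", "timepoint") %in% names(samples)),
            all(samples$sample_id %in% colnames(norm_counts)))
  t <- samples$timepoint
  rows <- lapply(rownames(norm_counts), function(tid) {
    fit <- suppressWarnings(
      fit_decay(t, norm_counts[tid, samples$sample_id], base, t0_normalize))
    if (is.null(fit)) {
      data.table(tile_id = tid, intercept = NA_real_, slope = NA_real_,
                 r_squared = NA_real_, half_life = NA_real_, n_points = 0L)
    } else {
      data.table(tile_id = tid, intercept = fit$intercept, slope = fit$slope,
                 r_squared = fit$r_squared, half_life = fit$half_life,
                 n_points = fit$n_points)
    }
  })
  data.table::rbindlist(rows)
}
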