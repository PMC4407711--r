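# Probe-level thresholding, sliding-window smoothing, and calling of
# whole-chromosome / segmental / focal imbalances from a CGH matrix.

#' Log2-ratio threshold calibrated to tumor-cell fraction
#'
#' A heterozygous single-copy gain present in a fraction `f` of sampled cells
#' shifts the bulk DNA ratio to `1 + f/2`; a single-copy loss to `1 - f/2`.
#' The corresponding log2-ratio detection thresholds at `f = 0.5` are 0.322
#' (gain) and -0.415 (loss).
#'
#' @param f Tumor-cell fraction in (0, 1].
#' @param direction `"gain"` or `"loss"`.
#' @return The log2-ratio threshold (positive for gains, negative for losses).
#' @examples
#' logratio_threshold(0.5, "gain")   # 0.322
#' logratio_threshold(0.5, "loss")   # -0.415
#' @export
logratio_threshold <- function(f, direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  if (any(f <= 0 | f > 1)) abort("cell fraction f must be in (0, 1]")
  if (direction == "gain") log2(1 + f / 2) else log2(1 - f / 2)
}

#' Amplification / deletion threshold pair
#'
#' Bundles the two calling thresholds. By default both are derived from one
#' cell fraction via [logratio_threshold()]; explicit thresholds may be given
#' instead.
#'
#' @param cell_fraction Calibrating tumor-cell fraction (default 0.5).
#' @param amp_threshold,del_threshold Optional explicit log2 thresholds
#'   (amp > 0 > del); both must be given to override the derivation.
#' @return A list of class `threshold_pair` with `amp_threshold`,
#'   `del_threshold`, `cell_fraction`.
#' @export
threshold_pair <- function(cell_fraction = 0.5, amp_threshold = NULL,
                           del_threshold = NULL) {
  if (is.null(amp_threshold) != is.null(del_threshold)) {
    abort("give both explicit thresholds or neither")
  }
  if (is.null(amp_threshold)) {
    amp_threshold <- logratio_threshold(cell_fraction, "gain")
    del_threshold <- logratio_threshold(cell_fraction, "loss")
  }
  if (!(amp_threshold > 0 && del_threshold < 0)) {
    abort("need amp_threshold > 0 > del_threshold")
  }
  structure(
    list(amp_threshold = amp_threshold, del_threshold = del_threshold,
         cell_fraction = cell_fraction),
    class = "threshold_pair"
  )
}

cgh_one_tumor <- function(cgh, tumor_id) {
  out <- cgh[cgh$tumor_id == tumor_id, ]
  if (nrow(out) == 0) abort(sprintf("unknown tumor '%s'", tumor_id))
  arrange(out, .data$chrom, .data$start)
}

#' Sliding-window mean of a CGH profile
#'
#' Averages one tumor's log2 ratios in windows of `window` bp advanced by
#' `step` bp along each chromosome. A probe belongs to a window when its
#' start position lies in the half-open window interval. Empty windows are
#' kept with `mean_log2 = NA`.
#'
#' @param cgh Long CGH tibble.
#' @param tumor_id Tumor to profile.
#' @param window Window width in bp (130 kb default, the usual display
#'   smoothing for a 13-kb-resolution chip).
#' @param step Step between window starts; defaults to `window`
#'   (non-overlapping tiling).
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the maximal probe end per chromosome.
#' @return Tibble `chrom`, `win_start`, `win_end`, `mean_log2`, `n_probes`.
#' @export
sliding_window_mean <- function(cgh, tumor_id, window = 130000, step = window,
                                chrom_lengths = NULL) {
  stopifnot(window > 0, step > 0)
  prof <- cgh_one_tumor(cgh, tumor_id)
  chroms <- unique(prof$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(prof$end, prof$chrom, max)
  }
  map(chroms, function(ch) {
    p <- prof[prof$chrom == ch, ]
    len <- chrom_lengths[[ch]]
    starts <- seq(0, max(0, len - 1), by = step)
    ends <- pmin(starts + window, len)
    idx <- findInterval(p$start, starts)   # valid when step == window
    if (step == window) {
      agg_mean <- tapply(p$log2ratio, factor(idx, levels = seq_along(starts)), mean)
      agg_n <- tapply(p$log2ratio, factor(idx, levels = seq_along(starts)), length)
      n_raw <- as.integer(as.vector(agg_n))
      n <- ifelse(is.na(n_raw), 0L, n_raw)
      m <- as.numeric(as.vector(agg_mean))
    } else {
      m <- rep(NA_real_, length(starts)); n <- integer(length(starts))
      for (w in seq_along(starts)) {
        inw <- p$start >= starts[w] & p$start < ends[w]
        n[w] <- sum(inw)
        if (n[w] > 0) m[w] <- mean(p$log2ratio[inw])
      }
    }
    tibble(chrom = ch, win_start = starts, win_end = ends,
           mean_log2 = m, n_probes = n)
  }) |> list_rbind()
}

# maximal runs of TRUE in a logical vector -> list of (from, to) index pairs
true_runs <- function(x, min_len = 1) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_len
  Map(c, starts[keep], ends[keep])
}

#' Call whole-chromosome, segmental and focal imbalances for one tumor
#'
#' Three-tier calling on one tumor's profile, per direction:
#' \enumerate{
#'   \item \emph{whole chromosome}: at least `coverage_min` of the non-empty
#'     130-kb windows are beyond half the threshold \emph{and} the
#'     chromosome-wide mean is beyond half the threshold (half-threshold
#'     because window and chromosome means are noise-averaged).
#'   \item \emph{window runs}: otherwise, maximal runs of consecutive
#'     non-empty windows beyond half the threshold containing at least
#'     `min_probes_segment` probes become calls; their extent is the probe
#'     extent widened by half the flanking inter-probe gaps.
#'   \item \emph{probe runs}: remaining maximal runs of >= 2 consecutive
#'     probes beyond the full threshold become focal calls.
#' }
#' A call's scale is `segment` when its span reaches `focal_max_span`, else
#' `focal`; large-scale means `whole_chromosome` or `segment`.
#'
#' @param cgh Long CGH tibble.
#' @param tumor_id Tumor to call; `NULL` calls every tumor.
#' @param thresholds A [threshold_pair()].
#' @param coverage_min Window fraction required for a whole-chromosome call.
#' @param min_probes_segment Minimum probes in a window-run call.
#' @param window Window width in bp for the smoothing tier.
#' @param focal_max_span Spans below this (bp) are `focal`, others `segment`.
#' @param chrom_lengths Optional named chromosome lengths.
#' @return Tibble of calls: `tumor_id`, `chrom`, `start`, `end`, `direction`,
#'   `scale`, `mean_log2`, `probe_count`.
#' @export
call_large_scale <- function(cgh, tumor_id = NULL, thresholds = threshold_pair(),
                             coverage_min = 0.8, min_probes_segment = 10,
                             window = 130000, focal_max_span = 1e6,
                             chrom_lengths = NULL) {
  if (is.null(tumor_id)) {
    return(map(unique(cgh$tumor_id), function(tu) {
      call_large_scale(cgh, tu, thresholds, coverage_min, min_probes_segment,
                       window, focal_max_span, chrom_lengths)
    }) |> list_rbind())
  }
  prof <- cgh_one_tumor(cgh, tumor_id)
  wins <- sliding_window_mean(cgh, tumor_id, window = window,
                              chrom_lengths = chrom_lengths)
  if (is.null(chrom_lengths)) chrom_lengths <- tapply(prof$end, prof$chrom, max)
  dirs <- tibble(
    direction = c("gain", "loss"),
    thr = c(thresholds$amp_threshold, thresholds$del_threshold)
  )
  calls <- list()
  for (ch in unique(prof$chrom)) {
    p <- prof[prof$chrom == ch, ]
    w <- wins[wins$chrom == ch & wins$n_probes > 0, ]
    len <- chrom_lengths[[ch]]
    # midpoints between adjacent probes bound each probe's "territory"
    mid <- (head(p$end, -1) + tail(p$start, -1)) / 2
    lo <- c(max(0, p$start[1] - 30), mid)
    hi <- c(mid, min(len, p$end[nrow(p)] + 30))
    for (d in seq_len(2)) {
      thr <- dirs$thr[d]
      beyond <- function(x, t) if (t > 0) x >= t else x <= t
      half_cov <- mean(beyond(w$mean_log2, thr / 2))
      chrom_mean <- mean(p$log2ratio)
      if (nrow(w) > 0 && half_cov >= coverage_min && beyond(chrom_mean, thr / 2)) {
        calls[[length(calls) + 1]] <- tibble(
          tumor_id = tumor_id, chrom = ch, start = 0, end = len,
          direction = dirs$direction[d], scale = "whole_chromosome",
          mean_log2 = chrom_mean, probe_count = nrow(p)
        )
        next
      }
      claimed <- rep(FALSE, nrow(p))
      # tier 2: window runs at half threshold
      for (run in true_runs(beyond(w$mean_log2, thr / 2))) {
        ws <- w$win_start[run[1]]; we <- w$win_end[run[2]]
        inw <- which(p$start >= ws & p$start < we)
        if (length(inw) < min_probes_segment) next
        s <- lo[inw[1]]; e <- hi[inw[length(inw)]]
        m <- mean(p$log2ratio[inw])
        if (!beyond(m, thr / 2)) next
        claimed[inw] <- TRUE
        calls[[length(calls) + 1]] <- tibble(
          tumor_id = tumor_id, chrom = ch, start = s, end = e,
          direction = dirs$direction[d],
          scale = if (e - s >= focal_max_span) "segment" else "focal",
          mean_log2 = m, probe_count = length(inw)
        )
      }
      # tier 3: probe runs at full threshold, outside claimed territory
      for (run in true_runs(beyond(p$log2ratio, thr) & !claimed, min_len = 2)) {
        inw <- run[1]:run[2]
        calls[[length(calls) + 1]] <- tibble(
          tumor_id = tumor_id, chrom = ch, start = lo[inw[1]],
          end = hi[inw[length(inw)]], direction = dirs$direction[d],
          scale = if (hi[inw[length(inw)]] - lo[inw[1]] >= focal_max_span)
            "segment" else "focal",
          mean_log2 = mean(p$log2ratio[inw]), probe_count = length(inw)
        )
      }
    }
  }
  if (length(calls) == 0) {
    return(tibble(
      tumor_id = character(), chrom = character(), start = numeric(),
      end = numeric(), direction = character(), scale = character(),
      mean_log2 = numeric(), probe_count = integer()
    ))
  }
  list_rbind(calls) |> arrange(.data$chrom, .data$start)
}

#' Recurrently altered probes
#'
#' A probe is amplified-recurrent when its log2 ratio reaches the
#' amplification threshold in at least `min_tumors` tumors, and
#' deleted-recurrent symmetrically; a probe can be both (in different
#' tumors).
#'
#' @param cgh Long CGH tibble.
#' @param thresholds A [threshold_pair()].
#' @param min_tumors Minimum number of tumors (2 = the recurrence rule).
#' @return Tibble `probe_id`, `chrom`, `start`, `end`, `direction`,
#'   `n_tumors`, `tumors` (list column of carrier tumor ids).
#' @export
recurrent_altered_probes <- function(cgh, thresholds = threshold_pair(),
                                     min_tumors = 2) {
  stopifnot(min_tumors >= 1)
  one_dir <- function(dir, keep) {
    cgh[keep, ] |>
      group_by(.data$probe_id, .data$chrom, .data$start, .data$end) |>
      summarise(n_tumors = n(), tumors = list(sort(.data$tumor_id)),
                .groups = "drop") |>
      filter(.data$n_tumors >= min_tumors) |>
      mutate(direction = dir, .after = "end")
  }
  bind_rows(
    one_dir("gain", cgh$log2ratio >= thresholds$amp_threshold),
    one_dir("loss", cgh$log2ratio <= thresholds$del_threshold)
  ) |> arrange(.data$chrom, .data$start, .data$direction)
}
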