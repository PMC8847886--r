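#' Censor high-motion time points
#'
#' Flags time points whose framewise displacement (FD) exceeds
#' `fd_threshold` for removal, then additionally removes any surviving
#' sub-threshold segment shorter than `min_segment` consecutive time points,
#' so that only segments of `min_segment` or more low-motion points are
#' preserved.
#'
#' @param fd numeric vector of FD values (mm), one per time point.
#' @param fd_threshold censoring threshold in mm (default 0.3).
#' @param min_segment minimum length of a kept low-motion segment (default 5).
#' @return logical vector `keep`, same length as `fd`.
#' @examples
#' censor_timepoints(c(0.1, 0.1, 0.1, 0.5, rep(0.1, 6)))
#' @export
censor_timepoints <- function(fd, fd_threshold = 0.3, min_segment = 5) {
  if (length(fd) == 0L) stop("`fd` must be non-empty", call. = FALSE)
  if (any(fd < 0)) stop("FD values must be non-negative", call. = FALSE)
  keep <- fd <= fd_threshold
  r <- rle(keep)
  r$values <- r$values & r$lengths >= min_segment
  inverse.rle(r)
}

#' Is a resting-state run usable?
#'
#' A run is good iff its mean FD is strictly below `fd_threshold` and its
#' pre-censoring length is at least `ceiling(min_frac * expected_length)`
#' time points (at the defaults, at least 190 of 380 expected points).
#'
#' @param fd numeric FD trace of the run (mm).
#' @param expected_length nominal acquisition length in time points.
#' @param fd_threshold mean-FD cutoff (strict inequality).
#' @param min_frac minimum fraction of the expected length.
#' @return logical scalar.
#' @export
run_is_good <- function(fd, expected_length = 380, fd_threshold = 0.3,
                        min_frac = 0.5) {
  mean(fd) < fd_threshold && length(fd) >= ceiling(min_frac * expected_length)
}

#' Number of time points in a scan duration
#'
#' Bookkeeping helper converting seconds of scan time to time points at a
#' given repetition time (10 min at TR 0.8 s gives 750 points).
#'
#' @param seconds scan duration in seconds.
#' @param tr repetition time in seconds.
#' @return integer number of time points.
#' @examples
#' scan_timepoints(600, tr = 0.8)
#' @export
scan_timepoints <- function(seconds, tr = 0.8) {
  as.integer(round(seconds / tr))
}

#' Select subjects by motion and QC criteria
#'
#' Applies the imaging-side inclusion rules in order: (1) at least
#' `min_good_runs` good runs (see [run_is_good()]); (2) at least
#' `min_post_censor` post-censoring time points summed over good runs;
#' (3) subject mean FD (over good runs) not in the top or bottom
#' `trim_frac` of the distribution of subjects surviving criteria 1-2;
#' (4) anatomical QC pass. Each excluded subject is ledgered under the first
#' criterion it fails, in this order.
#'
#' @param runs tibble with `subject_id`, `run_index`, `expected_length` and a
#'   list-column `fd`, as produced by [generate_motion_table()].
#' @param qc tibble with `subject_id`, `t1_pass`.
#' @param fd_threshold,min_segment censoring parameters, see
#'   [censor_timepoints()].
#' @param min_good_runs minimum number of good runs (default 2).
#' @param min_post_censor minimum total post-censor points (default 750).
#' @param trim_frac fraction trimmed from each tail of the mean-FD
#'   distribution (default 0.0025); bounds use linear-interpolation
#'   quantiles and exclusion is strictly beyond the quantile.
#' @return a list with `included` (character vector of subject ids),
#'   `ledger` (tibble: `subject_id`, `reason`) and `summary` (tibble of
#'   per-criterion exclusion counts).
#' @export
select_subjects <- function(runs, qc, fd_threshold = 0.3, min_segment = 5,
                            min_good_runs = 2, min_post_censor = 750,
                            trim_frac = 0.0025) {
  per_run <- runs |>
    dplyr::mutate(
      good = purrr::map2_lgl(.data$fd, .data$expected_length,
                             ~ run_is_good(.x, .y, fd_threshold = fd_threshold)),
      post_censor = purrr::map_int(.data$fd, ~ sum(censor_timepoints(
        .x, fd_threshold = fd_threshold, min_segment = min_segment))),
      mean_fd = purrr::map_dbl(.data$fd, mean)
    )
  per_subj <- per_run |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_good = sum(.data$good),
      post_censor_points = sum(.data$post_censor[.data$good]),
      mean_fd = mean(.data$mean_fd[.data$good]),
      .groups = "drop"
    )
  if (anyDuplicated(per_subj$subject_id)) {
    stop("duplicate subject ids in `runs`", call. = FALSE)
  }
  if (anyDuplicated(qc$subject_id)) stop("duplicate subject ids in `qc`", call. = FALSE)
  per_subj <- dplyr::left_join(per_subj, qc, by = "subject_id")
  per_subj$t1_pass[is.na(per_subj$t1_pass)] <- FALSE

  fail1 <- per_subj$n_good < min_good_runs
  fail2 <- !fail1 & per_subj$post_censor_points < min_post_censor
  candidates <- !fail1 & !fail2
  lo <- stats::quantile(per_subj$mean_fd[candidates], trim_frac, type = 7, names = FALSE)
  hi <- stats::quantile(per_subj$mean_fd[candidates], 1 - trim_frac, type = 7, names = FALSE)
  fail3 <- candidates & (per_subj$mean_fd < lo | per_subj$mean_fd > hi)
  fail4 <- candidates & !fail3 & !per_subj$t1_pass

  reason <- rep(NA_character_, nrow(per_subj))
  reason[fail4] <- "qc_fail"
  reason[fail3] <- "mean_fd_anomalous"
  reason[fail2] <- "insufficient_good_time"
  reason[fail1] <- "too_few_good_runs"

  ledger <- tibble::tibble(subject_id = per_subj$subject_id, reason = reason) |>
    dplyr::filter(!is.na(.data$reason))
  included <- per_subj$subject_id[is.na(reason)]
  summary <- tibble::tibble(
    reason = c("too_few_good_runs", "insufficient_good_time",
               "mean_fd_anomalous", "qc_fail"),
    n = c(sum(fail1), sum(fail2), sum(fail3), sum(fail4))
  )
  list(included = included, ledger = ledger, summary = summary)
}

#' Censor, concatenate and truncate a subject's runs
#'
#' Applies censor masks to each run, concatenates the surviving time points
#' in acquisition order, and truncates to exactly `target_points`.
#'
#' @param runs list of per-run matrices (`T_r x N`) or vectors in
#'   acquisition order.
#' @param masks list of logical keep-masks, one per run (e.g. from
#'   [censor_timepoints()]).
#' @param target_points output length (default 750, i.e. 10 min at
#'   TR = 0.8 s).
#' @return a matrix (or vector) with exactly `target_points` rows.
#' @export
truncate_concatenate <- function(runs, masks, target_points = 750) {
  stopifnot(length(runs) == length(masks))
  kept <- purrr::map2(runs, masks, function(r, m) {
    if (is.matrix(r)) {
      stopifnot(nrow(r) == length(m))
      r[m, , drop = FALSE]
    } else {
      stopifnot(length(r) == length(m))
      r[m]
    }
  })
  out <- if (is.matrix(kept[[1]])) do.call(rbind, kept) else unlist(kept, use.names = FALSE)
  n_avail <- if (is.matrix(out)) nrow(out) else length(out)
  if (n_avail < target_points) {
    stop(sprintf("only %d post-censor time points available; %d required (subject should have been excluded)",
                 n_avail, target_points), call. = FALSE)
  }
  if (is.matrix(out)) out[seq_len(target_points), , drop = FALSE] else out[seq_len(target_points)]
}

#' Summarize sequential exclusion counts
#'
#' Bookkeeping helper: given the number of candidates entering a sequential
#' filter and the count dropped at each criterion, reports the per-criterion
#' counts, the total dropped, and the number remaining.
#'
#' @param n_total number of records entering the filter.
#' @param dropped named or unnamed integer vector of counts dropped per
#'   criterion (in order).
#' @return tibble with one row per criterion plus `total_dropped` and
#'   `remaining` rows in a `quantity`/`n` layout.
#' @examples
#' filter_accounting(10038, c(434, 1743, 9, 40))
#' @export
filter_accounting <- function(n_total, dropped) {
  total <- sum(dropped)
  if (total > n_total) stop("more records dropped than available", call. = FALSE)
  labels <- names(dropped) %||% paste0("criterion_", seq_along(dropped))
  tibble::tibble(
    quantity = c(labels, "total_dropped", "remaining"),
    n = c(as.integer(dropped), as.integer(total), as.integer(n_total - total))
  )
}
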