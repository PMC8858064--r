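# Per-second detection scoring.  Predicted and reference annotations are
# compared as sets of flagged seconds over a session of `total` seconds, per
# category, with
#   detection = seconds the detector flagged,
#   wrong     = flagged seconds absent from the reference,
#   miss      = reference seconds the detector did not flag,
# and the derived rates
#   TPR = (detection - wrong) / (detection - wrong + miss) * 100
#   SPC = (total - detection - miss) / (total - detection - miss + wrong) * 100.
# Treating each second as one trial, TPR is the usual sensitivity
# TP / (TP + FN) with TP = detection - wrong, FN = miss, and SPC the
# specificity TN / (TN + FP) with TN = total - detection - miss, FP = wrong.

#' Construct per-category detection counts
#'
#' @param detection,wrong,miss non-negative integer counts of flagged,
#'   falsely flagged and missed seconds.
#' @param total session length in seconds (positive).
#' @return an `eval_counts` object.
#' @export
eval_counts <- function(detection, wrong, miss, total) {
  if (any(c(detection, wrong, miss) < 0) || total <= 0) {
    stop("counts must be >= 0 and total > 0", call. = FALSE)
  }
  if (wrong > detection) {
    stop("wrong (", wrong, ") cannot exceed detection (", detection, ")",
         call. = FALSE)
  }
  if (detection - wrong + miss > total) {
    stop("detection - wrong + miss cannot exceed total", call. = FALSE)
  }
  structure(list(detection = as.integer(detection), wrong = as.integer(wrong),
                 miss = as.integer(miss), total = as.integer(total)),
            class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("<eval_counts> detection %d  wrong %d  miss %d  / %d s\n",
              x$detection, x$wrong, x$miss, x$total))
  invisible(x)
}

#' Detection counts from predicted and reference flagged-second sets
#'
#' @param predicted,reference integer vectors of flagged seconds, 0-based,
#'   each a subset of `0:(total - 1)`.
#' @param total session length in seconds.
#' @return an `eval_counts` object.
#' @export
confusion_counts <- function(predicted, reference, total) {
  predicted <- unique(as.integer(predicted))
  reference <- unique(as.integer(reference))
  for (s in list(predicted, reference)) {
    if (length(s) && (min(s) < 0 || max(s) >= total)) {
      stop("flagged second outside 0..total-1", call. = FALSE)
    }
  }
  eval_counts(detection = length(predicted),
              wrong = length(setdiff(predicted, reference)),
              miss = length(setdiff(reference, predicted)),
              total = total)
}

#' Sensitivity (TPR) and specificity (SPC) of detection counts
#'
#' Exact fractions in percent.  When the denominator is zero (no positive
#' seconds exist for TPR; every second positive for SPC) the metric is
#' undefined and `NA` is returned rather than 0.
#'
#' @param counts an `eval_counts` object.
#' @return percent value in [0, 100], or `NA_real_` when undefined.
#' @export
tpr <- function(counts) {
  tp <- counts$detection - counts$wrong
  den <- tp + counts$miss
  if (den <= 0) return(NA_real_)
  tp / den * 100
}

#' @rdname tpr
#' @export
spc <- function(counts) {
  tn <- counts$total - counts$detection - counts$miss
  den <- tn + counts$wrong
  if (den <= 0) return(NA_real_)
  tn / den * 100
}

# Half-up rounding (0.005 -> 0.01), matching the conventional table
# formatting; base round() rounds half to even.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Flagged seconds of one category in an annotation track
#'
#' Maps events at 1-second granularity onto the 0-based seconds they cover
#' (an event spanning `[onset, onset + duration)` covers every second-window
#' it overlaps).
#'
#' @param track an `annotation_track`.
#' @param label category label to extract.
#' @param t0 clock origin subtracted from onsets (default 0).
#' @return sorted integer vector of flagged seconds.
#' @export
track_seconds <- function(track, label, t0 = 0) {
  ev <- track[track$label == label, , drop = FALSE]
  if (!nrow(ev)) return(integer(0))
  secs <- unlist(lapply(seq_len(nrow(ev)), function(k) {
    a <- ev$onset[k] - t0
    b <- a + ev$duration[k]
    lo <- floor(a + 1e-9)
    hi <- ceiling(b - 1e-9) - 1
    seq.int(lo, hi)
  }))
  sort(unique(as.integer(secs)))
}

#' Score annotation tracks against a reference, per category
#'
#' Each category (`blink_left`, `blink_right`, `head_micro`, `head_distinct`)
#' is scored as an independent binary per-second detection problem.  Reported
#' `tpr`/`spc` are rounded half-up to 2 decimals; `tpr_exact`/`spc_exact`
#' carry the unrounded fractions.
#'
#' @param tracks named list of `annotation_track`s to score.
#' @param reference the reference `annotation_track`.
#' @param total session length in seconds.
#' @param categories category labels to score (default the full vocabulary).
#' @param t0 clock origin shared by all tracks.
#' @return an `eval_report` data frame with columns `track`, `category`,
#'   `detection`, `wrong`, `miss`, `tpr`, `spc`, `tpr_exact`, `spc_exact`.
#' @export
evaluate_report <- function(tracks, reference, total,
                            categories = ANNOTATION_LABELS, t0 = 0) {
  if (inherits(tracks, "annotation_track")) tracks <- list(predicted = tracks)
  bad <- setdiff(categories, ANNOTATION_LABELS)
  if (length(bad)) {
    stop("unknown category label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (tr in c(tracks, list(reference))) {
    unknown <- setdiff(unique(tr$label), ANNOTATION_LABELS)
    if (length(unknown)) {
      stop("track contains unknown label(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  rows <- lapply(names(tracks), function(nm) {
    do.call(rbind, lapply(categories, function(cat) {
      cc <- confusion_counts(track_seconds(tracks[[nm]], cat, t0),
                             track_seconds(reference, cat, t0), total)
      data.frame(track = nm, category = cat, detection = cc$detection,
                 wrong = cc$wrong, miss = cc$miss,
                 tpr = round_half_up(tpr(cc)), spc = round_half_up(spc(cc)),
                 tpr_exact = tpr(cc), spc_exact = spc(cc))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("eval_report", "data.frame"))
}

#' Write an evaluation report as CSV
#' @param report an `eval_report`.
#' @param path output CSV.
#' @export
write_report_csv <- function(report, path) {
  cols <- c("track", "category", "detection", "wrong", "miss", "tpr", "spc")
  utils::write.csv(as.data.frame(report)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(NULL)
}
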