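# Interval label tracks: TSV I/O, two-rater merging with the 200 ms
# boundary rule, projection onto the 0.195 s frame grid, Cohen's kappa.

LABEL_SET <- c("exhalation_acoustic", "exhalation_airflow", "inhalation",
               "nonbreathing", "unclear")

#' Construct a label track
#'
#' Ordered, non-overlapping, half-open `[start_s, end_s)` intervals with
#' phase labels. Gaps between intervals are implicitly nonbreathing.
#'
#' @param start_s,end_s interval boundaries in seconds (start < end).
#' @param label labels from `exhalation_acoustic`, `exhalation_airflow`,
#'   `inhalation`, `nonbreathing`, `unclear`.
#' @param duration_s track duration; defaults to the last interval end.
#' @return A `label_track` data.frame with a `duration_s` attribute.
#' @export
label_track <- function(start_s = numeric(0), end_s = numeric(0),
                        label = character(0), duration_s = NULL) {
  stopifnot(length(start_s) == length(end_s),
            length(start_s) == length(label))
  label <- as.character(label)
  if (!all(label %in% LABEL_SET)) {
    stop(sprintf("label_track: unknown label(s): %s",
                 paste(setdiff(label, LABEL_SET), collapse = ", ")),
         call. = FALSE)
  }
  if (any(start_s >= end_s)) {
    stop("label_track: intervals must satisfy start < end", call. = FALSE)
  }
  ord <- order(start_s)
  df <- data.frame(start_s = start_s[ord], end_s = end_s[ord],
                   label = label[ord], stringsAsFactors = FALSE)
  if (nrow(df) > 1L && any(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-9)) {
    stop("label_track: intervals must not overlap", call. = FALSE)
  }
  if (is.null(duration_s)) duration_s <- if (nrow(df)) max(df$end_s) else 0
  structure(df, class = c("label_track", "data.frame"),
            duration_s = duration_s)
}

#' Read a label track TSV (columns start_s, end_s, label)
#' @param path TSV path.
#' @param duration_s optional track duration.
#' @return A `label_track`.
#' @export
read_label_track <- function(path, duration_s = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  label_track(df$start_s, df$end_s, df$label, duration_s)
}

#' Write a label track TSV
#' @param track a `label_track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_track <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("start_s", "end_s", "label")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Overlap length of [a1,a2) and [b1,b2)
.overlap <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))

#' Merge two raters' label tracks
#'
#' Intervals from the two raters are paired by temporal overlap (greedy,
#' largest overlap first, each interval used once). For a matched pair,
#' boundaries at most 200 ms apart are averaged; a pair whose start or
#' end differs by more than 200 ms is flagged for manual resolution and
#' excluded from the merged track. Matched pairs with different class
#' labels become `unclear`, as do intervals only one rater annotated
#' (the other rater's implicit nonbreathing contradicts them).
#'
#' @param a,b `label_track`s over the same recording.
#' @param boundary_tol_s boundary tolerance in seconds (default 0.2).
#' @return List with `merged` (a `label_track`), `flags` (data.frame of
#'   boundary pairs needing manual inspection) and `conflicts`
#'   (data.frame of class-conflict segments).
#' @export
merge_raters <- function(a, b, boundary_tol_s = 0.2) {
  stopifnot(inherits(a, "label_track"), inherits(b, "label_track"))
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || nb == 0L) {
    stop("merge_raters: both tracks must contain intervals", call. = FALSE)
  }
  ov <- outer(seq_len(na), seq_len(nb), function(i, j) {
    .overlap(a$start_s[i], a$end_s[i], b$start_s[j], b$end_s[j])
  })
  pairs <- list()
  used_a <- logical(na); used_b <- logical(nb)
  repeat {
    best <- which(ov == max(ov), arr.ind = TRUE)[1, , drop = TRUE]
    if (ov[best[1], best[2]] <= 0) break
    pairs[[length(pairs) + 1L]] <- best
    used_a[best[1]] <- TRUE; used_b[best[2]] <- TRUE
    ov[best[1], ] <- -1; ov[, best[2]] <- -1
  }
  merged_start <- numeric(0); merged_end <- numeric(0); merged_lab <- character(0)
  flags <- data.frame(rater_a_start = numeric(0), rater_a_end = numeric(0),
                      rater_b_start = numeric(0), rater_b_end = numeric(0),
                      label_a = character(0), label_b = character(0))
  conflicts <- data.frame(start_s = numeric(0), end_s = numeric(0),
                          label_a = character(0), label_b = character(0))
  for (p in pairs) {
    ia <- p[1]; ib <- p[2]
    d_start <- abs(a$start_s[ia] - b$start_s[ib])
    d_end <- abs(a$end_s[ia] - b$end_s[ib])
    if (d_start > boundary_tol_s || d_end > boundary_tol_s) {
      flags <- rbind(flags, data.frame(
        rater_a_start = a$start_s[ia], rater_a_end = a$end_s[ia],
        rater_b_start = b$start_s[ib], rater_b_end = b$end_s[ib],
        label_a = a$label[ia], label_b = b$label[ib]))
      next
    }
    s <- (a$start_s[ia] + b$start_s[ib]) / 2
    e <- (a$end_s[ia] + b$end_s[ib]) / 2
    if (identical(a$label[ia], b$label[ib])) {
      lab <- a$label[ia]
    } else {
      lab <- "unclear"
      conflicts <- rbind(conflicts, data.frame(
        start_s = s, end_s = e, label_a = a$label[ia], label_b = b$label[ib]))
    }
    merged_start <- c(merged_start, s); merged_end <- c(merged_end, e)
    merged_lab <- c(merged_lab, lab)
  }
  for (ia in which(!used_a)) {
    merged_start <- c(merged_start, a$start_s[ia])
    merged_end <- c(merged_end, a$end_s[ia])
    merged_lab <- c(merged_lab, "unclear")
    conflicts <- rbind(conflicts, data.frame(
      start_s = a$start_s[ia], end_s = a$end_s[ia],
      label_a = a$label[ia], label_b = "nonbreathing"))
  }
  for (ib in which(!used_b)) {
    merged_start <- c(merged_start, b$start_s[ib])
    merged_end <- c(merged_end, b$end_s[ib])
    merged_lab <- c(merged_lab, "unclear")
    conflicts <- rbind(conflicts, data.frame(
      start_s = b$start_s[ib], end_s = b$end_s[ib],
      label_a = "nonbreathing", label_b = b$label[ib]))
  }
  dur <- max(attr(a, "duration_s"), attr(b, "duration_s"))
  list(merged = label_track(merged_start, merged_end, merged_lab,
                            duration_s = dur),
       flags = flags, conflicts = conflicts)
}

#' Project a label track onto the 0.195 s frame grid
#'
#' Frame i covers `[i*0.195, (i+1)*0.195)`. Each frame takes the label
#' with the largest temporal overlap; track gaps count as nonbreathing;
#' exhalation subtypes collapse to `exhalation`. A frame overlapping an
#' `unclear` interval by any amount is masked out. Overlap ties break by
#' priority exhalation > inhalation > nonbreathing.
#'
#' @param track a `label_track`.
#' @param n_frames number of frames to label.
#' @param frame_s frame duration (default 0.195).
#' @return List with `labels` (character, one of the three phases) and
#'   `mask` (logical; TRUE = usable frame).
#' @export
frame_labels <- function(track, n_frames, frame_s = FRAME_SECONDS) {
  stopifnot(inherits(track, "label_track"), n_frames >= 0)
  collapse <- function(l) {
    ifelse(l %in% c("exhalation_acoustic", "exhalation_airflow"),
           "exhalation", l)
  }
  labels <- character(n_frames)
  mask <- rep(TRUE, n_frames)
  phase_order <- c("exhalation", "inhalation", "nonbreathing")
  for (i in seq_len(n_frames)) {
    f0 <- (i - 1) * frame_s; f1 <- i * frame_s
    ov <- .overlap(track$start_s, track$end_s, f0, f1)
    hit <- ov > 1e-12
    if (any(hit & track$label == "unclear")) {
      mask[i] <- FALSE
      labels[i] <- NA_character_
      next
    }
    acc <- c(exhalation = 0, inhalation = 0, nonbreathing = 0)
    if (any(hit)) {
      for (k in which(hit)) {
        cl <- collapse(track$label[k])
        acc[cl] <- acc[cl] + ov[k]
      }
    }
    acc["nonbreathing"] <- acc["nonbreathing"] + (frame_s - sum(ov[hit]))
    best <- max(acc)
    labels[i] <- phase_order[which(acc[phase_order] >= best - 1e-12)[1]]
  }
  list(labels = labels, mask = mask)
}

#' Cohen's kappa between two frame label sequences
#'
#' Multi-class chance-corrected agreement from the cross-tabulation of
#' the two sequences; pairs where either side is NA (masked) are
#' dropped.
#'
#' @param a_frames,b_frames equal-length label sequences.
#' @return List with `p_o`, `p_e` and `kappa`.
#' @export
cohen_kappa <- function(a_frames, b_frames) {
  stopifnot(length(a_frames) == length(b_frames))
  keep <- !is.na(a_frames) & !is.na(b_frames)
  a <- as.character(a_frames[keep]); b <- as.character(b_frames[keep])
  if (length(a) == 0L) stop("cohen_kappa: no jointly unmasked frames", call. = FALSE)
  lv <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = lv), factor(b, levels = lv))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)
  list(p_o = p_o, p_e = p_e, kappa = kappa)
}
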