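# Ordered-threshold decision policy and threshold diagnostics
# (Youden J search, TPR-by-threshold curves).

#' Threshold policy for turning class probabilities into a phase call
#'
#' In `ordered` mode the exhalation probability is checked against its
#' threshold first, then the inhalation probability; if neither clears,
#' the call is nonbreathing. Comparison is inclusive (`p >= tau`). In
#' `max` mode the most probable class wins.
#'
#' @param mode `"ordered"` (default) or `"max"`.
#' @param tau_exhalation,tau_inhalation thresholds in `[0, 1]`
#'   (default 0.3 each).
#' @return A `threshold_policy` object.
#' @export
threshold_policy <- function(mode = c("ordered", "max"),
                             tau_exhalation = 0.3, tau_inhalation = 0.3) {
  mode <- match.arg(mode)
  stopifnot(tau_exhalation >= 0, tau_exhalation <= 1,
            tau_inhalation >= 0, tau_inhalation <= 1)
  structure(list(mode = mode, tau_exhalation = tau_exhalation,
                 tau_inhalation = tau_inhalation),
            class = "threshold_policy")
}

#' Apply a threshold policy to class probabilities
#'
#' @param p named probability vector over
#'   (exhalation, inhalation, nonbreathing), or a matrix with one row per
#'   item.
#' @param policy a [threshold_policy()].
#' @return Phase label(s) as character.
#' @export
apply_policy <- function(p, policy = threshold_policy()) {
  stopifnot(inherits(policy, "threshold_policy"))
  P <- if (is.null(dim(p))) matrix(p, nrow = 1) else p
  if (ncol(P) != N_CLASSES) stop("apply_policy: need 3 class probabilities", call. = FALSE)
  out <- if (policy$mode == "max") {
    PHASES[max.col(P, ties.method = "first")]
  } else {
    ifelse(P[, 1] >= policy$tau_exhalation, PHASES[1],
           ifelse(P[, 2] >= policy$tau_inhalation, PHASES[2], PHASES[3]))
  }
  if (is.null(dim(p))) out[1] else out
}

#' Youden-J-optimal threshold for one class score
#'
#' Evaluates J = sensitivity + specificity - 1 at every candidate
#' threshold (the distinct observed scores plus 0 and 1; J is piecewise
#' constant between observed scores) under the decision rule
#' `score >= tau -> positive`, and returns the maximiser. Ties go to the
#' smallest threshold.
#'
#' @param scores numeric scores.
#' @param labels logical/0-1 vector of positives; both classes required.
#' @return List with `table` (tau, sensitivity, specificity, youden_j),
#'   `optimal_tau` and `optimal_j`.
#' @export
youden_optimal_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (all(labels) || !any(labels)) {
    stop("youden_optimal_threshold: J undefined with single-class labels",
         call. = FALSE)
  }
  taus <- sort(unique(c(0, 1, scores)))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  sens <- vapply(taus, function(tau) sum(scores >= tau & labels) / n_pos, numeric(1))
  spec <- vapply(taus, function(tau) sum(scores < tau & !labels) / n_neg, numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))[1] # taus sorted ascending: first max = smallest tau
  list(table = data.frame(tau = taus, sensitivity = sens,
                          specificity = spec, youden_j = j),
       optimal_tau = taus[best], optimal_j = j[best])
}

#' Per-class true-positive rates over a threshold grid
#'
#' For each candidate threshold tau the same value is applied to both
#' breathing classes under the ordered policy (exhalation first), every
#' item is classified, and the per-class recall is reported.
#'
#' @param probs matrix of class probabilities (rows = items, columns in
#'   phase order).
#' @param labels true phase labels.
#' @param grid numeric vector of thresholds in `[0, 1]`.
#' @return data.frame with tau and one TPR column per phase.
#' @export
tpr_by_threshold <- function(probs, labels, grid) {
  if (length(grid) == 0L) stop("tpr_by_threshold: empty threshold grid", call. = FALSE)
  stopifnot(all(grid >= 0), all(grid <= 1))
  labels <- as.character(labels)
  res <- lapply(grid, function(tau) {
    pred <- apply_policy(probs, threshold_policy("ordered", tau, tau))
    vapply(PHASES, function(cl) {
      n_cl <- sum(labels == cl)
      if (n_cl == 0L) NA_real_ else sum(pred == cl & labels == cl) / n_cl
    }, numeric(1))
  })
  out <- data.frame(tau = grid, do.call(rbind, res))
  names(out) <- c("tau", paste0("tpr_", PHASES))
  out
}
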