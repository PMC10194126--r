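#' Normalize a fiber trial by its bracketing reference contractions
#'
#' Divides the trial force by the degradation-corrected maximal force —
#' obtained by linear interpolation between the plateau forces of the
#' isometric reference contractions that bracket the trial's block, evaluated
#' at the trial's position within the block — and the fiber length by the
#' fiber's optimal length. A trial that is the j-th of k perturbation trials
#' in its block sits at fraction `j / (k + 1)` between the two references.
#'
#' @param trial a `fiber_trial` (kind `"perturbation"`).
#' @param session the `fiber_session` the trial belongs to.
#' @return a `normalized_trial`: data.frame `t_s, lce_norm, vce_norm_per_s,
#'   f_norm` with condition attributes (`fiber_id`, `scenario`,
#'   `speed_condition`, `activity`, `divisor_mN`).
#' @export
normalize_trial <- function(trial, session) {
  stopifnot(inherits(trial, "fiber_trial"),
            inherits(session, "fiber_session"))
  if (trial$kind != "perturbation") stop("only perturbation trials are normalized")
  man <- session$manifest
  row <- man[man$seed == trial$rng_seed & man$fiber == trial$fiber_id, ]
  if (nrow(row) != 1) stop("trial not found in the session manifest")
  ix <- row$trial_index
  fib <- man[man$fiber == trial$fiber_id, ]
  refs <- fib[fib$kind == "isometric_reference", "trial_index"]
  pre <- suppressWarnings(max(refs[refs < ix]))
  post <- suppressWarnings(min(refs[refs > ix]))
  if (!is.finite(pre) || !is.finite(post)) {
    stop("no bracketing reference contractions for block ", row$block,
         " of fiber ", trial$fiber_id)
  }
  plateau <- function(k) {
    d <- session$trials[[k]]$data
    mean(d$force_mN[d$t_s >= max(d$t_s) * 0.9])
  }
  in_block <- fib[fib$kind == "perturbation" & fib$block == row$block,
                  "trial_index"]
  j <- match(ix, sort(in_block)); k <- length(in_block)
  frac <- j / (k + 1)
  divisor <- (1 - frac) * plateau(pre) + frac * plateau(post)
  l_opt <- trial$fiber$l_opt_mm
  out <- data.frame(t_s = trial$data$t_s,
                    lce_norm = trial$data$length_mm / l_opt,
                    vce_norm_per_s = trial$data$velocity_mm_s / l_opt,
                    f_norm = trial$data$force_mN / divisor)
  attr(out, "fiber_id") <- trial$fiber_id
  attr(out, "scenario") <- trial$scenario
  attr(out, "speed_condition") <- trial$speed_condition
  attr(out, "activity") <- trial$activity
  attr(out, "divisor_mN") <- divisor
  class(out) <- c("normalized_trial", "data.frame")
  out
}

#' Preflex analysis window of a normalized trial
#'
#' Dynamic trials are windowed to the first 30 ms after stretch onset; for
#' quasistatic trials the window runs from the start until the fiber length
#' first reaches `matched_end_length` — the end-of-preflex length of the
#' matching dynamic condition — so the two speed conditions cover the same
#' stretch. Window boundaries are linearly interpolated so windows are
#' comparable across conditions.
#'
#' @param trial a `normalized_trial` (or any data.frame with `t_s`,
#'   `lce_norm`, `f_norm`).
#' @param t_px preflex duration \[s\] for dynamic trials.
#' @param matched_end_length end-of-preflex normalized length of the matching
#'   dynamic condition; required for quasistatic trials.
#' @return the windowed segment (same columns), with attributes preserved and
#'   `window_end_length` attached.
#' @export
preflex_window <- function(trial, t_px = 0.030, matched_end_length = NULL) {
  speed <- attr(trial, "speed_condition")
  if (identical(speed, "quasistatic") || !is.null(matched_end_length)) {
    if (is.null(matched_end_length)) {
      stop("quasistatic trials need `matched_end_length`")
    }
    if (matched_end_length <= trial$lce_norm[1]) {
      stop("matched end length is not above the start length")
    }
    hit <- which(trial$lce_norm >= matched_end_length)
    if (!length(hit)) {
      stop("trial never reaches the matched end length ",
           format(matched_end_length))
    }
    seg <- clip_segment_at_length(trial, matched_end_length)
  } else {
    keep <- trial$t_s <= t_px + 1e-12
    seg <- trial[keep, , drop = FALSE]
  }
  for (at in c("fiber_id", "scenario", "speed_condition", "activity")) {
    attr(seg, at) <- attr(trial, at)
  }
  attr(seg, "window_end_length") <- seg$lce_norm[nrow(seg)]
  seg
}

# cut a monotone-lengthening segment at an exact length, interpolating the
# boundary sample linearly
clip_segment_at_length <- function(trial, l_end) {
  i <- which(trial$lce_norm >= l_end)[1]
  seg <- trial[seq_len(i), , drop = FALSE]
  if (i > 1 && trial$lce_norm[i] > l_end) {
    w <- (l_end - trial$lce_norm[i - 1]) /
      (trial$lce_norm[i] - trial$lce_norm[i - 1])
    num <- vapply(seg, is.numeric, logical(1))
    seg[i, num] <- (1 - w) * unlist(trial[i - 1, num]) +
      w * unlist(trial[i, num])
  }
  seg
}

#' Mechanical work of a force-length segment
#'
#' Trapezoidal integral of the normalized force over the normalized length.
#' Positive when the fiber resists lengthening (energy absorbed by the
#' fiber).
#'
#' @param segment data.frame with `lce_norm` and `f_norm`.
#' @return work in `F_max * l_opt` units.
#' @export
mechanical_work <- function(segment) {
  if (nrow(segment) < 2) stop("need at least 2 samples to integrate")
  l <- segment$lce_norm; f <- segment$f_norm
  sum(diff(l) * (f[-1] + f[-length(f)]) / 2)
}

#' Short-range stiffness of a segment
#'
#' Ordinary least-squares slope of normalized force versus normalized length
#' restricted to the short-range-stiffness window (default 0.57 to 0.59
#' l_opt: from force onset to where the force responses start to deviate with
#' stretch velocity).
#'
#' @param segment data.frame with `lce_norm` and `f_norm`; must cover the
#'   window.
#' @param window length bounds of the fit \[l_opt\].
#' @return stiffness in `F_max / l_opt` units.
#' @export
srs_stiffness <- function(segment, window = c(0.57, 0.59)) {
  keep <- segment$lce_norm >= window[1] & segment$lce_norm <= window[2]
  if (sum(keep) < 3) {
    stop("fewer than 3 samples inside the short-range-stiffness window [",
         window[1], ", ", window[2], "]")
  }
  l <- segment$lce_norm[keep]; f <- segment$f_norm[keep]
  unname(stats::cov(l, f) / stats::var(l))
}

#' Detect the force onset length of a segment
#'
#' Optional alternative to the fixed short-range-stiffness window: the first
#' length at which the normalized force exceeds the starting force by
#' `threshold`.
#'
#' @param segment data.frame with `lce_norm` and `f_norm`.
#' @param threshold normalized force rise above the first sample.
#' @return onset length \[l_opt\].
#' @export
force_onset_length <- function(segment, threshold = 0.005) {
  i <- which(segment$f_norm > segment$f_norm[1] + threshold)[1]
  if (is.na(i)) stop("force never rises above the onset threshold")
  segment$lce_norm[i]
}

#' Work after the short-range-stiffness region
#'
#' Trapezoidal work from the end of the short-range-stiffness region to a
#' common end length (by default the step-up condition's end-of-preflex
#' length), so the stretch extent — and with it the elastic contribution —
#' is equalized across perturbations and only velocity-dependent differences
#' remain.
#'
#' @param segment data.frame with `lce_norm` and `f_norm` extending past
#'   `srs_end`.
#' @param common_end_length end length of the integration \[l_opt\].
#' @param srs_end end of the short-range-stiffness region \[l_opt\].
#' @return work in `F_max * l_opt` units.
#' @export
post_srs_work <- function(segment, common_end_length, srs_end = 0.59) {
  if (common_end_length < srs_end) {
    stop("common end length lies before the end of the short-range-stiffness region")
  }
  if (common_end_length == srs_end) return(0)
  if (max(segment$lce_norm) < common_end_length) {
    stop("segment does not reach the common end length")
  }
  seg <- clip_segment_at_length(segment, common_end_length)
  i0 <- which(seg$lce_norm >= srs_end)[1]
  if (is.na(i0)) stop("segment does not reach the short-range-stiffness end")
  head_seg <- if (i0 > 1) {
    clip_segment_at_length(seg, srs_end)
  } else {
    seg[1, , drop = FALSE]
  }
  start_row <- head_seg[nrow(head_seg), , drop = FALSE]
  tail_seg <- rbind(start_row, seg[seq(i0, nrow(seg)), , drop = FALSE])
  tail_seg <- tail_seg[tail_seg$lce_norm >= start_row$lce_norm[1], , drop = FALSE]
  mechanical_work(tail_seg)
}

#' Dynamic-minus-quasistatic work difference
#'
#' @param W_dynamic,W_quasistatic preflex work of the two speed conditions,
#'   computed on matched-length windows of the same fiber and condition.
#' @param check optional named lists of condition labels (`fiber_id`,
#'   `scenario`, `activity`) for both terms; mismatches raise an error.
#' @return `W_dynamic - W_quasistatic`.
#' @export
work_difference <- function(W_dynamic, W_quasistatic, check = NULL) {
  if (!is.null(check)) {
    same <- identical(check$dynamic[c("fiber_id", "scenario", "activity")],
                      check$quasistatic[c("fiber_id", "scenario", "activity")])
    if (!same) stop("condition mismatch between dynamic and quasistatic work")
  }
  W_dynamic - W_quasistatic
}

#' Per-trial preflex metrics for a whole session
#'
#' Normalizes every perturbation trial, applies the analysis-window rule
#' (30 ms for dynamic trials, matched stretch for quasistatic ones), and
#' computes the preflex work, the short-range stiffness, and — for dynamic
#' trials — the post-short-range-stiffness work up to the step-up
#' condition's end-of-preflex length. Dynamic-minus-quasistatic work
#' differences are reported per fiber, scenario and activity.
#'
#' @param session a `fiber_session`.
#' @param t_px preflex duration \[s\].
#' @param srs_window short-range-stiffness fit window \[l_opt\].
#' @return list with `metrics` (one row per perturbation trial: fiber,
#'   scenario, speed_condition, activity, work, srs, post_srs,
#'   window_end_length) and `work_diff` (fiber, scenario, activity,
#'   dwork = dynamic - quasistatic).
#' @export
analyze_session <- function(session, t_px = 0.030,
                            srs_window = c(0.57, 0.59)) {
  stopifnot(inherits(session, "fiber_session"))
  man <- session$manifest
  pert <- which(man$kind == "perturbation")
  norm <- lapply(pert, function(k) normalize_trial(session$trials[[k]], session))
  info <- man[pert, ]

  # end-of-preflex length per scenario x activity x fiber (dynamic trials)
  end_len <- new.env()
  key <- function(f, s, a) paste(f, s, a, sep = "|")
  for (j in seq_along(norm)) {
    if (info$speed_condition[j] == "dynamic") {
      w <- preflex_window(norm[[j]], t_px = t_px)
      assign(key(info$fiber[j], info$scenario[j], info$activity[j]),
             attr(w, "window_end_length"), envir = end_len)
    }
  }
  up_end <- function(f, a) get(key(f, "up", a), envir = end_len)

  rows <- vector("list", length(norm))
  for (j in seq_along(norm)) {
    nt <- norm[[j]]
    dyn <- info$speed_condition[j] == "dynamic"
    w <- if (dyn) {
      preflex_window(nt, t_px = t_px)
    } else {
      preflex_window(nt, matched_end_length =
                       get(key(info$fiber[j], info$scenario[j],
                               info$activity[j]), envir = end_len))
    }
    srs <- srs_stiffness(w, window = srs_window)
    ps <- if (dyn) {
      post_srs_work(w, common_end_length = up_end(info$fiber[j],
                                                  info$activity[j]),
                    srs_end = srs_window[2])
    } else NA_real_
    rows[[j]] <- data.frame(
      fiber = info$fiber[j], scenario = info$scenario[j],
      speed_condition = info$speed_condition[j],
      activity = info$activity[j],
      work = mechanical_work(w), srs = srs, post_srs = ps,
      window_end_length = attr(w, "window_end_length"))
  }
  metrics <- do.call(rbind, rows)

  dyn <- metrics[metrics$speed_condition == "dynamic", ]
  qs <- metrics[metrics$speed_condition == "quasistatic", ]
  mrg <- merge(dyn, qs, by = c("fiber", "scenario", "activity"),
               suffixes = c("_dyn", "_qs"))
  work_diff <- data.frame(fiber = mrg$fiber, scenario = mrg$scenario,
                          activity = mrg$activity,
                          dwork = mrg$work_dyn - mrg$work_qs)
  list(metrics = metrics, work_diff = work_diff)
}
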