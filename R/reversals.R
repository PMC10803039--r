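#' Detect polarity reversals with a Schmitt trigger
#'
#' A reversal is a zero crossing of the polarity indicator
#' `sigma(t) = A_r - A_l` that occurs after the previous excursion exceeded
#' `theta` times the indicator amplitude (hysteresis suppresses
#' sub-threshold wiggles). Crossing times are refined by linear
#' interpolation between outputs. The first `t_burn` seconds are discarded
#' before amplitude estimation and counting.
#'
#' @param traj A `gr_trajectory`, or a list with `times` and `sigma`.
#' @param theta Hysteresis fraction in (0, 0.5); defaults to the parameter
#'   set's `theta` (0.1) when available.
#' @param t_burn Burn-in discarded from the start, s (default 7200).
#' @param amp_min Absolute amplitude floor (default 0.02 in units of the
#'   MglA total): an indicator that never leaves `[-amp_min, amp_min]` is
#'   an unpolarized cell, not an oscillator, and yields zero reversals.
#' @return A `gr_reversals` list: `times` (reversal times, s), `intervals`
#'   (s), `mean_interval_min`, `frequency_per_h` (3600 / mean interval in
#'   s), `n`, `low_confidence` (TRUE when fewer than 3 reversals remain
#'   after burn-in), `amplitude`.
#' @examples
#' t <- seq(0, 6 * 3600)
#' r <- detect_reversals(list(times = t, sigma = sin(2 * pi * t / (24 * 60))),
#'                       theta = 0.1, t_burn = 0)
#' r$frequency_per_h  # 5 reversals per hour
#' @export
detect_reversals <- function(traj, theta = NULL, t_burn = 7200,
                             amp_min = 0.02) {
  if (is.null(theta))
    theta <- if (!is.null(traj$params)) traj$params$theta else 0.1
  stopifnot(theta > 0, theta < 0.5)
  tt <- traj$times; sig <- traj$sigma
  stopifnot(length(tt) == length(sig))
  keep <- tt >= t_burn
  if (!any(keep)) stop("trajectory shorter than t_burn")
  tt <- tt[keep]; sig <- sig[keep]
  amp <- max(abs(sig))
  res <- list(times = numeric(0), intervals = numeric(0),
              mean_interval_min = NA_real_, frequency_per_h = 0,
              n = 0L, low_confidence = TRUE, amplitude = amp, theta = theta)
  class(res) <- "gr_reversals"
  if (amp <= amp_min) return(res)
  th <- max(theta * amp, amp_min)
  armed <- 0
  rev_t <- numeric(0)
  for (i in seq_along(sig)) {
    s <- sig[i]
    if (armed == 0) {
      if (abs(s) > th) armed <- sign(s)
    } else if (sign(s) == -armed && abs(s) > th) {
      # crossed zero and exceeded the opposite threshold: locate the crossing
      j <- i
      while (j > 1 && sign(sig[j - 1]) == sign(s)) j <- j - 1
      if (j > 1) {
        s0 <- sig[j - 1]; s1 <- sig[j]
        tc <- tt[j - 1] + (tt[j] - tt[j - 1]) * (0 - s0) / (s1 - s0)
      } else tc <- tt[j]
      rev_t <- c(rev_t, tc)
      armed <- sign(s)
    }
  }
  res$times <- rev_t
  res$n <- length(rev_t)
  res$low_confidence <- res$n < 3
  if (res$n >= 2) {
    res$intervals <- diff(rev_t)
    res$mean_interval_min <- mean(res$intervals) / 60
    res$frequency_per_h <- 3600 / mean(res$intervals)
  }
  res
}

#' @export
print.gr_reversals <- function(x, ...) {
  cat(sprintf("<gr_reversals> %d reversals; mean period %.2f min; %.2f /h%s\n",
              x$n, x$mean_interval_min, x$frequency_per_h,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

#' Steady-phase summary of a trajectory
#'
#' Computes the reversal statistics plus motor-state and MglA-partition
#' observables. "Steady phase" means the midpoints between consecutive
#' reversals, where the polarized state is fully developed; the nonpolar
#' MglA fraction is sampled there, while the motor fractions are averaged
#' over the whole post-burn-in window.
#'
#' @param traj A `gr_trajectory`.
#' @param t_burn Burn-in, s.
#' @param theta Hysteresis fraction (default from the parameter set).
#' @return List: `mean_period_min`, `frequency_per_h`, `f_active`,
#'   `f_engaged`, `nonpolar_A`, `engaged_active_ratio`, `reversals`
#'   (the `gr_reversals`), `midpoints` (steady-phase sample times),
#'   `leading_pole` (factor series "l"/"r" at the sample times).
#' @export
summarize_trajectory <- function(traj, t_burn = 7200, theta = NULL) {
  stopifnot(inherits(traj, "gr_trajectory"))
  rev <- detect_reversals(traj, theta = theta, t_burn = t_burn)
  keep <- traj$times >= t_burn
  fa <- mean(traj$f_active[keep]); fe <- mean(traj$f_engaged[keep])
  mid <- if (rev$n >= 2) head(rev$times, -1) + diff(rev$times) / 2 else numeric(0)
  npA <- if (length(mid)) {
    idx <- vapply(mid, function(m) which.min(abs(traj$times - m)), 1L)
    mean(traj$nonpolar_A[idx])
  } else mean(traj$nonpolar_A[keep])
  lead <- if (length(mid)) {
    idx <- vapply(mid, function(m) which.min(abs(traj$times - m)), 1L)
    ifelse(traj$sigma[idx] > 0, "r", "l")
  } else character(0)
  list(mean_period_min = rev$mean_interval_min,
       frequency_per_h = rev$frequency_per_h,
       f_active = fa, f_engaged = fe, nonpolar_A = npA,
       engaged_active_ratio = if (fa > 0) fe / fa else NA_real_,
       reversals = rev, midpoints = mid, leading_pole = lead)
}

#' Steady-phase spatial profiles for one heading
#'
#' Returns the 8-bin spatial profiles ([bin_profile()]) of the engaged
#' motors and of total MglA (free + motor-bound + polar pools in the `l`/`r`
#' bins) at the steady-phase snapshot closest to a mid-reversal time point
#' with the requested heading.
#'
#' @param traj A `gr_trajectory` with snapshots.
#' @param which `"rightward"` or `"leftward"`.
#' @param t_burn Burn-in, s.
#' @return List: `engaged`, `active`, `mglA` (named 8-bin vectors), `time`
#'   (snapshot time used), `heading`.
#' @export
spatial_snapshot <- function(traj, which = c("rightward", "leftward"),
                             t_burn = 7200) {
  which <- match.arg(which)
  stopifnot(inherits(traj, "gr_trajectory"))
  sm <- summarize_trajectory(traj, t_burn = t_burn)
  if (!length(sm$midpoints)) stop("no steady-phase points in trajectory")
  want <- if (which == "rightward") "r" else "l"
  mids <- sm$midpoints[sm$leading_pole == want]
  if (!length(mids)) stop("requested heading never attained")
  # snap to nearest stored snapshot
  i <- which.min(abs(traj$snapshot_times - mids[length(mids)]))
  st <- vector_to_state(traj$snapshots[i, ], traj$params$geometry)
  g <- traj$params$geometry
  eng_cells <- (st$fields[, "M_ep"] + st$fields[, "M_em"]) * g$dx
  act_cells <- (st$fields[, "M_ap"] + st$fields[, "M_am"]) * g$dx
  A_cells <- (st$fields[, "a"] + st$fields[, "M_ap"] + st$fields[, "M_am"] +
                st$fields[, "M_ep"] + st$fields[, "M_em"]) * g$dx
  eng <- bin_profile(eng_cells, g)
  act <- bin_profile(act_cells, g)
  mglA <- bin_profile(A_cells, g)
  mglA["l"] <- mglA["l"] + unname(st$pools["A_l"])
  mglA["r"] <- mglA["r"] + unname(st$pools["A_r"])
  list(engaged = eng, active = act, mglA = mglA,
       time = traj$snapshot_times[i], heading = which)
}
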