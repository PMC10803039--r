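#' Load a run configuration
#'
#' Reads a flat JSON configuration whose keys are exactly the parameter
#' names of [default_params()] (plus the geometry fields `L`, `n_cells`,
#' `pole_width` and an optional `numerics` section with `t_end`,
#' `output_dt`, `snapshot_dt`, `t_burn`, `dt_max`, `cfl`). Missing keys take
#' their defaults; unknown keys are rejected by name; constraint violations
#' (e.g. a negative rate) name the offending key. An empty file or empty
#' object yields the full defaults.
#'
#' @param path Path to a JSON file.
#' @return List with `params` (a `gr_params`) and `numerics` (named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  cfg <- if (nchar(trimws(txt)) == 0) list()
         else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  numerics <- list(t_end = 36000, output_dt = 1, snapshot_dt = 60,
                   t_burn = 7200, dt_max = 0.05, cfl = 0.75)
  if (!is.null(cfg$numerics)) {
    nn <- as.list(cfg$numerics)
    bad <- setdiff(names(nn), names(numerics))
    if (length(bad)) stop("unknown numerics key: ", paste(bad, collapse = ", "))
    numerics <- utils::modifyList(numerics, nn)
    cfg$numerics <- NULL
  }
  params <- tryCatch(do.call(default_params, cfg),
                     error = function(e) stop(conditionMessage(e), call. = FALSE))
  for (nm in c("t_end", "output_dt", "dt_max", "cfl"))
    if (!is.numeric(numerics[[nm]]) || numerics[[nm]] <= 0)
      stop("numerics key '", nm, "' must be positive")
  list(params = params, numerics = numerics)
}

#' Write a parameter set (plus optional numerics) as JSON
#'
#' Round-trips with [load_config()]: loading the written file reproduces an
#' identical parameter set.
#'
#' @param params A `gr_params`.
#' @param path Output path.
#' @param numerics Optional numerics list.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path, numerics = NULL) {
  stopifnot(inherits(params, "gr_params"))
  out <- params_to_clist(params)
  if (!is.null(numerics)) out$numerics <- numerics
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a trajectory as tidy CSV
#'
#' Long format `(time_s, variable, value)` with the derived series
#' (polarity indicator, velocity, motor fractions, nonpolar MglA fraction)
#' and the six polar pools.
#'
#' @param traj A `gr_trajectory`.
#' @param path Output path.
#' @param thin Keep every `thin`-th output row (default 1).
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, thin = 1) {
  stopifnot(inherits(traj, "gr_trajectory"))
  idx <- seq(1, length(traj$times), by = thin)
  series <- list(sigma = traj$sigma, velocity_um_s = traj$velocity,
                 f_active = traj$f_active, f_engaged = traj$f_engaged,
                 nonpolar_A = traj$nonpolar_A)
  for (nm in colnames(traj$pools)) series[[nm]] <- traj$pools[, nm]
  df <- do.call(rbind, lapply(names(series), function(nm)
    data.frame(time_s = traj$times[idx], variable = nm,
               value = series[[nm]][idx])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a phase diagram as CSV
#'
#' Schema: `(k_eng, k_act, frequency_per_h, f_engaged)`, one row per node.
#'
#' @param diagram A `gr_phase_diagram`.
#' @param path CSV path.
#' @return `path` (write) / a `gr_phase_diagram` (read; `base_params` is
#'   restored as defaults and not round-tripped).
#' @export
write_phase_diagram_csv <- function(diagram, path) {
  stopifnot(inherits(diagram, "gr_phase_diagram"))
  grid <- expand.grid(i = seq_along(diagram$k_eng),
                      j = seq_along(diagram$k_act))
  df <- data.frame(k_eng = diagram$k_eng[grid$i],
                   k_act = diagram$k_act[grid$j],
                   frequency_per_h = diagram$frequency[cbind(grid$i, grid$j)],
                   f_engaged = diagram$f_engaged[cbind(grid$i, grid$j)])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_diagram_csv
#' @export
read_phase_diagram_csv <- function(path) {
  df <- utils::read.csv(path)
  ke <- sort(unique(df$k_eng)); ka <- sort(unique(df$k_act))
  F <- matrix(NA_real_, length(ke), length(ka))
  G <- matrix(NA_real_, length(ke), length(ka))
  for (row in seq_len(nrow(df))) {
    i <- match(df$k_eng[row], ke); j <- match(df$k_act[row], ka)
    F[i, j] <- df$frequency_per_h[row]; G[i, j] <- df$f_engaged[row]
  }
  structure(list(k_eng = ke, k_act = ka, frequency = F, f_engaged = G,
                 low_confidence = matrix(FALSE, length(ke), length(ka)),
                 base_params = default_params(), t_end = NA, t_burn = NA),
            class = "gr_phase_diagram")
}

#' Synthetic test fixtures with known answers
#'
#' * `sinusoid_polarity`: a pure cosine polarity indicator with period
#'   `T_min` minutes over `hours` hours; starting from the polarized phase,
#'   zero crossings occur every half period beginning at a quarter period,
#'   so the expected count is `hours*60/(T_min/2)` and the expected
#'   frequency `120/T_min` per hour.
#' * `linear_toy_6cell`: a 6-cell frozen-regulator motor system (diffusion
#'   and advection off) whose generator matrix is returned for a
#'   matrix-exponential oracle, together with the matching `gr_params`
#'   and initial state.
#' * `step_advection`: a single-cell pulse plus the hand-computed result of
#'   one explicit first-order upwind Euler step.
#'
#' @param kind Fixture name.
#' @param T_min,hours Sinusoid period (min) and duration (h).
#' @return A list; contents depend on `kind`.
#' @export
make_fixture <- function(kind = c("sinusoid_polarity", "linear_toy_6cell",
                                  "step_advection"),
                         T_min = 24, hours = 6) {
  kind <- match.arg(kind)
  if (kind == "sinusoid_polarity") {
    tt <- seq(0, hours * 3600)
    list(times = tt, sigma = cos(2 * pi * tt / (T_min * 60)),
         expected_reversals = as.integer(floor(hours * 60 / (T_min / 2))),
         expected_frequency_per_h = 120 / T_min)
  } else if (kind == "linear_toy_6cell") {
    p <- default_params(n_cells = 6, pole_width = 5 / 6,
                        v_a = 0, D_i = 0, D_A = 0, D_B = 0, D_R = 0)
    st <- initial_state(p)
    st$pools[] <- c(0.3, 0.1, 0.05, 0.4, 0.1, 0.2)
    st$fields[, "M_i"] <- c(0.3, 0.2, 0.1, 0.1, 0.2, 0.3)
    st$fields[, "M_ap"] <- 0.05
    st$fields[, "M_em"] <- c(0, 0.1, 0.2, 0.2, 0.1, 0)
    list(params = p, state = st, A = motor_generator_matrix(p, st$pools))
  } else {
    n <- 10
    q0 <- numeric(n); q0[4] <- 1
    v <- 2; dx <- 0.5; dt <- 0.1
    q1 <- q0
    q1[4] <- q0[4] - v * dt / dx * q0[4]
    q1[5] <- q0[5] + v * dt / dx * q0[4]
    list(q0 = q0, q1 = q1, v = v, dx = dx, dt = dt)
  }
}

# Generator matrix of the frozen-regulator motor subsystem (no diffusion,
# no advection): state order (M_i, M_ap, M_am, M_ep, M_em) per cell,
# cells varying fastest within each block.
motor_generator_matrix <- function(params, pools) {
  g <- params$geometry; n <- g$n_cells
  wl <- g$wl; wr <- g$wr; cj <- 1 - wl - wr
  kact <- params$k_act * (pools["A_l"] * wl + pools["A_r"] * wr)
  kdeact <- params$k_deact * (pools["B_l"] * wl + pools["B_r"] * wr)
  kdis <- params$k_dis * cj + params$k_dis_pole * (1 - cj)
  half <- params$act_split == "half"
  A <- matrix(0, 5 * n, 5 * n)
  ix <- function(f, j) (f - 1) * n + j  # f: 1=Mi 2=Map 3=Mam 4=Mep 5=Mem
  for (j in 1:n) {
    A[ix(1, j), ix(1, j)] <- -kact[j]
    A[ix(1, j), ix(2, j)] <- A[ix(1, j), ix(3, j)] <- kdeact[j]
    actLj <- params$k_act * pools["A_l"] * wl[j]
    actRj <- params$k_act * pools["A_r"] * wr[j]
    if (half) {
      A[ix(2, j), ix(1, j)] <- 0.5 * kact[j]
      A[ix(3, j), ix(1, j)] <- 0.5 * kact[j]
    } else {
      A[ix(2, j), ix(1, j)] <- actLj
      A[ix(3, j), ix(1, j)] <- actRj
    }
    A[ix(2, j), ix(2, j)] <- -params$k_sw - params$k_eng * cj[j] - kdeact[j]
    A[ix(2, j), ix(3, j)] <- params$k_sw
    A[ix(2, j), ix(4, j)] <- kdis[j]
    A[ix(3, j), ix(3, j)] <- -params$k_sw - params$k_eng * cj[j] - kdeact[j]
    A[ix(3, j), ix(2, j)] <- params$k_sw
    A[ix(3, j), ix(5, j)] <- kdis[j]
    A[ix(4, j), ix(2, j)] <- params$k_eng * cj[j]
    A[ix(4, j), ix(4, j)] <- -kdis[j]
    A[ix(5, j), ix(3, j)] <- params$k_eng * cj[j]
    A[ix(5, j), ix(5, j)] <- -kdis[j]
  }
  A
}

#' Export a model state as tidy CSV
#'
#' Columns `(x_center_um, species, value)`: one row per grid cell per
#' field (densities, amount/um), plus the six polar pools with `NA`
#' coordinates (amounts).
#'
#' @param state A `gr_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_csv <- function(state, path) {
  stopifnot(inherits(state, "gr_state"))
  g <- state$geometry
  df <- do.call(rbind, lapply(colnames(state$fields), function(nm)
    data.frame(x_center_um = g$x_centers, species = nm,
               value = state$fields[, nm])))
  pools <- data.frame(x_center_um = NA_real_, species = names(state$pools),
                      value = unname(state$pools))
  utils::write.csv(rbind(df, pools), path, row.names = FALSE)
  invisible(path)
}
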