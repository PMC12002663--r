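#' Cell cycle phase thresholds on MPF
#'
#' The cell cycle is divided into G1, S/G2 and M by the MPF level: G1 below
#' `theta_S`, S/G2 between `theta_S` and `theta_M`, and M from the first
#' upward crossing of `theta_M` (latched until division).  Division fires at
#' the downward crossing of `theta_div` while latched in M, i.e. at the
#' post-peak collapse of the MPF relaxation spike.  Defaults place
#' `theta_M` at 60% and `theta_S = theta_div` at 20% of the deterministic
#' uncoupled MPF peak.
#'
#' @param model A `clock_model` (used for its calibrated MPF peak), or
#'   `NULL` when giving all thresholds explicitly.
#' @param theta_S,theta_M,theta_div Explicit threshold concentrations.
#' @return A `phase_thresholds` object.
#' @export
phase_thresholds <- function(model = NULL, theta_S = NULL, theta_M = NULL,
                             theta_div = NULL) {
  if (!is.null(model)) {
    stopifnot(inherits(model, "clock_model"))
    peak <- model$mpf_peak
    if (is.na(peak)) {
      model <- calibrate_model(model)
      peak <- model$mpf_peak
    }
    if (is.null(theta_S)) theta_S <- 0.2 * peak
    if (is.null(theta_M)) theta_M <- 0.6 * peak
    if (is.null(theta_div)) theta_div <- theta_S
  }
  if (is.null(theta_S) || is.null(theta_M)) {
    stop("theta_S and theta_M are required when no model is given")
  }
  if (is.null(theta_div)) theta_div <- theta_S
  if (!(theta_S > 0 && theta_S < theta_M)) {
    stop("need 0 < theta_S < theta_M")
  }
  if (theta_div >= theta_M) stop("theta_div must be below theta_M")
  structure(list(theta_S = theta_S, theta_M = theta_M,
                 theta_div = theta_div),
            class = "phase_thresholds")
}

#' Classify cell cycle phase from the MPF level
#'
#' @param mpf Numeric vector of MPF concentrations.
#' @param thresholds A [phase_thresholds()].
#' @param in_M_latch Logical (recycled): whether the cell has already
#'   entered M this cycle; a latched cell stays in M even if MPF dips below
#'   `theta_M`, until division.
#' @return A factor with levels `G1`, `S/G2`, `M`.
#' @export
phase_of <- function(mpf, thresholds, in_M_latch = FALSE) {
  stopifnot(inherits(thresholds, "phase_thresholds"))
  latch <- rep_len(in_M_latch, length(mpf))
  out <- ifelse(latch | mpf >= thresholds$theta_M, "M",
                ifelse(mpf >= thresholds$theta_S, "S/G2", "G1"))
  factor(out, levels = cl_phase_levels)
}

cl_phase_levels <- c("G1", "S/G2", "M")

## deterministic seed chain: base seed + run index -> run seed -> cell seed.
## Plain 31-bit congruential mixing; reproducibility of lineage simulations
## must not depend on the order in which cells are processed.
#' Derive the seed of one run in an ensemble
#' @param base_seed Integer base seed of the ensemble.
#' @param run_index Run number (1-based).
#' @return Integer seed below 2^31.
#' @export
run_seed <- function(base_seed, run_index) {
  mix31(mix31(base_seed, 2654435769) + run_index)
}

cell_seed <- function(run_seed, cell_id) {
  mix31(mix31(run_seed, 2246822519) + cell_id)
}

mix31 <- function(x, salt = 0) {
  x <- (x + salt) %% 2147483647
  x <- (x * 48271) %% 2147483647
  as.integer((x * 16807 + 1) %% 2147483647)
}

#' Grow stochastic cell lineages
#'
#' Event-driven lineage simulation: each cell integrates the model SDE from
#' its birth state, enters M at the upward `theta_M` crossing of MPF and
#' divides at the subsequent downward `theta_div` crossing.  Division
#' replaces the mother by two daughters that inherit her concentrations
#' verbatim (symmetric inheritance).  Ancestor cells are drawn
#' phase-randomised from [burn_in_ensemble()].  Each cell consumes an RNG
#' stream spawned deterministically from the run seed and its cell id, so a
#' run is bit-reproducible.
#'
#' @param model A `clock_model`.
#' @param noise A [noise_spec()].
#' @param thresholds A [phase_thresholds()]; defaults to
#'   `phase_thresholds(model)`.
#' @param n_ancestors Number of independent ancestor cells.
#' @param stop A list with `max_population` and/or `max_time` (h); at least
#'   one must be given.  `max_population` counts alive cells; the simulation
#'   halts at the division event that reaches it.
#' @param config An [integrator_config()] (its `t_max`/`seed` are ignored;
#'   use `seed` and `stop`).
#' @param seed Integer run seed.
#' @param keep_trajectories Retain full per-cell state trajectories
#'   (memory-hungry; phase series are always retained).
#' @param synchronize Ancestor sampling mode passed to
#'   [burn_in_ensemble()]: `"none"` (fully asynchronous) or `"clock"`
#'   (clock-coherent, cell-cycle-spread).
#' @param guard_factor A cell that has not divided within
#'   `guard_factor * autonomous_TCC` hours is censored with a warning
#'   (arrested cell).
#' @return A `lineage_run` with fields `cells` (tibble), `phases` (per-cell
#'   phase series), `model`, `noise`, `thresholds`, `seed`, `stop_time`.
#' @export
run_lineage <- function(model, noise = noise_spec(), thresholds = NULL,
                        n_ancestors = 1,
                        stop = list(max_population = 64),
                        config = integrator_config(), seed = 1,
                        keep_trajectories = FALSE, guard_factor = 10,
                        synchronize = c("none", "clock")) {
  synchronize <- match.arg(synchronize)
  stopifnot(inherits(model, "clock_model"))
  if (is.null(thresholds)) thresholds <- phase_thresholds(model)
  if (is.null(stop$max_population) && is.null(stop$max_time)) {
    stop("stop rule needs max_population and/or max_time")
  }
  max_pop <- stop$max_population %||% Inf
  if (!is.infinite(max_pop) && max_pop < n_ancestors) {
    stop("max_population must be >= n_ancestors")
  }
  ## horizon within which cells are simulated; beyond it they are censored
  horizon <- stop$max_time %||%
    (model$autonomous_TCC * (log2(max(max_pop / n_ancestors, 2)) + 4))
  guard <- guard_factor * model$autonomous_TCC
  nv <- noise_vectors(model, noise)
  pvec <- unname(model_param_vector(model))
  mpf_idx <- cl_mpf_index(model$model_id)

  set.seed(run_seed(seed, 0))
  anc_states <- burn_in_ensemble(
    model, noise,
    config = integrator_config(dt = config$dt,
                               t_max = 12 * model$clock_period,
                               record_every = config$record_every),
    n = n_ancestors, synchronize = synchronize)

  ## growing columnar storage; ids index directly into these vectors
  cap <- max(64L, 2L * n_ancestors)
  st <- new.env(parent = emptyenv())
  st$lineage_id <- st$parent_id <- st$generation <- integer(cap)
  st$birth_time <- st$division_time <- st$t_s <- st$t_m <- numeric(cap)
  st$censored <- logical(cap)
  grow_to <- function(n) {
    while (n > length(st$birth_time)) {
      for (f in c("lineage_id", "parent_id", "generation", "birth_time",
                  "division_time", "t_s", "t_m", "censored")) {
        x <- st[[f]]
        length(x) <- 2L * length(x)
        ## integer slots use 0 as the "unassigned" marker
        if (f == "lineage_id") x[is.na(x)] <- 0L
        st[[f]] <- x
      }
    }
  }
  phases <- vector("list", cap)
  trajs <- if (keep_trajectories) list() else NULL
  birth_states <- vector("list", cap)
  record <- function(id, lineage, parent, gen, birth, div, cens, t_s, t_m) {
    st$lineage_id[id] <- lineage
    st$parent_id[id] <- parent
    st$generation[id] <- gen
    st$birth_time[id] <- birth
    st$division_time[id] <- if (cens) NA_real_ else div
    st$censored[id] <- cens
    st$t_s[id] <- t_s
    st$t_m[id] <- t_m
  }
  for (i in seq_len(n_ancestors)) birth_states[[i]] <- anc_states[i, ]

  ## queue of unsimulated cells (ids + metadata); with a population cap the
  ## queue is processed in birth-time order, otherwise order is free
  q_id <- seq_len(n_ancestors)
  q_lin <- seq_len(n_ancestors)
  q_par <- rep(NA_integer_, n_ancestors)
  q_gen <- rep(0L, n_ancestors)
  q_birth <- rep(0, n_ancestors)
  next_id <- n_ancestors + 1L
  division_times <- numeric()
  n_rec <- 0L

  while (length(q_id) > 0) {
    i <- if (is.infinite(max_pop)) length(q_id) else which.min(q_birth)
    id <- q_id[i]; lin <- q_lin[i]; par <- q_par[i]
    gen <- q_gen[i]; birth <- q_birth[i]
    if (!is.infinite(max_pop)) {
      k_needed <- max_pop - n_ancestors
      if (sum(division_times <= birth) >= k_needed) break
    }
    q_id <- q_id[-i]; q_lin <- q_lin[-i]; q_par <- q_par[-i]
    q_gen <- q_gen[-i]; q_birth <- q_birth[-i]
    grow_to(id)
    n_rec <- max(n_rec, id)
    t_left <- horizon - birth
    if (t_left <= config$dt) {
      record(id, lin, par, gen, birth, NA, TRUE, NA_real_, NA_real_)
      phases[[id]] <- list(t0 = birth,
                           dt = config$dt * config$record_every,
                           phase = integer())
      next
    }
    set.seed(cell_seed(seed, id))
    res <- cl_simulate_cell_cpp(model$model_id, pvec,
                                as.numeric(birth_states[[id]]),
                                config$dt, min(t_left, guard), mpf_idx,
                                thresholds$theta_S, thresholds$theta_M,
                                thresholds$theta_div, nv$mode, nv$sigma,
                                noise$omega, nv$gmult, config$record_every,
                                keep_trajectories)
    birth_states[id] <- list(NULL)
    if (!res$divided && t_left > guard) {
      warning("arrested cell ", id, " censored after ", guard,
              " h without division", call. = FALSE)
    }
    if (length(phases) < id) phases <- c(phases, vector("list", id))
    phases[[id]] <- list(t0 = birth, dt = res$record_dt, phase = res$phase)
    if (keep_trajectories) trajs[[as.character(id)]] <- res$states
    t_s <- birth + res$t_enter_s
    t_m <- birth + res$t_enter_m
    if (res$divided) {
      t_div <- birth + res$t_div
      division_times <- c(division_times, t_div)
      record(id, lin, par, gen, birth, t_div, FALSE, t_s, t_m)
      kid1 <- next_id
      next_id <- next_id + 2L
      if (t_div < horizon - config$dt || !is.infinite(max_pop)) {
        q_id <- c(q_id, kid1, kid1 + 1L)
        q_lin <- c(q_lin, lin, lin)
        q_par <- c(q_par, id, id)
        q_gen <- c(q_gen, gen + 1L, gen + 1L)
        q_birth <- c(q_birth, t_div, t_div)
        grow_to(kid1 + 1L)
        birth_states[[kid1]] <- res$state_end
        birth_states[[kid1 + 1L]] <- res$state_end
      } else {
        ## horizon reached: daughters exist only as censored leaves
        grow_to(kid1 + 1L)
        for (k in c(kid1, kid1 + 1L)) {
          record(k, lin, id, gen + 1L, t_div, NA, TRUE, NA_real_, NA_real_)
          phases[[k]] <- list(t0 = t_div,
                              dt = config$dt * config$record_every,
                              phase = integer())
        }
        n_rec <- max(n_rec, kid1 + 1L)
      }
    } else {
      record(id, lin, par, gen, birth, NA, TRUE, t_s, t_m)
    }
  }
  ## cells never simulated because the population cap hit first
  if (length(q_id) > 0) {
    for (j in seq_along(q_id)) {
      grow_to(q_id[j])
      record(q_id[j], q_lin[j], q_par[j], q_gen[j], q_birth[j], NA, TRUE,
             NA_real_, NA_real_)
      n_rec <- max(n_rec, q_id[j])
    }
  }
  ids <- seq_len(n_rec)
  ## unassigned slots keep the 0 lineage marker
  ids <- ids[st$lineage_id[ids] > 0 & !is.na(st$lineage_id[ids])]
  cells <- tibble::tibble(
    cell_id = as.numeric(ids),
    lineage_id = st$lineage_id[ids],
    parent_id = as.numeric(st$parent_id[ids]),
    generation = st$generation[ids],
    birth_time = st$birth_time[ids],
    division_time = st$division_time[ids],
    imt = st$division_time[ids] - st$birth_time[ids],
    censored = st$censored[ids],
    t_enter_s = st$t_s[ids],
    t_enter_m = st$t_m[ids])
  stop_time <- if (!is.infinite(max_pop) &&
                   length(division_times) >= max_pop - n_ancestors) {
    sort(division_times)[max_pop - n_ancestors]
  } else {
    horizon
  }
  ## censor anything recorded as dividing after the stop time
  late <- !is.na(cells$division_time) & cells$division_time > stop_time
  cells$division_time[late] <- NA_real_
  cells$imt[late] <- NA_real_
  cells$censored[late] <- TRUE
  keep <- cells$birth_time <= stop_time
  cells <- cells[keep, , drop = FALSE]
  structure(list(cells = cells, phases = phases, trajectories = trajs,
                 model = model, noise = noise, thresholds = thresholds,
                 seed = seed, stop_time = stop_time),
            class = "lineage_run")
}

cell_record <- function(cell, division_time, censored = FALSE,
                        t_s = NA_real_, t_m = NA_real_) {
  data.frame(cell_id = cell$cell_id, lineage_id = cell$lineage_id,
             parent_id = cell$parent_id, generation = cell$generation,
             birth_time = cell$birth_time,
             division_time = if (censored) NA_real_ else division_time,
             imt = if (censored) NA_real_ else division_time - cell$birth_time,
             censored = censored,
             t_enter_s = t_s, t_enter_m = t_m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lineage_run <- function(x, ...) {
  n <- nrow(x$cells)
  cat("<lineage_run>", n, "cells,", sum(!x$cells$censored), "divided,",
      length(unique(x$cells$lineage_id)), "lineage(s), stop at",
      round(x$stop_time, 2), "h\n")
  invisible(x)
}

#' Extract the cell table of a lineage run
#'
#' @param run A `lineage_run`.
#' @return The `cells` tibble (cell_id, lineage_id, parent_id, generation,
#'   birth_time, division_time, imt, censored).
#' @export
lineage_cells <- function(run) {
  stopifnot(inherits(run, "lineage_run"))
  run$cells
}

#' Lineage tree as a directed igraph
#'
#' Mother-to-daughter edges; vertex attributes carry the cell table
#' columns.
#'
#' @param cells A cell table as returned by [lineage_cells()].
#' @return An [igraph::igraph] object.
#' @export
lineage_graph <- function(cells) {
  cells <- as.data.frame(cells)
  edges <- cells[!is.na(cells$parent_id), c("parent_id", "cell_id")]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$parent_id),
               to = as.character(edges$cell_id)),
    directed = TRUE,
    vertices = data.frame(name = as.character(cells$cell_id),
                          cells[setdiff(names(cells), "cell_id")]))
  g
}

#' Check structural validity of a lineage forest
#'
#' Asserts binary out-degree (0 or 2), acyclicity, one root per lineage,
#' and time consistency (child birth equals parent division, positive IMT
#' for divided cells).
#'
#' @param cells A cell table.
#' @return `TRUE` (invisibly); otherwise an error describing the violation.
#' @export
validate_lineage <- function(cells) {
  g <- lineage_graph(cells)
  outd <- igraph::degree(g, mode = "out")
  if (!all(outd %in% c(0, 2))) stop("out-degree must be 0 or 2")
  if (!igraph::is_acyclic(g)) stop("lineage graph has a cycle")
  roots <- cells$cell_id[is.na(cells$parent_id)]
  if (length(roots) != length(unique(cells$lineage_id))) {
    stop("each lineage must have exactly one root")
  }
  kids <- cells[!is.na(cells$parent_id), ]
  if (nrow(kids)) {
    par <- cells[match(kids$parent_id, cells$cell_id), ]
    if (any(is.na(par$division_time))) {
      stop("censored cells cannot have children")
    }
    if (any(abs(kids$birth_time - par$division_time) > 1e-9)) {
      stop("child birth time must equal parent division time")
    }
    if (any(kids$generation != par$generation + 1L)) {
      stop("generation bookkeeping broken")
    }
  }
  div <- cells[!cells$censored, ]
  if (any(div$imt <= 0)) stop("IMT must be positive for divided cells")
  invisible(TRUE)
}

#' Count alive cells per phase over time
#'
#' @param run A `lineage_run`.
#' @param times Numeric vector of times (h) within the run horizon.
#' @return A tibble with columns `time`, `phase`, `count` (alive cells in
#'   that phase) and `alive` (total alive).
#' @export
snapshot_phase_counts <- function(run, times) {
  stopifnot(inherits(run, "lineage_run"))
  if (any(times > run$stop_time + 1e-9)) {
    stop("requested time beyond the run horizon (", round(run$stop_time, 2),
         " h)")
  }
  cells <- run$cells
  counts <- matrix(0L, nrow = length(times), ncol = 3,
                   dimnames = list(NULL, cl_phase_levels))
  ## accumulate each cell's phase over the grid points it is alive for
  for (k in seq_len(nrow(cells))) {
    id <- cells$cell_id[k]
    t0 <- cells$birth_time[k]
    t1 <- if (is.na(cells$division_time[k])) Inf else cells$division_time[k]
    sel <- which(times >= t0 & times < t1)
    if (!length(sel)) next
    rec <- run$phases[[id]]
    ph <- if (is.null(rec) || length(rec$phase) == 0) {
      rep(1L, length(sel))
    } else {
      j <- pmin(length(rec$phase), pmax(1L, 1L + floor((times[sel] - rec$t0) /
                                                         rec$dt)))
      rec$phase[j]
    }
    for (p in 1:3) counts[sel[ph == p], p] <- counts[sel[ph == p], p] + 1L
  }
  tibble::tibble(time = rep(times, each = 3),
                 phase = factor(rep(cl_phase_levels, length(times)),
                                levels = cl_phase_levels),
                 count = as.integer(t(counts)),
                 alive = rep(rowSums(counts), each = 3))
}

#' Alive-population curve of a run
#'
#' @param run A `lineage_run`.
#' @param times Time grid (h); defaults to 40 points over the run.
#' @return A tibble with `time` and `alive`.
#' @export
population_curve <- function(run, times = NULL) {
  stopifnot(inherits(run, "lineage_run"))
  if (is.null(times)) times <- seq(0, run$stop_time, length.out = 40)
  cells <- run$cells
  alive <- vapply(times, function(t) {
    sum(cells$birth_time <= t &
          (is.na(cells$division_time) | cells$division_time > t))
  }, numeric(1))
  tibble::tibble(time = times, alive = alive)
}
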