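#' Export a lineage tree
#'
#' CSV export writes the cell attribute table (cell_id, parent_id,
#' lineage_id, birth_time, division_time, imt, generation, censored).
#' Newick export writes one record per lineage with IMT as branch length;
#' censored leaves carry a `*` suffix on the label and use their observed
#' lifetime as branch length.
#'
#' @param cells A cell table or `lineage_run`.
#' @param path Output file path.
#' @param format `"csv"` or `"newick"`.
#' @return `path`, invisibly.
#' @export
export_tree <- function(cells, path, format = c("csv", "newick")) {
  if (inherits(cells, "lineage_run")) cells <- cells$cells
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(as.data.frame(cells), path, row.names = FALSE)
  } else {
    writeLines(vapply(split(as.data.frame(cells), cells$lineage_id),
                      newick_record, character(1)),
               path)
  }
  invisible(path)
}

newick_record <- function(cells, stop_time = NULL) {
  lab <- function(i) {
    paste0("c", cells$cell_id[i], if (cells$censored[i]) "*" else "")
  }
  blen <- function(i) {
    if (!cells$censored[i]) return(cells$imt[i])
    0
  }
  rec <- function(i) {
    kids <- which(!is.na(cells$parent_id) &
                    cells$parent_id == cells$cell_id[i])
    if (!length(kids)) {
      sprintf("%s:%.10g", lab(i), blen(i))
    } else {
      sprintf("(%s,%s)%s:%.10g", rec(kids[1]), rec(kids[2]), lab(i),
              blen(i))
    }
  }
  root <- which(is.na(cells$parent_id))
  paste0(rec(root), ";")
}

#' Read a lineage tree from CSV
#'
#' @param path File written by [export_tree()] with `format = "csv"`.
#' @return A cell tibble.
#' @export
read_tree_csv <- function(path) {
  df <- read.csv(path)
  df$parent_id <- as.integer(df$parent_id)
  tibble::as_tibble(df)
}

#' Read lineage trees from a Newick file
#'
#' Reconstructs cell ids, IMTs (branch lengths) and censoring flags from a
#' file written by [export_tree()] with `format = "newick"`.  Birth times
#' are rebuilt by accumulating branch lengths from each root.
#'
#' @param path Newick file, one record per lineage.
#' @return A cell tibble.
#' @export
read_tree_newick <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  single <- grepl("^c[0-9]+\\*?:[0-9.eE+-]+;$", lines)
  singles <- purrr::imap(which(single), function(k, i) {
    lab <- sub(";$", "", lines[k])
    cens <- grepl("\\*", lab)
    id <- as.integer(sub("^c([0-9]+)\\*?:.*$", "\\1", lab))
    len <- as.numeric(sub("^.*:", "", lab))
    data.frame(cell_id = id, lineage_id = k, parent_id = NA_integer_,
               generation = 0L, birth_time = 0,
               division_time = if (cens) NA_real_ else len,
               imt = if (cens) NA_real_ else len, censored = cens)
  })
  multi_idx <- which(!single)
  trees <- if (length(multi_idx)) {
    tr <- ape::read.tree(text = paste(lines[multi_idx], collapse = "\n"),
                         keep.multi = TRUE)
    if (inherits(tr, "phylo")) list(tr) else tr
  } else {
    list()
  }
  names(trees) <- multi_idx
  rows <- purrr::imap(trees, function(tr, li) {
    labels <- c(tr$tip.label, tr$node.label)
    n_tip <- length(tr$tip.label)
    root <- n_tip + 1L
    parse_lab <- function(s) {
      cens <- grepl("\\*$", s)
      id <- as.integer(sub("^c", "", sub("\\*$", "", s)))
      list(id = id, censored = cens)
    }
    edges <- tr$edge
    depth <- numeric(n_tip + tr$Nnode)
    root_len <- if (!is.null(tr$root.edge)) tr$root.edge else 0
    depth[root] <- root_len
    ord <- order(edges[, 1])  # parents before children in ape's numbering
    for (k in ord) {
      depth[edges[k, 2]] <- depth[edges[k, 1]] + tr$edge.length[k]
    }
    out <- lapply(seq_len(n_tip + tr$Nnode), function(v) {
      pl <- parse_lab(labels[v])
      par_edge <- which(edges[, 2] == v)
      parent <- if (length(par_edge)) {
        parse_lab(labels[edges[par_edge, 1]])$id
      } else {
        NA_integer_
      }
      blen <- if (length(par_edge)) tr$edge.length[par_edge] else root_len
      birth <- depth[v] - blen
      data.frame(cell_id = pl$id, lineage_id = as.integer(li),
                 parent_id = parent,
                 birth_time = birth,
                 division_time = if (pl$censored) NA_real_ else depth[v],
                 imt = if (pl$censored) NA_real_ else blen,
                 censored = pl$censored)
    })
    dplyr::bind_rows(out)
  })
  cells <- dplyr::bind_rows(c(singles, rows)) |>
    dplyr::arrange(.data$cell_id)
  ## rebuild generations from parent pointers
  gen <- setNames(rep(NA_integer_, nrow(cells)), cells$cell_id)
  gen[is.na(cells$parent_id)] <- 0L
  while (anyNA(gen)) {
    todo <- which(is.na(gen))
    gen[todo] <- gen[as.character(cells$parent_id[todo])] + 1L
  }
  cells$generation <- unname(gen)
  tibble::as_tibble(cells[, c("cell_id", "lineage_id", "parent_id",
                              "generation", "birth_time", "division_time",
                              "imt", "censored")])
}

#' Export a trajectory as tidy CSV
#'
#' @param traj A `trajectory`.
#' @param path Output path.
#' @param cell_id,run_id Optional identifiers added as columns.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path, cell_id = NA, run_id = NA) {
  df <- as_tibble(traj)
  df$cell_id <- cell_id
  df$run_id <- run_id
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Experiment configuration
#'
#' Bundles everything needed to reproduce one named experiment: model
#' definition, noise, integrator settings, thresholds, population settings
#' and seeds.  The configuration is serialisable to YAML and hashable;
#' `base_seed` and the run index determine each run's seed, so a config
#' reproduces its outputs bit for bit.
#'
#' @param experiment One of `"entrainment"`, `"cmi"`, `"kl001_sweep"`,
#'   `"growth"`, `"phases"`, `"custom"`.
#' @param model_id,C1,C2,autonomous_TCC,kl001_factor Model settings.
#' @param overrides Named kinetic-parameter overrides.
#' @param noise A [noise_spec()].
#' @param dt,record_every Integrator settings.
#' @param thresholds Optional explicit [phase_thresholds()].
#' @param n_ancestors,max_population,max_time Population settings.
#' @param n_runs Ensemble size.
#' @param base_seed Integer base seed.
#' @param profile `"desk"` (default; n_runs 20, max_population 128) or
#'   `"paper"` (n_runs 100); explicit arguments win over the profile.
#' @param extra Free-form list for experiment-specific settings (e.g.
#'   `factors` for the KL001 sweep, `grid` for entrainment).
#' @return An `experiment_config`.
#' @export
experiment_config <- function(experiment = "custom", model_id = 2,
                              C1 = 0.55, C2 = 0, autonomous_TCC = 20,
                              kl001_factor = 1, overrides = NULL,
                              noise = noise_spec(), dt = 0.01,
                              record_every = 10, thresholds = NULL,
                              n_ancestors = 1, max_population = NULL,
                              max_time = NULL, n_runs = NULL,
                              base_seed = 1,
                              profile = c("desk", "paper"),
                              extra = list()) {
  profile <- match.arg(profile)
  experiment <- match.arg(experiment, c("entrainment", "cmi", "kl001_sweep",
                                        "growth", "phases", "custom"))
  if (is.null(n_runs)) n_runs <- if (profile == "desk") 20 else 100
  if (is.null(max_population) && is.null(max_time)) max_population <- 128
  structure(list(experiment = experiment, model_id = model_id, C1 = C1,
                 C2 = C2, autonomous_TCC = autonomous_TCC,
                 kl001_factor = kl001_factor,
                 overrides = overrides, noise = noise, dt = dt,
                 record_every = record_every, thresholds = thresholds,
                 n_ancestors = n_ancestors,
                 max_population = max_population, max_time = max_time,
                 n_runs = n_runs, base_seed = base_seed,
                 profile = profile, extra = extra),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>", x$experiment, "| model", x$model_id,
      "C1 =", x$C1, "C2 =", x$C2, "TCC =", x$autonomous_TCC, "h |",
      x$n_runs, "runs, base seed", x$base_seed, "\n")
  invisible(x)
}

#' Write / read an experiment configuration (YAML)
#'
#' @param config An `experiment_config`.
#' @param path File path.
#' @return `path` (write) or the config (read).
#' @export
write_experiment_config <- function(config, path) {
  x <- unclass(config)
  x$noise <- unclass(x$noise)
  x$thresholds <- if (!is.null(x$thresholds)) unclass(x$thresholds)
  x$overrides <- if (!is.null(x$overrides)) as.list(x$overrides)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$noise <- do.call(noise_spec, x$noise[c("mode", "sigma", "omega",
                                           "clock_noise_scale")])
  if (!is.null(x$thresholds)) {
    x$thresholds <- do.call(phase_thresholds,
                            c(list(model = NULL), x$thresholds))
  }
  if (!is.null(x$overrides)) x$overrides <- unlist(x$overrides)
  do.call(experiment_config, x[setdiff(names(x), "profile")])
}

#' Stable hash of an experiment configuration
#'
#' @param config An `experiment_config`.
#' @return A hexadecimal string.
#' @export
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config),
                                              digits.d = 15)),
             collapse = "\n")
  ## 31-bit polynomial rolling hash over the serialised text
  h <- 17
  for (ch in utf8ToInt(s)) {
    h <- (h * 131 + ch) %% 2147483629
  }
  sprintf("%08x", h)
}

build_config_model <- function(config) {
  model <- build_model(config$model_id, C1 = config$C1, C2 = config$C2,
                       autonomous_TCC = config$autonomous_TCC,
                       overrides = config$overrides)
  if (config$kl001_factor > 1) {
    model <- apply_kl001(model, config$kl001_factor)
  }
  model
}

#' Run a lineage ensemble under a configuration
#'
#' @param config An `experiment_config`.
#' @param model Optional pre-built model (saves recalibration).
#' @param keep_runs Return the full `lineage_run` objects (memory-hungry)
#'   instead of cell tables only.
#' @return A list of per-run cell tables (or runs), named by run index.
#' @export
run_ensemble <- function(config, model = NULL, keep_runs = FALSE) {
  if (is.null(model)) model <- build_config_model(config)
  thr <- config$thresholds %||% phase_thresholds(model)
  runs <- lapply(seq_len(config$n_runs), function(i) {
    run <- run_lineage(model, config$noise, thr,
                       n_ancestors = config$n_ancestors,
                       stop = list(max_population = config$max_population,
                                   max_time = config$max_time),
                       config = integrator_config(dt = config$dt,
                                                  record_every =
                                                    config$record_every),
                       seed = run_seed(config$base_seed, i))
    if (keep_runs) run else run$cells
  })
  names(runs) <- seq_len(config$n_runs)
  runs
}

#' Run a named experiment and write its output bundle
#'
#' Dispatches on `config$experiment`: `entrainment` (deterministic
#' frequency sweeps over both couplings), `cmi` (lineage ensemble with the
#' correlation battery), `kl001_sweep` (deterministic dose-response plus a
#' lineage ensemble per dose), `growth` (per-run growth fits), `phases`
#' (phase-proportion analysis).  Every output row carries the run id and
#' seed, and the config (with its hash) is echoed next to the tables.
#'
#' @param config An `experiment_config`.
#' @param out_dir Output directory (created if missing).
#' @return A list of the tables written, invisibly.
#' @export
run_experiment <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  write_experiment_config(config, file.path(out_dir, "config.yaml"))
  out <- switch(
    config$experiment,
    entrainment = {
      model <- build_config_model(config)
      grid <- config$extra$grid %||% seq(0, 1, by = 0.1)
      tab <- dplyr::bind_rows(
        entrainment_curve(model, "forward", grid),
        entrainment_curve(model, "reverse", config$extra$reverse_grid %||%
                            c(0, 0.5, 1, 2, 4)))
      list(entrainment = tab)
    },
    cmi = {
      runs <- run_ensemble(config)
      cors <- purrr::imap(runs, function(cells, run) {
        correlation_summary(cells, cl_relations) |>
          dplyr::mutate(run_id = as.integer(run),
                        seed = run_seed(config$base_seed, as.integer(run)),
                        .before = 1)
      }) |> dplyr::bind_rows()
      stat <- cmi(runs)
      list(correlations = cors, cmi = tidy(stat))
    },
    kl001_sweep = {
      model <- build_config_model(config)
      factors <- config$extra$factors %||% c(1, 2, 5, 10, 100, 1000)
      dose <- kl001_dose_response(model, factors)
      list(dose_response = dose)
    },
    growth = {
      runs <- run_ensemble(config, keep_runs = TRUE)
      fits <- purrr::imap(runs, function(run, id) {
        g <- glance(fit_growth_rate(population_curve(run)))
        g$run_id <- as.integer(id)
        g$seed <- run_seed(config$base_seed, as.integer(id))
        g
      }) |> dplyr::bind_rows()
      list(growth = fits)
    },
    phases = {
      model <- build_config_model(config)
      run <- run_lineage(model, config$noise,
                         n_ancestors = config$n_ancestors,
                         stop = list(max_population = config$max_population,
                                     max_time = config$max_time),
                         config = integrator_config(dt = config$dt,
                                                    record_every =
                                                      config$record_every),
                         seed = run_seed(config$base_seed, 1))
      pp <- phase_proportion_analysis(run)
      list(phase_series = pp$series, ergodic = pp$ergodic)
    },
    custom = {
      runs <- run_ensemble(config)
      list(cells = purrr::imap(runs, function(cells, run) {
        dplyr::mutate(cells, run_id = as.integer(run), .before = 1)
      }) |> dplyr::bind_rows())
    })
  for (nm in names(out)) {
    df <- out[[nm]]
    df$config_hash <- hash
    write.csv(df, file.path(out_dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  invisible(out)
}

#' Deterministic test fixtures
#'
#' Programmatically built inputs with known expected values: a complete
#' three-generation binary lineage (7 divided cells, 8 censored leaves)
#' with known pair counts, pure and mixed sinusoidal tones, and an exact
#' exponential count series.
#'
#' @param seed RNG seed for the randomised IMTs of the tree fixture.
#' @return A list with elements `tree`, `tree_expected_pairs`, `tone24`,
#'   `two_tone`, `exp_counts`.
#' @export
make_fixtures <- function(seed = 1) {
  set.seed(seed)
  ## complete binary tree: ancestor 1; gen1: 2,3; gen2: 4-7; gen3: 8-15
  imt <- round(runif(7, 15, 25), 3)
  birth <- c(0, rep(imt[1], 2), rep(imt[1] + imt[2:3], each = 2))
  cells <- tibble::tibble(
    cell_id = 1:15,
    lineage_id = 1L,
    parent_id = c(NA, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 6L, 6L,
                  7L, 7L),
    generation = c(0L, 1L, 1L, rep(2L, 4), rep(3L, 8)),
    birth_time = c(birth, rep(NA, 8)),
    division_time = c(birth + imt, rep(NA, 8)),
    imt = c(imt, rep(NA, 8)),
    censored = c(rep(FALSE, 7), rep(TRUE, 8)))
  cells$birth_time[8:15] <- cells$division_time[cells$parent_id[8:15]]
  tt <- seq(0, 240, by = 0.1)
  list(tree = cells,
       tree_expected_pairs = c(mother_daughter = 6, sister = 3,
                               cousin = 4, grandmother = 4,
                               great_grandmother = 0),
       tone24 = tibble::tibble(time = tt, value = sin(2 * pi * tt / 24)),
       two_tone = tibble::tibble(time = tt,
                                 value = 2 * sin(2 * pi * tt / 24) +
                                   0.5 * sin(2 * pi * tt / 6)),
       exp_counts = tibble::tibble(time = seq(0, 100, by = 10),
                                   count = 100 * 2^(seq(0, 100, by = 10) /
                                                      20)))
}
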