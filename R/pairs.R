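#' Extract related cell pairs from a lineage table
#'
#' Builds the unique related pairs used for intermitotic-time (IMT)
#' correlations: `sister` (same mother), `mother_daughter` (direct edge),
#' `cousin` (same grandmother, different mothers), `grandmother` and
#' `great_grandmother` (ancestor exactly two / three generations up).  Only
#' pairs in which both members divided (uncensored IMT) are returned; each
#' unordered pair appears exactly once, and for the asymmetric relations
#' the ancestor occupies slot `a`.
#'
#' @param cells A cell table ([lineage_cells()]) or `lineage_run`.
#' @param relation One of `"sister"`, `"mother_daughter"`, `"cousin"`,
#'   `"grandmother"`, `"great_grandmother"`.
#' @return A tibble with columns `relation`, `id_a`, `id_b`, `imt_a`,
#'   `imt_b`.
#' @export
extract_pairs <- function(cells, relation) {
  if (inherits(cells, "lineage_run")) cells <- cells$cells
  relation <- match.arg(relation, cl_relations)
  cells <- as.data.frame(cells)
  anc_of <- function(ids, k) {
    for (i in seq_len(k)) ids <- cells$parent_id[match(ids, cells$cell_id)]
    ids
  }
  div <- cells[!cells$censored & !is.na(cells$imt), ]
  pairs <- switch(
    relation,
    mother_daughter = ,
    grandmother = ,
    great_grandmother = {
      k <- switch(relation, mother_daughter = 1L, grandmother = 2L,
                  great_grandmother = 3L)
      anc <- anc_of(div$cell_id, k)
      ok <- !is.na(anc) & anc %in% div$cell_id
      data.frame(id_a = anc[ok], id_b = div$cell_id[ok])
    },
    sister = {
      kids <- div[!is.na(div$parent_id), ]
      sp <- split(kids$cell_id, kids$parent_id)
      sp <- sp[lengths(sp) == 2]
      if (!length(sp)) {
        data.frame(id_a = integer(), id_b = integer())
      } else {
        m <- do.call(rbind, lapply(sp, sort))
        data.frame(id_a = m[, 1], id_b = m[, 2])
      }
    },
    cousin = {
      gm <- anc_of(div$cell_id, 2L)
      mo <- anc_of(div$cell_id, 1L)
      ok <- !is.na(gm)
      d <- data.frame(id = div$cell_id[ok], mo = mo[ok], gm = gm[ok])
      out <- lapply(split(d, d$gm), function(grp) {
        if (nrow(grp) < 2) return(NULL)
        cmb <- utils::combn(nrow(grp), 2)
        sel <- grp$mo[cmb[1, ]] != grp$mo[cmb[2, ]]
        if (!any(sel)) return(NULL)
        data.frame(id_a = pmin(grp$id[cmb[1, sel]], grp$id[cmb[2, sel]]),
                   id_b = pmax(grp$id[cmb[1, sel]], grp$id[cmb[2, sel]]))
      })
      out <- dplyr::bind_rows(out)
      if (!nrow(out)) data.frame(id_a = integer(), id_b = integer()) else out
    })
  imt <- cells$imt[match(pairs$id_a, cells$cell_id)]
  tibble::tibble(relation = relation,
                 id_a = pairs$id_a, id_b = pairs$id_b,
                 imt_a = imt,
                 imt_b = cells$imt[match(pairs$id_b, cells$cell_id)])
}

cl_relations <- c("sister", "mother_daughter", "cousin", "grandmother",
                  "great_grandmother")

cl_symmetric_relations <- c("sister", "cousin")

#' Pearson correlation of a relation pair set
#'
#' Symmetric relations (sister, cousin) are symmetrised by including each
#' pair in both orders before computing the product-moment correlation.
#' With fewer than three pairs, or zero variance in either margin, the
#' correlation is undefined and `NA` is returned with a warning of class
#' `clocklineage_undefined_correlation`.
#'
#' @param pairs A pair tibble from [extract_pairs()].
#' @return A single correlation in `[-1, 1]`, or `NA`.
#' @export
pearson_pairs <- function(pairs) {
  x <- pairs$imt_a
  y <- pairs$imt_b
  rel <- if (nrow(pairs)) as.character(pairs$relation[1]) else ""
  if (rel %in% cl_symmetric_relations) {
    xy <- c(x, y)
    y <- c(y, x)
    x <- xy
  }
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0 ||
      any(!is.finite(c(x, y)))) {
    warning(warningCondition(
      paste0("undefined correlation (", length(x), " pairs)"),
      class = "clocklineage_undefined_correlation"))
    return(NA_real_)
  }
  cor(x, y)
}

#' Correlation summary over relations
#'
#' @param cells A cell table or `lineage_run`.
#' @param relations Character vector of relations.
#' @return A tibble with `relation`, `r`, `n_pairs`.
#' @export
correlation_summary <- function(cells, relations = c("sister",
                                                     "mother_daughter",
                                                     "cousin")) {
  rows <- lapply(relations, function(rel) {
    p <- extract_pairs(cells, rel)
    r <- suppressWarnings(pearson_pairs(p))
    tibble::tibble(relation = rel, r = r, n_pairs = nrow(p))
  })
  dplyr::bind_rows(rows)
}

#' Cousin-mother inequality statistic
#'
#' For each run, `delta = r_cousin - r_mother_daughter`; the cousin-mother
#' inequality is present when the ensemble median delta is positive.
#'
#' @param runs A list of cell tables (one per run), a single cell table, or
#'   a tibble with a `run_id` column.
#' @return A `cmi_stat` object: per-run tibble plus the ensemble median.
#' @export
cmi <- function(runs) {
  runs <- as_run_list(runs)
  per_run <- purrr::imap(runs, function(cells, run) {
    cs <- correlation_summary(cells, c("cousin", "mother_daughter"))
    tibble::tibble(
      run_id = run,
      r_cousin = cs$r[cs$relation == "cousin"],
      r_mother_daughter = cs$r[cs$relation == "mother_daughter"],
      n_cousin = cs$n_pairs[cs$relation == "cousin"],
      n_mother_daughter = cs$n_pairs[cs$relation == "mother_daughter"],
      delta = .data$r_cousin - .data$r_mother_daughter)
  }) |> dplyr::bind_rows()
  structure(list(per_run = per_run,
                 median_delta = median(per_run$delta, na.rm = TRUE)),
            class = "cmi_stat")
}

as_run_list <- function(runs) {
  if (inherits(runs, "lineage_run")) return(list(`1` = runs$cells))
  if (is.data.frame(runs)) {
    if ("run_id" %in% names(runs)) {
      return(split(runs, runs$run_id))
    }
    return(list(`1` = runs))
  }
  if (is.list(runs)) {
    runs <- lapply(runs, function(r) {
      if (inherits(r, "lineage_run")) r$cells else r
    })
    if (is.null(names(runs))) names(runs) <- seq_along(runs)
    return(runs)
  }
  stop("cannot interpret `runs` as a run ensemble")
}

#' @export
print.cmi_stat <- function(x, ...) {
  cat("<cmi_stat>", nrow(x$per_run), "run(s); median delta =",
      signif(x$median_delta, 4), "\n")
  invisible(x)
}

#' @rdname cmi
#' @param x A `cmi_stat`.
#' @param ... Unused.
#' @export
tidy.cmi_stat <- function(x, ...) x$per_run

#' @rdname cmi
#' @export
glance.cmi_stat <- function(x, ...) {
  d <- x$per_run$delta
  tibble::tibble(n_runs = nrow(x$per_run),
                 median_delta = x$median_delta,
                 mean_delta = mean(d, na.rm = TRUE),
                 sd_delta = sd(d, na.rm = TRUE),
                 n_undefined = sum(is.na(d)))
}

#' Bootstrap confidence interval for the median CMI delta
#'
#' @param x A `cmi_stat`.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @return Named numeric `c(lower, upper)`.
#' @export
cmi_boot_ci <- function(x, n_boot = 2000, conf = 0.95) {
  d <- x$per_run$delta
  d <- d[!is.na(d)]
  meds <- vapply(seq_len(n_boot), function(i) {
    median(sample(d, length(d), replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  setNames(quantile(meds, c(alpha, 1 - alpha), names = FALSE),
           c("lower", "upper"))
}

#' Vertical-generation IMT correlation
#'
#' Pearson correlation between a cell's IMT and that of its k-th generation
#' ancestor (k = 1 mother, 2 grandmother, 3 great-grandmother).
#'
#' @param cells A cell table or `lineage_run`.
#' @param k Generations up (1, 2 or 3).
#' @return A correlation (or `NA` with warning when undefined).
#' @export
vertical_correlation <- function(cells, k) {
  rel <- switch(as.character(k), `1` = "mother_daughter",
                `2` = "grandmother", `3` = "great_grandmother",
                stop("k must be 1, 2 or 3"))
  pearson_pairs(extract_pairs(cells, rel))
}

#' IMT summary statistics
#'
#' Sample moments of the intermitotic times of divided (uncensored) cells;
#' the SD uses the n-1 denominator.
#'
#' @param cells A cell table, `lineage_run`, or numeric vector of IMTs.
#' @return A tibble with `n`, `mean`, `sd`, `cv`.
#' @export
imt_stats <- function(cells) {
  imt <- if (is.numeric(cells)) {
    cells[!is.na(cells)]
  } else {
    if (inherits(cells, "lineage_run")) cells <- cells$cells
    cells$imt[!cells$censored & !is.na(cells$imt)]
  }
  if (length(imt) < 2) stop("need at least 2 uncensored IMTs")
  m <- mean(imt)
  s <- sd(imt)
  tibble::tibble(n = length(imt), mean = m, sd = s, cv = s / m)
}

#' Percent change of a median metric against a reference ensemble
#'
#' `100 * (median(test) - median(reference)) / median(reference)`.
#'
#' @param test,reference Numeric vectors of per-run metric values.
#' @return Percent change (scalar).
#' @export
percent_change <- function(test, reference) {
  if (!length(test) || !length(reference)) {
    stop("both ensembles must be non-empty")
  }
  mref <- median(reference, na.rm = TRUE)
  if (!is.finite(mref) || mref == 0) {
    stop("reference median is zero or undefined")
  }
  100 * (median(test, na.rm = TRUE) - mref) / mref
}
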