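## Independent oracles used across test files.

## O(n^2) classification of every unordered pair of divided cells by the
## depth of their lowest common ancestor; the reference for extract_pairs().
brute_force_pairs <- function(cells, relation) {
  cells <- as.data.frame(cells)
  chain <- function(id) {
    out <- integer()
    while (!is.na(id)) {
      out <- c(out, id)
      id <- cells$parent_id[match(id, cells$cell_id)]
    }
    out
  }
  div <- cells$cell_id[!cells$censored & !is.na(cells$imt)]
  if (length(div) < 2) return(data.frame(id_a = integer(), id_b = integer()))
  chains <- lapply(div, chain)
  names(chains) <- div
  res <- list()
  for (i in seq_along(div)) {
    for (j in seq_along(div)) {
      if (i >= j) next
      a <- div[i]; b <- div[j]
      ca <- chains[[as.character(a)]]
      cb <- chains[[as.character(b)]]
      common <- intersect(ca, cb)
      if (!length(common)) next
      lca <- common[which.min(match(common, ca))]
      da <- match(lca, ca) - 1L  # generations from a up to LCA
      db <- match(lca, cb) - 1L
      hit <- switch(relation,
        sister = (da == 1L && db == 1L),
        mother_daughter = (min(da, db) == 0L && max(da, db) == 1L),
        cousin = (da == 2L && db == 2L &&
                    ca[2] != cb[2]),  # different mothers
        grandmother = (min(da, db) == 0L && max(da, db) == 2L),
        great_grandmother = (min(da, db) == 0L && max(da, db) == 3L))
      if (hit) {
        if (relation %in% c("mother_daughter", "grandmother",
                            "great_grandmother")) {
          ## ancestor first
          if (da == 0L) res[[length(res) + 1L]] <- c(a, b)
          else res[[length(res) + 1L]] <- c(b, a)
        } else {
          res[[length(res) + 1L]] <- c(min(a, b), max(a, b))
        }
      }
    }
  }
  if (!length(res)) return(data.frame(id_a = integer(), id_b = integer()))
  m <- do.call(rbind, res)
  data.frame(id_a = m[, 1], id_b = m[, 2])
}

## random binary lineage forest with iid IMTs and random censoring
random_forest <- function(n_lineages = 2, max_gen = 4, p_divide = 0.8,
                          imt_fun = function(n) runif(n, 10, 30)) {
  rows <- list()
  nid <- 0L
  for (li in seq_len(n_lineages)) {
    nid <- nid + 1L
    queue <- data.frame(cell_id = nid, parent_id = NA_integer_,
                        generation = 0L, birth_time = 0)
    while (nrow(queue)) {
      cell <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      divides <- cell$generation < max_gen && runif(1) < p_divide
      imt <- if (divides) imt_fun(1) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell$cell_id, lineage_id = li,
        parent_id = cell$parent_id, generation = cell$generation,
        birth_time = cell$birth_time,
        division_time = cell$birth_time + imt,
        imt = imt, censored = !divides)
      if (divides) {
        kids <- data.frame(cell_id = c(nid + 1L, nid + 2L),
                           parent_id = cell$cell_id,
                           generation = cell$generation + 1L,
                           birth_time = cell$birth_time + imt)
        nid <- nid + 2L
        queue <- rbind(queue, kids)
      }
    }
  }
  tibble::as_tibble(dplyr::bind_rows(rows))
}

## damped Newton with a finite-difference Jacobian; used to locate fixed
## points of the deterministic vector field independently of integration
newton_fixed_point <- function(f, x0, tol = 1e-12, max_iter = 300) {
  x <- x0
  n <- length(x)
  for (it in seq_len(max_iter)) {
    fx <- f(x)
    if (max(abs(fx)) < tol) break
    J <- matrix(0, n, n)
    h <- pmax(1e-7, 1e-7 * abs(x))
    for (j in seq_len(n)) {
      xp <- x
      xp[j] <- xp[j] + h[j]
      J[, j] <- (f(xp) - fx) / h[j]
    }
    step <- tryCatch(solve(J, fx), error = function(e) qr.solve(J, fx))
    lam <- 1
    improved <- FALSE
    while (lam >= 1e-6) {
      xn <- pmax(x - lam * step, 0)
      if (max(abs(f(xn))) < max(abs(fx))) {
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
    x <- xn
  }
  x
}

## small shared models, built once per test session
cached_model <- local({
  cache <- list()
  function(key, builder) {
    if (is.null(cache[[key]])) cache[[key]] <<- builder()
    cache[[key]]
  }
})

model2_default <- function() {
  cached_model("m2_tcc20", function() build_model(2, autonomous_TCC = 20))
}
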