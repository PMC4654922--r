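#' Permute the trait column of a dataset
#'
#' Returns a copy of the dataset whose trait is a uniform random
#' permutation of the original (genotypes untouched), drawn from the
#' current RNG state.
#'
#' @param dataset an [mbmdr_dataset()].
#' @return A permuted [mbmdr_dataset()].
#' @export
permute_trait <- function(dataset) {
  dataset$trait <- dataset$trait[sample.int(length(dataset$trait))]
  dataset
}

#' Exact maximum statistic over the non-stored pairs
#'
#' Exhaustively evaluates every pair not in `top_pairs` under the (usually
#' permuted) dataset and returns the maximum statistic.  When the stored
#' pairs exhaust all pairs the remainder is empty and the maximum is 0 by
#' convention.
#'
#' @param dataset an [mbmdr_dataset()] (typically trait-permuted).
#' @param top_pairs data.frame with columns `snp_a`, `snp_b`: the stored
#'   pairs to exclude.
#' @inheritParams scan_all_pairs
#' @return The exact remainder maximum, a non-negative number.
#' @export
exact_remainder_max <- function(dataset, top_pairs, alpha_cell = 0.1,
                                adjust_main = FALSE, min_cell = 10) {
  r <- cpp_perm_exact(dataset$genotypes, as.numeric(dataset$trait),
                      as.integer(top_pairs$snp_a),
                      as.integer(top_pairs$snp_b),
                      dataset$trait_type == "binary", alpha_cell, adjust_main,
                      min_cell)
  if (!r$any_rest) 0 else r$max_rest
}

#' Force a vector to be non-increasing (suffix maximum)
#'
#' Walking from the last rank to the first, each entry is replaced by the
#' maximum of itself and its successor, so the permutation vector is
#' non-increasing in rank; idempotent.
#'
#' @param stats numeric vector ordered by observed rank.
#' @return The suffix-maximum vector.
#' @export
enforce_monotone_desc <- function(stats) {
  rev(cummax(rev(stats)))
}

#' Adjusted p-values from permutation records (step-down maxT)
#'
#' For each stored rank `j`, counts the permutations whose (monotonized)
#' statistic at rank `j` reaches the observed `T0_j`, sets
#' `p_j = (1 + count) / (B + 1)` — the observed statistic counts as one
#' exceedance, bounding p away from 0 — and finally forces step-down
#' monotonicity so adjusted p-values never decrease with rank.
#'
#' @param records list of permutation records as returned by
#'   [run_permutation()] (each with a `stats` vector).
#' @param toplist the observed [scan_all_pairs()] `top_list`.
#' @return A data.frame `rank, snp_a, snp_b, statistic, p_adj`.
#' @export
finalize_pvalues <- function(records, toplist) {
  B <- length(records)
  stopifnot(B >= 1)
  counts <- numeric(nrow(toplist))
  for (rec in records) counts <- counts + (rec$stats >= toplist$statistic)
  p <- (1 + counts) / (B + 1)
  p <- cummax(p)
  data.frame(rank = toplist$rank, snp_a = toplist$snp_a,
             snp_b = toplist$snp_b, statistic = toplist$statistic,
             p_adj = p)
}

#' Engine state shared across the permutations of one run
#'
#' Holds the dataset, the stored top list and the tail-fit configuration;
#' the gamma backend caches its latest [fit_tail()] here between refits.
#'
#' @param dataset,toplist the scanned data and stored pairs.
#' @param backend `"gamma"` (sampled remainder maximum) or `"exact"`.
#' @param S,tail_fraction,refit_interval,precision,initial_guess gammaMAXT
#'   tuning parameters, see [gamma_maxt()].
#' @return An environment of class `maxt_state`.
#' @export
maxt_state <- function(dataset, toplist, backend = c("gamma", "exact"),
                       S = 1e6, tail_fraction = 0.10, refit_interval = 20,
                       precision = 1e-6, initial_guess = 1000) {
  backend <- match.arg(backend)
  st <- new.env(parent = emptyenv())
  st$dataset <- dataset
  st$toplist <- toplist
  st$backend <- backend
  st$m <- attr(toplist, "m")
  st$n_stored <- nrow(toplist)
  st$alpha_cell <- attr(toplist, "alpha_cell")
  st$adjust <- attr(toplist, "adjust_main")
  st$min_cell <- attr(toplist, "min_cell")
  if (is.null(st$min_cell)) st$min_cell <- 10
  st$S <- as.integer(min(S, max(100, st$m - st$n_stored)))
  st$tail_fraction <- tail_fraction
  st$refit_interval <- refit_interval
  st$precision <- precision
  st$initial_guess <- initial_guess
  s <- ncol(dataset$genotypes)
  st$excluded <- sort((toplist$snp_a - 1) * s -
                        (toplist$snp_a - 1) * toplist$snp_a / 2 +
                        (toplist$snp_b - toplist$snp_a - 1))
  st$fit <- NULL
  st$fits <- list()
  class(st) <- "maxt_state"
  st
}

#' Run one permutation of the step-down engine
#'
#' Permutes the trait (or accepts a given permutation), recomputes the
#' statistics of the stored pairs, obtains the remainder maximum `M_i` —
#' exactly, or sampled from the gamma tail model, refitted on permutations
#' `1, 1 + refit_interval, ...` and reused in between — replaces the last
#' stored statistic by `M_i` when smaller, and monotonizes.
#'
#' @param i permutation index (1-based); drives the refit schedule.
#' @param state a [maxt_state()].
#' @param perm optional permutation of individuals; defaults to a fresh
#'   random one.
#' @return A list `(i, stats, M)`; `stats` is non-increasing.
#' @export
run_permutation <- function(i, state, perm = NULL) {
  ds <- state$dataset
  if (is.null(perm)) perm <- sample.int(length(ds$trait))
  y <- as.numeric(ds$trait[perm])
  binary <- ds$trait_type == "binary"
  stats <- cpp_stats_pairs(ds$genotypes, y,
                           as.integer(state$toplist$snp_a),
                           as.integer(state$toplist$snp_b),
                           binary, state$alpha_cell, state$adjust,
                           state$min_cell)
  if (state$m > state$n_stored) {
    if (state$backend == "exact") {
      ds_p <- ds
      ds_p$trait <- y
      M <- exact_remainder_max(ds_p, state$toplist, state$alpha_cell,
                               state$adjust, state$min_cell)
    } else {
      if ((i - 1) %% state$refit_interval == 0 || is.null(state$fit)) {
        raw <- cpp_sample_tail(ds$genotypes, y, as.numeric(state$excluded),
                               state$S, 1000 * state$S, binary,
                               state$alpha_cell, state$adjust,
                               state$min_cell)
        smp <- new_tail_sample(raw$v, raw$z, state$S, state$tail_fraction)
        state$fit <- fit_tail(smp, state$m, state$n_stored,
                              tol = state$precision)
        state$fits[[length(state$fits) + 1]] <-
          c(i = i, unlist(state$fit[c("pi", "y0", "k", "theta", "q")]))
      }
      M <- sample_max(state$fit, state$initial_guess, state$precision)
    }
  } else {
    M <- 0
  }
  nlast <- length(stats)
  if (stats[nlast] < M) stats[nlast] <- M
  list(i = i, stats = enforce_monotone_desc(stats), M = M)
}

#' Pairwise epistasis scan with permutation-based FWER control
#'
#' The central fitting function of the package.  Scans all SNP pairs with
#' the MB-MDR statistic, keeps the `n` best, and adjusts their p-values for
#' the full family of pairs by step-down maxT over `B` trait permutations.
#' Three backends provide the per-permutation maximum over the non-stored
#' pairs:
#'
#' * `"gamma"` (gammaMAXT, the default): the maximum is sampled from a
#'   point-mass-at-zero + shifted-gamma tail mixture fitted to a random
#'   sample of `S` strictly positive null statistics, refitted every
#'   `refit_interval` permutations.  Cost per permutation is independent
#'   of the number of pairs.
#' * `"exact"`: the memory-bounded variant — the remainder maximum is
#'   computed exhaustively.
#' * `"classical"`: textbook step-down maxT over all pairs (stores all
#'   statistics; small panels only).  Its top-`n` adjusted p-values agree
#'   exactly with `"exact"` under shared permutation streams.
#'
#' Reproducibility: a master `seed` derives one RNG substream per
#' permutation, so runs are identical for a fixed seed regardless of how
#' permutations are partitioned over workers, and backends sharing a seed
#' see identical trait permutations.
#'
#' @param dataset an [mbmdr_dataset()].
#' @param n number of top pairs stored and reported (default 1000).
#' @param B number of trait permutations (default 999).
#' @param backend `"gamma"`, `"exact"` or `"classical"`.
#' @param S target tail-sample size of strictly positive statistics per
#'   refit (default `1e6`, capped at the number of available pairs).
#' @param tail_fraction fraction of positive values kept for the tail fit
#'   (default 0.10).
#' @param refit_interval permutations between tail refits (default 20).
#' @param alpha_cell cell-labelling significance level (default 0.1).
#' @param min_cell minimum cell size eligible for H/L labelling (default
#'   10); see [categorize_cells()].
#' @param precision Newton-Raphson and bisection tolerance (default
#'   `1e-6`).
#' @param correct_main apply the pair-local codominant main-effect
#'   correction (residualized trait, continuous tests) to every pair.
#' @param seed master seed; `NULL` uses the current RNG state.
#' @param initial_guess starting upper bound for the maximum bisection.
#' @param verbose print fitted tail parameters at each refit.
#' @return An object of class `maxt_result`; see [print.maxt_result()].
#'   Component `table` holds `rank`, `snp_a`, `snp_b`, `statistic`,
#'   `p_adj`.
#' @examples
#' d <- simulate_null(n_snps = 12, n_individuals = 80, seed = 1)
#' fit <- gamma_maxt(d, n = 10, B = 49, backend = "exact", seed = 7)
#' fit
#' @export
gamma_maxt <- function(dataset, n = 1000, B = 999,
                       backend = c("gamma", "exact", "classical"),
                       S = 1e6, tail_fraction = 0.10, refit_interval = 20,
                       alpha_cell = 0.1, min_cell = 10, precision = 1e-6,
                       correct_main = FALSE, seed = NULL,
                       initial_guess = 1000, verbose = FALSE) {
  backend <- match.arg(backend)
  stopifnot(B >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  toplist <- scan_all_pairs(dataset, n = n, alpha_cell = alpha_cell,
                            adjust_main = correct_main, min_cell = min_cell)
  perm_seeds <- sample.int(2147483646L, B)
  if (backend == "classical") {
    tab <- classical_maxt_engine(dataset, toplist, B, perm_seeds,
                                 alpha_cell, correct_main, min_cell)
    fits <- list()
  } else {
    st <- maxt_state(dataset, toplist, backend, S = S,
                     tail_fraction = tail_fraction,
                     refit_interval = refit_interval, precision = precision,
                     initial_guess = initial_guess)
    records <- vector("list", B)
    for (i in seq_len(B)) {
      set.seed(perm_seeds[i])
      records[[i]] <- run_permutation(i, st)
      if (verbose && state_refitted(st, i))
        print(st$fit)
    }
    tab <- finalize_pvalues(records, toplist)
    fits <- st$fits
  }
  structure(list(table = tab, backend = backend, n = nrow(toplist), B = B,
                 m = attr(toplist, "m"), alpha_cell = alpha_cell,
                 correct_main = correct_main, trait_type = dataset$trait_type,
                 n_individuals = nrow(dataset$genotypes),
                 n_snps = ncol(dataset$genotypes), snp_ids = dataset$snp_ids,
                 fits = fits, seed = seed, call = match.call()),
            class = "maxt_result")
}

state_refitted <- function(st, i) {
  length(st$fits) > 0 && st$fits[[length(st$fits)]]["i"] == i
}

# Classical step-down maxT over all m pairs; reference backend for small
# panels.  Shares the per-permutation seed discipline of the other
# backends, so the three agree on the permutations they see.
classical_maxt_engine <- function(dataset, toplist, B, perm_seeds,
                                  alpha_cell, adjust, min_cell = 10) {
  g <- dataset$genotypes
  s <- ncol(g)
  binary <- dataset$trait_type == "binary"
  obs <- cpp_all_stats(g, as.numeric(dataset$trait), binary, alpha_cell,
                       adjust, min_cell)
  ord <- order(-obs, seq_along(obs))      # stat desc, pair index asc
  obs_sorted <- obs[ord]
  counts <- numeric(length(obs))
  for (i in seq_len(B)) {
    set.seed(perm_seeds[i])
    perm <- sample.int(length(dataset$trait))
    ps <- cpp_all_stats(g, as.numeric(dataset$trait[perm]), binary,
                        alpha_cell, adjust, min_cell)
    u <- rev(cummax(rev(ps[ord])))        # successive maxima, step-down
    counts <- counts + (u >= obs_sorted)
  }
  p <- cummax((1 + counts) / (B + 1))
  keep <- seq_len(nrow(toplist))
  lin <- ord[keep] - 1
  a <- floor(s - 0.5 - sqrt((s - 0.5)^2 - 2 * lin))
  off <- a * s - a * (a + 1) / 2
  a <- ifelse(lin < off, a - 1, a)
  off <- a * s - a * (a + 1) / 2
  b <- a + 1 + (lin - off)
  data.frame(rank = keep, snp_a = as.integer(a + 1), snp_b = as.integer(b + 1),
             statistic = obs_sorted[keep], p_adj = p[keep])
}

#' @describeIn gamma_maxt print method: top of the adjusted p-value table.
#' @param x,... method arguments.
#' @export
print.maxt_result <- function(x, ...) {
  cat(sprintf(
    "MB-MDR pairwise scan, %s backend: %d SNPs (%s pairs), %d individuals, %s trait\n",
    x$backend, x$n_snps, format(x$m, big.mark = ","), x$n_individuals,
    x$trait_type))
  cat(sprintf("  %d permutations, %d pairs stored%s\n", x$B, x$n,
              if (x$correct_main) ", codominant main-effect correction" else ""))
  top <- utils::head(x$table, 5)
  top$snp_a <- x$snp_ids[top$snp_a]
  top$snp_b <- x$snp_ids[top$snp_b]
  print(top, row.names = FALSE)
  if (x$n > 5) cat("  ...", x$n - 5, "more rows\n")
  invisible(x)
}

#' @export
summary.maxt_result <- function(object, alpha = 0.05, ...) {
  tab <- object$table
  sig <- tab[tab$p_adj < alpha, , drop = FALSE]
  cat(sprintf("%d of %d stored pairs significant at FWER %.2g (min p = %.4g)\n",
              nrow(sig), nrow(tab), alpha, min(tab$p_adj)))
  if (length(object$fits) > 0) {
    f <- do.call(rbind, object$fits)
    cat("gamma tail refits:\n")
    print(round(f, 4), row.names = FALSE)
  }
  invisible(sig)
}

#' @export
as.data.frame.maxt_result <- function(x, ...) x$table

#' @export
plot.maxt_result <- function(x, ...) {
  tab <- x$table
  plot(tab$rank, tab$p_adj, type = "s", xlab = "rank",
       ylab = "adjusted p-value", ylim = c(0, 1),
       main = sprintf("step-down maxT (%s backend)", x$backend), ...)
  graphics::abline(h = 0.05, lty = 2, col = "grey40")
  invisible(x)
}
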