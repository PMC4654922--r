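#' Two-locus cross-tabulation for one SNP pair
#'
#' Tabulates the nine two-locus genotype cells of a SNP pair.  Individuals
#' missing either genotype are excluded from all cells (pairwise-complete
#' analysis).  For binary traits the table holds case and control counts;
#' for continuous traits it holds per-cell trait sums and sums of squares.
#'
#' @param dataset an [mbmdr_dataset()].
#' @param pair integer vector of length 2: SNP column indices (1-based).
#' @return An object of class `pair_crosstab` with 3x3 matrices `n` (counts)
#'   and, depending on the trait type, `cases`/`controls` or `sum`/`sumsq`,
#'   plus `trait_type`, the `pair` and the per-cell trait values (`values`,
#'   a 3x3 list matrix) used by downstream tests.
#' @export
crosstab_pair <- function(dataset, pair) {
  stopifnot(length(pair) == 2)
  pair <- as.integer(pair)
  s <- ncol(dataset$genotypes)
  if (any(pair < 1 | pair > s)) stop("pair indices out of range")
  if (pair[1] == pair[2]) stop("self-pair: the two SNP indices must differ")
  g1 <- dataset$genotypes[, pair[1]]
  g2 <- dataset$genotypes[, pair[2]]
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  y <- dataset$trait[keep]
  dn <- list(g1 = 0:2, g2 = 0:2)
  n <- matrix(0, 3, 3, dimnames = dn)
  values <- matrix(vector("list", 9), 3, 3, dimnames = dn)
  if (dataset$trait_type == "binary") {
    cases <- controls <- matrix(0, 3, 3, dimnames = dn)
  } else {
    sum_ <- sumsq <- matrix(0, 3, 3, dimnames = dn)
  }
  for (a in 0:2) for (b in 0:2) {
    idx <- g1 == a & g2 == b
    n[a + 1, b + 1] <- sum(idx)
    values[[a + 1, b + 1]] <- y[idx]
    if (dataset$trait_type == "binary") {
      cases[a + 1, b + 1] <- sum(y[idx] == 1)
      controls[a + 1, b + 1] <- sum(y[idx] == 0)
    } else {
      sum_[a + 1, b + 1] <- sum(y[idx])
      sumsq[a + 1, b + 1] <- sum(y[idx]^2)
    }
  }
  out <- list(n = n, trait_type = dataset$trait_type, pair = pair,
              n_used = sum(keep), values = values)
  if (dataset$trait_type == "binary") {
    out$cases <- cases
    out$controls <- controls
  } else {
    out$sum <- sum_
    out$sumsq <- sumsq
  }
  structure(out, class = "pair_crosstab")
}

#' Label two-locus genotype cells as higher-risk, lower-risk, or undecided
#'
#' Each of the nine cells is tested one-vs-rest for association with the
#' trait: a Pearson chi-squared test on the 2x2 case/control collapse for
#' binary traits, a pooled-variance two-sample t test for continuous traits (pooling keeps
#' the squared statistic on a chi-squared(1)-like scale even for tiny
#' cells, which the gamma tail model downstream relies on).  Cells
#' significant at `alpha_cell` are labelled `H` when the cell's case rate
#' (or mean trait) exceeds the remaining subjects' and `L` when it is
#' below; empty cells and cells whose test is incomputable are `O`.
#'
#' @param ct a [crosstab_pair()] result.
#' @param alpha_cell per-cell significance level in (0, 1); default 0.1,
#'   the conventional MB-MDR setting.
#' @param min_cell minimum number of subjects a cell needs to be eligible
#'   for an H/L label (default 10, the published MB-MDR convention);
#'   smaller cells are always O.  Keeping tiny cells out of the risk pools
#'   also keeps the null statistic tail gamma-compatible.
#' @return A 3x3 character matrix with entries `"H"`, `"L"` or `"O"`.
#' @export
categorize_cells <- function(ct, alpha_cell = 0.1, min_cell = 10) {
  stopifnot(inherits(ct, "pair_crosstab"),
            alpha_cell > 0, alpha_cell < 1)
  hlo <- matrix("O", 3, 3, dimnames = dimnames(ct$n))
  for (i in 1:3) for (j in 1:3) {
    if (ct$n[i, j] < min_cell || ct$n[i, j] == 0) next
    if (ct$trait_type == "binary") {
      a <- ct$cases[i, j]; b <- ct$controls[i, j]
      cc <- sum(ct$cases) - a; d <- sum(ct$controls) - b
      tab <- matrix(c(a, cc, b, d), 2, 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      if (!is.finite(chi$statistic)) next
      crit <- stats::qchisq(1 - alpha_cell, df = 1)
      if (chi$statistic > crit)
        hlo[i, j] <- if (a / (a + b) > cc / (cc + d)) "H" else "L"
    } else {
      x <- ct$values[[i, j]]
      rest <- unlist(ct$values[-((j - 1) * 3 + i)])
      tt <- tryCatch(stats::t.test(x, rest, var.equal = TRUE), error = function(e) NULL)
      if (is.null(tt) || !is.finite(tt$statistic)) next
      if (tt$p.value < alpha_cell)
        hlo[i, j] <- if (tt$statistic > 0) "H" else "L"
    }
  }
  hlo
}

#' MB-MDR association statistic from labelled cells
#'
#' Pools the `H`-labelled cells and tests them against all remaining
#' subjects (Pearson chi-squared for binary traits; squared pooled-variance t for
#' continuous traits), does the same for the `L` cells, and returns the
#' larger of the two statistics.  An absent category contributes 0 and an
#' all-`O` table returns an exact 0, the point mass exploited by the
#' gammaMAXT null model.
#'
#' @param hlo 3x3 label matrix from [categorize_cells()].
#' @param ct the matching [crosstab_pair()] result.
#' @return A single non-negative number.
#' @export
mbmdr_statistic <- function(hlo, ct) {
  stopifnot(inherits(ct, "pair_crosstab"), all(hlo %in% c("H", "L", "O")))
  one_side <- function(label) {
    sel <- hlo == label
    if (!any(sel)) return(0)
    if (ct$trait_type == "binary") {
      a <- sum(ct$cases[sel]); b <- sum(ct$controls[sel])
      cc <- sum(ct$cases) - a; d <- sum(ct$controls) - b
      tab <- matrix(c(a, cc, b, d), 2, 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(0)
      chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      if (!is.finite(chi$statistic)) return(0)
      unname(chi$statistic)
    } else {
      x <- unlist(ct$values[sel])
      rest <- unlist(ct$values[!sel])
      tt <- tryCatch(stats::t.test(x, rest, var.equal = TRUE), error = function(e) NULL)
      if (is.null(tt) || !is.finite(tt$statistic)) return(0)
      unname(tt$statistic)^2
    }
  }
  max(one_side("H"), one_side("L"), 0)
}

#' MB-MDR statistic of one SNP pair (reference implementation)
#'
#' Composes [crosstab_pair()], [categorize_cells()] and [mbmdr_statistic()]
#' in plain R.  With `adjust_main = TRUE` the trait is first replaced by
#' the residuals of an OLS regression on the pair's four codominant dummy
#' variables (pair-local main-effect correction) and analysed with the
#' continuous-trait tests.  The compiled scan kernel used by
#' [scan_all_pairs()] computes the same quantity; this function is the
#' readable single-pair route and the oracle the kernel is tested against.
#'
#' @inheritParams crosstab_pair
#' @inheritParams categorize_cells
#' @param adjust_main residualize the trait on the pair's main effects
#'   before testing.
#' @return The non-negative pair statistic.
#' @export
pair_statistic <- function(dataset, pair, alpha_cell = 0.1,
                           adjust_main = FALSE, min_cell = 10) {
  if (adjust_main) dataset <- residualize_pair(dataset, pair)
  ct <- crosstab_pair(dataset, pair)
  mbmdr_statistic(categorize_cells(ct, alpha_cell, min_cell), ct)
}

# Pair-local codominant correction: OLS residuals of the trait on the four
# genotype dummies of the pair, computed on pairwise-complete individuals.
# The residual trait is continuous downstream regardless of its origin.
residualize_pair <- function(dataset, pair) {
  g1 <- dataset$genotypes[, pair[1]]
  g2 <- dataset$genotypes[, pair[2]]
  keep <- !is.na(g1) & !is.na(g2)
  X <- cbind(1, g1 == 1, g1 == 2, g2 == 1, g2 == 2)[keep, , drop = FALSE]
  storage.mode(X) <- "double"
  y <- dataset$trait[keep]
  r <- stats::lm.fit(X, y)$residuals
  mbmdr_dataset(dataset$genotypes[keep, , drop = FALSE], r,
                trait_type = "continuous", snp_ids = dataset$snp_ids)
}

#' Residualize the trait on all SNP main effects (codominant coding)
#'
#' Regresses the trait on the two-dummy codominant encoding of every SNP in
#' a single OLS fit and returns a dataset carrying the residual trait,
#' marked continuous.  Missing genotype dummies are mean-imputed so that
#' every individual is retained.  This global correction is intended for
#' small SNP panels; inside a scan the pair-local correction
#' (`adjust_main = TRUE`) is used instead, which is well-defined at any
#' scale.
#'
#' @param dataset an [mbmdr_dataset()].
#' @return A new [mbmdr_dataset()] with the residual (continuous) trait.
#' @export
correct_main_effects <- function(dataset) {
  y <- dataset$trait
  if (stats::var(y) == 0) stop("degenerate trait: trait is constant")
  g <- dataset$genotypes
  X <- cbind(g == 1, g == 2)
  storage.mode(X) <- "double"
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mean(X[!nas, j])
  }
  r <- stats::lm.fit(cbind(1, X), y)$residuals
  mbmdr_dataset(g, r, trait_type = "continuous", snp_ids = dataset$snp_ids)
}

#' Exhaustive pairwise scan keeping the top n statistics
#'
#' Visits every unordered SNP pair once, computes the MB-MDR statistic with
#' the compiled kernel, and keeps the `n` largest values in bounded memory
#' (a size-`n` heap, independent of the number of pairs).  Ties at the cut
#' are broken deterministically in favour of the lower pair index.
#'
#' @inheritParams pair_statistic
#' @param n number of top pairs to retain (default 1000).
#' @return A `top_list`: a data.frame with columns `rank`, `snp_a`, `snp_b`
#'   (1-based SNP indices, `snp_a < snp_b`) and `statistic`, sorted
#'   non-increasing, with attributes `n` (capacity) and `m` (pairs
#'   visited).
#' @export
scan_all_pairs <- function(dataset, n = 1000, alpha_cell = 0.1,
                           adjust_main = FALSE, min_cell = 10) {
  stopifnot(n >= 1)
  s <- ncol(dataset$genotypes)
  if (s < 2) stop("need at least 2 SNPs")
  m <- n_pairs(dataset)
  if (n > m) {
    warning("n = ", n, " exceeds the number of pairs (", m,
            "); returning all pairs")
    n <- m
  }
  res <- cpp_scan_top(dataset$genotypes,
                      as.numeric(dataset$trait),
                      dataset$trait_type == "binary",
                      alpha_cell, adjust_main, min_cell, as.integer(n))
  out <- data.frame(rank = seq_along(res$statistic), snp_a = res$snp_a,
                    snp_b = res$snp_b, statistic = res$statistic)
  attr(out, "n") <- n
  attr(out, "m") <- m
  attr(out, "alpha_cell") <- alpha_cell
  attr(out, "adjust_main") <- adjust_main
  attr(out, "min_cell") <- min_cell
  class(out) <- c("top_list", "data.frame")
  out
}
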