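# File-based split/merge workflow: the scan and the permutations are
# partitioned into contiguous blocks whose results travel through small
# TSV files, so independent processes (or cluster nodes) can each take a
# block.  Per-permutation RNG substreams keyed off the master seed make
# the merged result identical to a single-worker run.

lin_to_pair <- function(lin, s) {
  a <- floor(s - 0.5 - sqrt((s - 0.5)^2 - 2 * lin))
  off <- a * s - a * (a + 1) / 2
  a <- ifelse(lin < off, a - 1, a)
  off <- a * s - a * (a + 1) / 2
  cbind(a + 1, a + 2 + (lin - off))
}

#' Scan pair blocks and write one top file per worker
#'
#' Splits the lexicographic pair enumeration into `workers` near-equal
#' contiguous blocks, computes each block's statistics and writes its top
#' `n` to `top_<c>.txt` (TSV: rank, snp_a, snp_b, statistic; 1-based SNP
#' indices).
#'
#' @inheritParams scan_all_pairs
#' @param workers number of blocks.
#' @param dir output directory.
#' @return Character vector of the files written.
#' @export
split_scan <- function(dataset, n = 1000, workers = 2, dir = tempdir(),
                       alpha_cell = 0.1, adjust_main = FALSE,
                       min_cell = 10) {
  m <- n_pairs(dataset)
  s <- ncol(dataset$genotypes)
  bounds <- round(seq(0, m, length.out = workers + 1))
  files <- character(workers)
  for (cw in seq_len(workers)) {
    lin <- seq.int(bounds[cw], bounds[cw + 1] - 1)
    pr <- lin_to_pair(lin, s)
    st <- cpp_stats_pairs(dataset$genotypes, as.numeric(dataset$trait),
                          as.integer(pr[, 1]), as.integer(pr[, 2]),
                          dataset$trait_type == "binary", alpha_cell,
                          adjust_main, min_cell)
    ord <- order(-st, lin)[seq_len(min(n, length(st)))]
    tab <- data.frame(rank = seq_along(ord), snp_a = pr[ord, 1],
                      snp_b = pr[ord, 2], statistic = st[ord])
    files[cw] <- file.path(dir, sprintf("top_%d.txt", cw))
    utils::write.table(tab, files[cw], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  files
}

#' Merge per-worker top files into the overall top list
#'
#' @param files top files written by [split_scan()].
#' @param n overall capacity.
#' @param m total number of pairs (for downstream bookkeeping); inferred
#'   as unknown (`NA`) when missing.
#' @param alpha_cell,adjust_main,min_cell scan settings the statistics
#'   were computed under, recorded as attributes.
#' @return A `top_list` as from [scan_all_pairs()].
#' @export
merge_topfiles <- function(files, n = 1000, m = NA, alpha_cell = 0.1,
                           adjust_main = FALSE, min_cell = 10) {
  missing <- !file.exists(files)
  if (any(missing))
    stop("missing worker top file(s): ", paste(files[missing], collapse = ", "))
  tabs <- lapply(files, utils::read.table, header = TRUE, sep = "\t")
  all_ <- do.call(rbind, tabs)
  s_hint <- max(all_$snp_b)
  lin <- (all_$snp_a - 1) * s_hint - (all_$snp_a - 1) * all_$snp_a / 2 +
    (all_$snp_b - all_$snp_a - 1)
  ord <- order(-all_$statistic, lin)[seq_len(min(n, nrow(all_)))]
  out <- data.frame(rank = seq_along(ord), snp_a = all_$snp_a[ord],
                    snp_b = all_$snp_b[ord], statistic = all_$statistic[ord])
  attr(out, "n") <- n
  attr(out, "m") <- m
  attr(out, "alpha_cell") <- alpha_cell
  attr(out, "adjust_main") <- adjust_main
  attr(out, "min_cell") <- min_cell
  class(out) <- c("top_list", "data.frame")
  out
}

# contiguous permutation blocks aligned to the refit schedule, so each
# block starts on a refit permutation and the cached tail fit never has
# to cross a worker boundary
perm_blocks <- function(B, workers, refit_interval) {
  groups <- seq(1, B, by = refit_interval)
  bounds <- unique(round(seq(0, length(groups), length.out = workers + 1)))
  lapply(seq_len(length(bounds) - 1), function(cw) {
    from <- groups[bounds[cw] + 1]
    to <- if (bounds[cw + 1] == length(groups)) B
          else groups[bounds[cw + 1] + 1] - 1
    seq.int(from, to)
  })
}

#' Run a block of permutations and write its exceedance counts
#'
#' Executes permutations `i_set` (using the per-permutation seeds derived
#' from the master seed) and writes `permut_<c>.txt`: a comment line with
#' the block metadata followed by the exceedance count vector `V`, one
#' rank per line.
#'
#' @param dataset,toplist scanned data and stored pairs.
#' @param i_set permutation indices of this block.
#' @param perm_seeds per-permutation seeds for all `B` permutations.
#' @param worker_id block label used in the file name.
#' @param dir output directory.
#' @inheritParams gamma_maxt
#' @return The file written.
#' @export
permute_block <- function(dataset, toplist, i_set, perm_seeds, worker_id,
                          dir = tempdir(), backend = "gamma", S = 1e6,
                          tail_fraction = 0.10, refit_interval = 20,
                          precision = 1e-6, initial_guess = 1000) {
  st <- maxt_state(dataset, toplist, backend, S = S,
                   tail_fraction = tail_fraction,
                   refit_interval = refit_interval, precision = precision,
                   initial_guess = initial_guess)
  V <- numeric(nrow(toplist))
  for (i in i_set) {
    set.seed(perm_seeds[i])
    rec <- run_permutation(i, st)
    V <- V + (rec$stats >= toplist$statistic)
  }
  path <- file.path(dir, sprintf("permut_%d.txt", worker_id))
  con <- file(path, "w")
  writeLines(sprintf("# block %d permutations %d-%d of %d", worker_id,
                     min(i_set), max(i_set), length(perm_seeds)), con)
  utils::write.table(data.frame(rank = seq_along(V), count = V), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Aggregate per-worker exceedance counts into adjusted p-values
#'
#' Sums the count vectors, adds the observed statistic as one exceedance,
#' divides by `B + 1` and forces step-down monotonicity.
#'
#' @param files `permut_<c>.txt` files from [permute_block()].
#' @param toplist the stored top list the counts refer to.
#' @param B total number of permutations across all blocks.
#' @return A data.frame `rank, snp_a, snp_b, statistic, p_adj`.
#' @export
aggregate_counts <- function(files, toplist, B) {
  missing <- !file.exists(files)
  if (any(missing))
    stop("missing worker count file(s): ",
         paste(files[missing], collapse = ", "))
  V <- numeric(nrow(toplist))
  for (f in files) {
    tab <- utils::read.table(f, header = TRUE, sep = "\t", comment.char = "#")
    V <- V + tab$count
  }
  p <- cummax((1 + V) / (B + 1))
  data.frame(rank = toplist$rank, snp_a = toplist$snp_a,
             snp_b = toplist$snp_b, statistic = toplist$statistic,
             p_adj = p)
}

#' Write a result table as TSV
#'
#' Columns `rank, snp_a, snp_b, statistic, p_adj`, tab-separated, full
#' double precision, 1-based SNP indices.
#'
#' @param result a `maxt_result` or the bare result data.frame.
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  tab <- if (inherits(result, "maxt_result")) result$table else result
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
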