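#' Two-locus penetrance model
#'
#' A 3x3 table of penetrances P(case | genotype pair) together with the
#' minor allele frequencies of the two functional loci.  Prevalence `K`
#' (the Hardy-Weinberg-weighted mean penetrance) and broad-sense
#' heritability are derived on construction.
#'
#' @param pen 3x3 numeric matrix of penetrances in \[0, 1\]; rows index
#'   the first locus genotype (0/1/2 minor alleles), columns the second.
#' @param maf_a,maf_b minor allele frequencies of the two loci.
#' @return An object of class `penetrance_model`: list with `pen`,
#'   `maf_a`, `maf_b`, `prevalence` and `h2`.
#' @examples
#' m <- checkerboard_model()   # the 0 / 0.1 checkerboard at MAF 0.5
#' m$prevalence                # 0.05
#' @export
penetrance_model <- function(pen, maf_a = 0.5, maf_b = 0.5) {
  pen <- as.matrix(pen)
  stopifnot(all(dim(pen) == c(3, 3)), all(pen >= 0 & pen <= 1),
            maf_a > 0, maf_a <= 0.5, maf_b > 0, maf_b <= 0.5)
  pg <- outer(hw_probs(maf_a), hw_probs(maf_b))
  K <- sum(pg * pen)
  h2 <- if (K > 0 && K < 1) sum(pg * (pen - K)^2) / (K * (1 - K)) else NA_real_
  structure(list(pen = pen, maf_a = maf_a, maf_b = maf_b, prevalence = K,
                 h2 = h2),
            class = "penetrance_model")
}

hw_probs <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

#' @export
print.penetrance_model <- function(x, ...) {
  cat("two-locus penetrance model (MAFs", x$maf_a, "/", x$maf_b, ")\n")
  print(round(x$pen, 4))
  cat(sprintf("prevalence K = %.4f, heritability h2 = %.4f\n",
              x$prevalence, x$h2))
  invisible(x)
}

#' Checkerboard pure-epistasis penetrance table
#'
#' `pen = base + amplitude * (u %o% u)` where `u` is chosen orthogonal to
#' the Hardy-Weinberg genotype weights, so both single-locus penetrance
#' margins are flat (no main effects) at any MAF.  At MAF 0.5 and
#' `base = amplitude = 0.05` this is exactly the 0 / 0.1 checkerboard used
#' for the reference epistasis datasets.
#'
#' @param base baseline penetrance (equals the prevalence).
#' @param amplitude deviation amplitude; must keep penetrances in \[0, 1\].
#' @param maf shared minor allele frequency of the two functional loci.
#' @return A [penetrance_model()].
#' @export
checkerboard_model <- function(base = 0.05, amplitude = 0.05, maf = 0.5) {
  u <- checker_vector(maf)
  pen <- base - amplitude * outer(u, u)   # heterozygous-rich cells raised
  if (any(pen < 0 | pen > 1))
    stop("amplitude ", amplitude, " pushes penetrances outside [0, 1]")
  penetrance_model(pen, maf, maf)
}

# vector orthogonal to the HW weights with alternating signs, scaled to
# max |u| = 1; at MAF 0.5 this is (1, -1, 1), the classic checkerboard
checker_vector <- function(maf) {
  p <- hw_probs(maf)
  u <- c(1, -(p[1] + p[3]) / p[2], 1)
  u / max(abs(u))
}

#' Broad-sense heritability of a penetrance model
#'
#' Variance explained on the penetrance scale:
#' `h2 = sum(p * (pen - K)^2) / (K * (1 - K))` with Hardy-Weinberg genotype
#' probabilities `p` and prevalence `K` — the definition conventional in
#' two-locus epistasis simulators.
#'
#' @param model a [penetrance_model()].
#' @return The heritability, a number in \[0, 1\].
#' @export
heritability <- function(model) {
  stopifnot(inherits(model, "penetrance_model"))
  K <- model$prevalence
  if (K <= 0 || K >= 1) stop("degenerate model: prevalence K = ", K)
  pg <- outer(hw_probs(model$maf_a), hw_probs(model$maf_b))
  sum(pg * (model$pen - K)^2) / (K * (1 - K))
}

#' Calibrate a pure-epistasis model to a target heritability
#'
#' Scales the amplitude of the zero-main-effect checkerboard pattern by
#' scalar root-finding until [heritability()] hits `h2_target` (within
#' `1e-6`); the single-locus penetrance margins stay flat by construction.
#'
#' @param h2_target desired heritability.
#' @param maf minor allele frequency of both functional loci.
#' @param base baseline penetrance / prevalence (default 0.05).
#' @return A calibrated [penetrance_model()].
#' @export
calibrate_penetrance <- function(h2_target, maf = 0.5, base = 0.05) {
  stopifnot(h2_target >= 0, base > 0, base < 1)
  if (h2_target == 0) return(checkerboard_model(base, 0, maf))
  amp_max <- min(base, 1 - base)
  h_of <- function(a) heritability(checkerboard_model(base, a, maf))
  h_max <- h_of(amp_max)
  if (h2_target > h_max)
    stop("unreachable heritability ", h2_target,
         ": maximum achievable for this pattern is ", signif(h_max, 6))
  amp <- stats::uniroot(function(a) h_of(a) - h2_target,
                        interval = c(0, amp_max), tol = 1e-12)$root
  checkerboard_model(base, amp, maf)
}

#' Simulate a null genotype/trait dataset
#'
#' Per-SNP minor allele frequencies are drawn uniformly on `maf_range` and
#' genotypes sampled under Hardy-Weinberg equilibrium.  A balanced binary
#' trait assigns exactly `floor(n/2)` cases independently of the
#' genotypes; a continuous trait is standard normal.
#'
#' @param n_snps,n_individuals panel dimensions.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param maf_range interval for the uniform MAF draw (default
#'   `c(0.05, 0.5)`).
#' @param balanced for binary traits, fix the case count at `floor(n/2)`
#'   (default) rather than sampling it.
#' @param seed optional seed.
#' @return An [mbmdr_dataset()] with attribute `mafs`.
#' @export
simulate_null <- function(n_snps, n_individuals,
                          trait_type = c("binary", "continuous"),
                          maf_range = c(0.05, 0.5), balanced = TRUE,
                          seed = NULL) {
  trait_type <- match.arg(trait_type)
  if (!is.null(seed)) set.seed(seed)
  mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
  g <- hw_genotypes(n_individuals, mafs)
  trait <- switch(trait_type,
    binary = if (balanced) {
      ncase <- floor(n_individuals / 2)
      sample(c(rep(1, ncase), rep(0, n_individuals - ncase)))
    } else {
      stats::rbinom(n_individuals, 1, 0.5)
    },
    continuous = stats::rnorm(n_individuals))
  d <- mbmdr_dataset(g, trait, trait_type)
  attr(d, "mafs") <- mafs
  d
}

hw_genotypes <- function(n, mafs) {
  g <- vapply(mafs, function(f) stats::rbinom(n, 2L, f), integer(n))
  if (n == 1) g <- matrix(g, nrow = 1)
  g
}

#' Simulate a dataset with one epistatic SNP pair
#'
#' Two functional SNPs follow the penetrance model; the rest are null with
#' MAFs uniform on `maf_range`.  Binary traits use rejection sampling of
#' individuals until `floor(n/2)` cases and the complementary controls are
#' reached (balanced design); continuous traits are
#' `mu * z(g1, g2) + N(0, 1)` where `z` is the standardized penetrance
#' deviation and `mu` is set so the model explains the model's
#' heritability share of the trait variance.
#'
#' @param model a [penetrance_model()].
#' @inheritParams simulate_null
#' @param missing_rate probability that any genotype call is missing.
#' @return An [mbmdr_dataset()] with attributes `causal_pair` (the two
#'   functional SNP column indices, increasing) and `model`.
#' @export
simulate_epistasis <- function(model, n_snps, n_individuals,
                               trait_type = c("binary", "continuous"),
                               maf_range = c(0.05, 0.5), missing_rate = 0,
                               seed = NULL) {
  trait_type <- match.arg(trait_type)
  stopifnot(inherits(model, "penetrance_model"), n_snps >= 2)
  if (!is.null(seed)) set.seed(seed)
  K <- model$prevalence
  if (K <= 0 || K >= 1) stop("degenerate model: prevalence K = ", K)
  n <- n_individuals
  if (trait_type == "binary") {
    ncase <- floor(n / 2)
    nctrl <- n - ncase
    ga_case <- gb_case <- integer(ncase)
    ga_ctrl <- gb_ctrl <- integer(nctrl)
    ic <- it <- 0L
    while (ic < ncase || it < nctrl) {
      a <- stats::rbinom(1, 2, model$maf_a)
      b <- stats::rbinom(1, 2, model$maf_b)
      case <- stats::runif(1) < model$pen[a + 1, b + 1]
      if (case && ic < ncase) {
        ic <- ic + 1L; ga_case[ic] <- a; gb_case[ic] <- b
      } else if (!case && it < nctrl) {
        it <- it + 1L; ga_ctrl[it] <- a; gb_ctrl[it] <- b
      }
    }
    ord <- sample.int(n)
    trait <- c(rep(1, ncase), rep(0, nctrl))[ord]
    ga <- c(ga_case, ga_ctrl)[ord]
    gb <- c(gb_case, gb_ctrl)[ord]
  } else {
    ga <- stats::rbinom(n, 2, model$maf_a)
    gb <- stats::rbinom(n, 2, model$maf_b)
    pg <- outer(hw_probs(model$maf_a), hw_probs(model$maf_b))
    sd_pen <- sqrt(sum(pg * (model$pen - K)^2))
    if (sd_pen == 0) {
      trait <- stats::rnorm(n)
    } else {
      z <- (model$pen[cbind(ga + 1, gb + 1)] - K) / sd_pen
      h2 <- heritability(model)
      mu <- sqrt(h2 / (1 - h2))
      trait <- mu * z + stats::rnorm(n)
    }
  }
  mafs <- stats::runif(n_snps - 2, maf_range[1], maf_range[2])
  g <- hw_genotypes(n, mafs)
  causal <- sort(sample.int(n_snps, 2))
  full <- matrix(0L, n, n_snps)
  full[, -causal] <- g
  full[, causal[1]] <- ga
  full[, causal[2]] <- gb
  d <- mbmdr_dataset(full, trait, trait_type)
  if (missing_rate > 0) d <- inject_missing(d, missing_rate)
  attr(d, "causal_pair") <- causal
  attr(d, "model") <- model
  d
}

#' Set genotype calls to missing at random
#'
#' Each genotype independently becomes missing with probability `rate`;
#' the trait is never masked.
#'
#' @param dataset an [mbmdr_dataset()].
#' @param rate missingness probability in \[0, 1).
#' @return The dataset with missing calls injected.
#' @export
inject_missing <- function(dataset, rate) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(dataset)
  g <- dataset$genotypes
  g[stats::runif(length(g)) < rate] <- NA
  dataset$genotypes <- g
  dataset
}
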