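#' Genotype/trait dataset for pairwise interaction scans
#'
#' Bundles a genotype matrix coded 0/1/2 (minor-allele counts, `NA` for
#' missing) with a single trait column.  Binary traits are coded 0/1
#' (controls/cases); continuous traits are real-valued.  This is the unit
#' every scan, permutation backend and simulator in the package consumes.
#'
#' @param genotypes integer matrix, individuals in rows and SNPs in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param trait numeric vector, one value per individual; no missing values.
#' @param trait_type `"binary"`, `"continuous"`, or `"auto"` (binary iff the
#'   trait takes values in \{0, 1\}).
#' @param snp_ids character vector of SNP labels; defaults to the column
#'   names of `genotypes` or `SNP1...SNPs`.
#'
#' @return An object of class `mbmdr_dataset`: a list with elements
#'   `genotypes`, `trait`, `trait_type` and `snp_ids`.
#' @examples
#' g <- matrix(sample(0:2, 60, replace = TRUE), nrow = 20)
#' d <- mbmdr_dataset(g, rbinom(20, 1, 0.5))
#' d
#' @export
mbmdr_dataset <- function(genotypes, trait,
                          trait_type = c("auto", "binary", "continuous"),
                          snp_ids = NULL) {
  trait_type <- match.arg(trait_type)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  trait <- as.numeric(trait)
  if (nrow(genotypes) != length(trait))
    stop("trait length (", length(trait), ") does not match genotype rows (",
         nrow(genotypes), ")")
  if (anyNA(trait))
    stop("missing trait values are not supported")
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA; first offender at row ",
         which(bad, arr.ind = TRUE)[1, 1])
  if (trait_type == "auto")
    trait_type <- if (all(trait %in% c(0, 1))) "binary" else "continuous"
  if (trait_type == "binary" && !all(trait %in% c(0, 1)))
    stop("binary trait must contain only 0 and 1")
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("SNP", seq_len(ncol(genotypes)))
  if (length(snp_ids) != ncol(genotypes))
    stop("snp_ids length does not match number of SNPs")
  colnames(genotypes) <- snp_ids
  structure(list(genotypes = genotypes, trait = trait,
                 trait_type = trait_type, snp_ids = snp_ids),
            class = "mbmdr_dataset")
}

#' @export
print.mbmdr_dataset <- function(x, ...) {
  cat("MB-MDR dataset:", nrow(x$genotypes), "individuals x",
      ncol(x$genotypes), "SNPs\n")
  cat("  trait:", x$trait_type)
  if (x$trait_type == "binary")
    cat(" (", sum(x$trait == 1), " cases / ", sum(x$trait == 0),
        " controls)", sep = "")
  cat("\n")
  nm <- sum(is.na(x$genotypes))
  cat("  missing genotypes:", nm,
      sprintf("(%.2f%%)\n", 100 * nm / length(x$genotypes)))
  invisible(x)
}

#' Number of unordered SNP pairs in a dataset
#' @param dataset an [mbmdr_dataset()].
#' @return `s * (s - 1) / 2` where `s` is the number of SNPs.
#' @export
n_pairs <- function(dataset) {
  s <- ncol(dataset$genotypes)
  s * (s - 1) / 2
}

#' Read a genotype/trait dataset from a plain-text file
#'
#' The format is whitespace- or tab-separated text: a header row naming the
#' trait column (`trait`) followed by the SNP identifiers, then one row per
#' individual holding the trait value and the genotype codes 0/1/2 (or
#' `missing_code` for missing calls).
#'
#' @param path file to read.
#' @param trait_type passed to [mbmdr_dataset()].
#' @param missing_code genotype sentinel for missing calls (default `-9`).
#' @return An [mbmdr_dataset()].
#' @export
read_dataset <- function(path, trait_type = c("auto", "binary", "continuous"),
                         missing_code = -9) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("no such file: ", path)
  header <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  if (length(header) < 2 || tolower(header[1]) != "trait")
    stop("malformed header in ", path,
         ": expected 'trait' followed by SNP ids")
  snp_ids <- header[-1]
  body <- utils::read.table(path, header = FALSE, skip = 1,
                            colClasses = "numeric")
  if (ncol(body) != length(header))
    stop("malformed line in ", path, ": expected ", length(header),
         " fields, found ", ncol(body))
  trait <- body[[1]]
  g <- as.matrix(body[, -1, drop = FALSE])
  g[g == missing_code] <- NA
  bad <- which(!is.na(g) & !(g %in% 0:2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("unknown genotype code ", g[bad[1, 1], bad[1, 2]], " at row ",
         bad[1, 1] + 1, ", column ", bad[1, 2] + 1, " of ", path)
  dimnames(g) <- NULL
  mbmdr_dataset(g, trait, trait_type, snp_ids = snp_ids)
}

#' Write a dataset to the plain-text format read by [read_dataset()]
#'
#' @param dataset an [mbmdr_dataset()].
#' @param path destination file.
#' @param missing_code value written for missing genotypes.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, missing_code = -9) {
  g <- dataset$genotypes
  g[is.na(g)] <- missing_code
  tab <- cbind(trait = dataset$trait, g)
  colnames(tab) <- c("trait", dataset$snp_ids)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
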