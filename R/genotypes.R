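#' Genotype matrix objects
#'
#' Biallelic SNP dosages for N samples at M loci.  Dosages count copies of
#' the declared alternate allele (0, 1 or 2); missing genotypes are `NA`.
#' The SNP map records chromosome, 1-based base-pair position and the two
#' alleles; columns are kept sorted by (chromosome, position).
#'
#' @param dosage integer matrix, samples in rows (rownames = sample ids).
#' @param map data frame with columns `snp`, `chrom`, `pos`, `allele1`
#'   (reference), `allele2` (counted alternate).  Defaults to a single
#'   pseudo-chromosome with unit spacing.
#' @return An object of class `genotypes`.
#' @export
genotype_matrix <- function(dosage, map = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("id", seq_len(nrow(dosage)))
  if (is.null(map)) {
    map <- data.frame(snp = colnames(dosage) %||% paste0("snp", seq_len(ncol(dosage))),
                      chrom = "1", pos = seq_len(ncol(dosage)),
                      allele1 = "A", allele2 = "B",
                      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(map) == ncol(dosage))
  bad <- !(dosage %in% c(0L, 1L, 2L, NA))
  if (any(bad, na.rm = TRUE)) stop("dosages must be 0, 1, 2 or missing")
  o <- order(map$chrom, map$pos)
  map <- map[o, , drop = FALSE]
  dosage <- dosage[, o, drop = FALSE]
  colnames(dosage) <- map$snp
  rownames(map) <- NULL
  all_missing <- colSums(!is.na(dosage)) == 0L
  if (any(all_missing))
    stop("SNP(s) with all genotypes missing: ",
         paste(map$snp[all_missing], collapse = ", "))
  structure(list(dosage = dosage, map = map, ids = rownames(dosage)),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  cat("Genotypes: ", nrow(x$dosage), " samples x ", ncol(x$dosage),
      " SNPs on ", length(unique(x$map$chrom)), " chromosome(s); ",
      sprintf("%.2f%%", 100 * mean(is.na(x$dosage))), " missing\n", sep = "")
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$dosage)

#' Read SNP genotypes
#'
#' Supports PLINK text `.ped`/`.map` pairs (pass the `.ped` path or the
#' common prefix) and plain dosage CSV (first column sample id, remaining
#' columns one SNP each; `-9` or empty cells are missing).  In `.ped`
#' input, `0` alleles mark missing calls and a half-missing genotype is
#' treated as fully missing; dosages count the alternate allele, defined
#' as the second distinct allele observed per SNP (alphabetically last
#' when only one is observed).
#'
#' @param path file path.
#' @param format `"ped_map"` or `"dosage_csv"`.
#' @return A [genotype_matrix()] object.
#' @export
read_genotypes <- function(path, format = c("ped_map", "dosage_csv")) {
  format <- match.arg(format)
  if (format == "dosage_csv") return(.read_dosage_csv(path))
  prefix <- sub("\\.(ped|map)$", "", path)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map) < 4L) stop("malformed .map: expected 4 columns")
  names(map)[1:4] <- c("chrom", "snp", "cm", "pos")
  m <- nrow(map)
  lines <- strsplit(trimws(readLines(ped_path)), "[ \t]+")
  ncols <- lengths(lines)
  if (length(unique(ncols)) != 1L)
    stop("inconsistent column counts in .ped: rows have ",
         paste(unique(ncols), collapse = ", "), " fields")
  if (unique(ncols) != 6L + 2L * m)
    stop("inconsistent column counts: .ped has ", unique(ncols),
         " fields per row but .map declares ", m, " SNPs (need ",
         6L + 2L * m, ")")
  ped <- do.call(rbind, lines)
  ids <- ped[, 2L]
  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA; a2[half] <- NA
  dosage <- matrix(NA_integer_, nrow(ped), m)
  alt <- character(m); ref <- character(m)
  for (j in seq_len(m)) {
    alleles <- sort(unique(stats::na.omit(c(a1[, j], a2[, j]))))
    if (length(alleles) > 2L)
      stop("non-biallelic SNP ", map$snp[j], ": alleles ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0L)
      stop("SNP(s) with all genotypes missing: ", map$snp[j])
    ref[j] <- alleles[1L]
    alt[j] <- alleles[length(alleles)]
    dosage[, j] <- (a1[, j] == alt[j]) + (a2[, j] == alt[j])
  }
  rownames(dosage) <- ids
  genotype_matrix(dosage,
                  data.frame(snp = map$snp, chrom = as.character(map$chrom),
                             pos = as.integer(map$pos),
                             allele1 = ref, allele2 = alt,
                             stringsAsFactors = FALSE))
}

.read_dosage_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(x[[1L]])
  d <- as.matrix(x[, -1L, drop = FALSE])
  storage.mode(d) <- "integer"
  d[d == -9L] <- NA_integer_
  rownames(d) <- ids
  genotype_matrix(d)
}

#' Write SNP genotypes
#'
#' Round-trips with [read_genotypes()]: dosage CSV uses `-9` for missing;
#' `ped_map` writes a PLINK text pair (alleles from the map, `0 0` for
#' missing).
#'
#' @param geno genotypes object.
#' @param path output path (for `ped_map`, the prefix or `.ped` path).
#' @param format `"dosage_csv"` or `"ped_map"`.
#' @export
write_genotypes <- function(geno, path, format = c("dosage_csv", "ped_map")) {
  format <- match.arg(format)
  stopifnot(inherits(geno, "genotypes"))
  if (format == "dosage_csv") {
    d <- geno$dosage
    d[is.na(d)] <- -9L
    out <- data.frame(id = geno$ids, d, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  prefix <- sub("\\.(ped|map)$", "", path)
  map <- geno$map
  utils::write.table(data.frame(map$chrom, map$snp, 0, map$pos),
                     paste0(prefix, ".map"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  m <- ncol(geno$dosage)
  al <- matrix("0", nrow(geno$dosage), 2L * m)
  for (j in seq_len(m)) {
    g <- geno$dosage[, j]
    a <- c(map$allele1[j], map$allele2[j])
    al[, 2L * j - 1L] <- ifelse(is.na(g), "0", ifelse(g >= 1L, a[2L], a[1L]))
    al[, 2L * j] <- ifelse(is.na(g), "0", ifelse(g == 2L, a[2L], a[1L]))
  }
  out <- cbind(geno$ids, geno$ids, "0", "0", "0", "-9", al)
  utils::write.table(out, paste0(prefix, ".ped"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read/write relationship matrices in GCTA-style text format
#'
#' `write_grm()` writes the lower triangle as whitespace-separated rows
#' `i j n_snps value` to `<path>.grm.txt` (indices 1-based, row-major over
#' `j <= i`, values at 6 decimals) and the sample ids to `<path>.grm.id`.
#' `read_grm()` inverts it.
#'
#' @param K symmetric relationship matrix with sample ids as dimnames
#'   (a [numerator_relationship()] / [realized_relationship()] result or
#'   plain matrix).
#' @param path file prefix.
#' @param n_snps integer count stored in the third column (scalar or
#'   per-entry); purely informational.
#' @return `read_grm()` returns the matrix with ids as dimnames.
#' @export
write_grm <- function(K, path, n_snps = NA_integer_) {
  K <- unclass(K)
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop("relationship matrix must be square")
  if (max(abs(K - t(K))) > 1e-8)
    stop("relationship matrix must be symmetric")
  n <- nrow(K)
  ids <- rownames(K) %||% paste0("id", seq_len(n))
  i <- rep(seq_len(n), seq_len(n))
  j <- sequence(seq_len(n))
  df <- data.frame(i = i, j = j, n = n_snps,
                   v = sprintf("%.6f", K[cbind(i, j)]))
  utils::write.table(df, paste0(path, ".grm.txt"), row.names = FALSE,
                     col.names = FALSE, quote = FALSE, sep = "\t")
  utils::write.table(data.frame(ids, ids), paste0(path, ".grm.id"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE,
                     sep = "\t")
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  tri <- utils::read.table(paste0(path, ".grm.txt"), header = FALSE)
  ids <- utils::read.table(paste0(path, ".grm.id"), header = FALSE,
                           stringsAsFactors = FALSE)[[2L]]
  n <- length(ids)
  K <- matrix(0, n, n, dimnames = list(ids, ids))
  K[cbind(tri[[1L]], tri[[2L]])] <- tri[[4L]]
  K[cbind(tri[[2L]], tri[[1L]])] <- tri[[4L]]
  K
}
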