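#' Phased haplotype matrices
#'
#' The central container: a 2n x m binary allele matrix over phased
#' chromosomes (two rows per subject, 0 = reference, 1 = alternate) together
#' with SNP metadata and the chromosome-to-subject linkage.  Missing or
#' unphased entries are not representable: phasing and imputation are
#' upstream of this tool.
#'
#' @param alleles Integer matrix, 2n x m, entries 0/1.
#' @param subject_ids Character vector of length 2n, the owning subject of
#'   each chromosome row (each id appearing exactly twice).
#' @param snps Data frame with columns `chrom`, `pos` (1-based, strictly
#'   increasing), `id`, `ref`, `alt`, `genotyped` (logical).
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, subject_ids, snps) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (anyNA(alleles) || !all(alleles %in% c(0L, 1L))) {
    stop("allele matrix must contain only 0/1 with no missing entries")
  }
  subject_ids <- as.character(subject_ids)
  if (nrow(alleles) != length(subject_ids)) {
    stop("one subject id is required per chromosome row")
  }
  if (nrow(alleles) %% 2L != 0L ||
      !all(table(subject_ids) == 2L)) {
    stop("each subject must contribute exactly two chromosome rows")
  }
  snps <- as.data.frame(snps)
  need <- c("chrom", "pos", "id", "ref", "alt", "genotyped")
  if (!all(need %in% names(snps))) {
    stop("snps must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(snps) != ncol(alleles)) {
    stop("snps must describe each allele column")
  }
  if (nrow(snps) > 1 && any(diff(snps$pos) <= 0)) {
    stop("SNP positions must be strictly increasing")
  }
  hap_index <- stats::ave(seq_along(subject_ids), subject_ids,
                          FUN = seq_along)
  structure(list(alleles = alleles,
                 subject_ids = subject_ids,
                 chromosome_ids = paste(subject_ids, hap_index, sep = "_"),
                 snps = snps),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat("<haplotype_matrix>", nrow(x$alleles), "chromosomes (",
      nrow(x$alleles) / 2, "subjects ) x", ncol(x$alleles), "SNPs\n")
  invisible(x)
}

#' @rdname haplotype_matrix
#' @param x A `haplotype_matrix`.
#' @export
n_chromosomes <- function(x) nrow(x$alleles)

#' Parse a genomic region string
#'
#' Accepts `"chr11:69,419,318-69,616,860"` (thousands separators optional);
#' coordinates are 1-based and the interval is fully closed.
#'
#' @param region Region string `"chrom:start-end"`.
#' @return List with `chrom`, `start`, `end`.
#' @export
parse_region <- function(region) {
  region <- gsub(",", "", region, fixed = TRUE)
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)[-–]([0-9]+)$", region))[[1]]
  if (length(m) != 4) stop("malformed region string: ", region)
  out <- list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
  if (out$start > out$end) stop("region start exceeds end: ", region)
  out
}

#' Read phased genotypes from a VCF into a haplotype matrix
#'
#' Restricts to biallelic SNPs inside `region` (position order), giving each
#' requested subject exactly two chromosome rows.  Multiallelic sites are
#' excluded with a warning; a missing or unphased genotype is a hard error
#' naming the subject and position, because this tool does not phase or
#' impute.
#'
#' @param path Path to a VCF file (phased GT fields).
#' @param region Optional region string (see [parse_region()]); `NULL` keeps
#'   all sites.
#' @param subjects Optional character vector of sample names to keep (order
#'   preserved); `NULL` keeps all samples.
#' @return A [haplotype_matrix].
#' @export
read_phased_vcf <- function(path, region = NULL, subjects = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt <- vcf@gt[, -1, drop = FALSE]
  if (!nrow(fix)) stop("VCF contains no variant records")
  pos <- as.numeric(fix$POS)
  keep <- rep(TRUE, nrow(fix))
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- fix$CHROM == r$chrom & pos >= r$start & pos <= r$end
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE) | fix$ALT == "*"
  if (any(multi & keep)) {
    warning(sum(multi & keep), " multiallelic site(s) excluded: ",
            paste(fix$ID[multi & keep], collapse = ", "))
  }
  keep <- keep & !multi
  if (!any(keep)) stop("no biallelic SNPs in the requested region")
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]
  gt <- gt[keep, , drop = FALSE]
  if (is.null(subjects)) subjects <- colnames(gt)
  missing_subj <- setdiff(subjects, colnames(gt))
  if (length(missing_subj)) {
    stop("subjects absent from VCF: ", paste(missing_subj, collapse = ", "))
  }
  gt <- gt[, subjects, drop = FALSE]
  # genotype calls may carry trailing fields (GT:DS:...) -- keep field 1
  calls <- sub(":.*$", "", gt)
  dim(calls) <- dim(gt)
  bad <- !grepl("^[01]\\|[01]$", calls)
  dim(bad) <- dim(calls)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("missing or unphased genotype '", calls[bad][1], "' for subject ",
         subjects[w[2]], " at ", fix$CHROM[w[1]], ":", pos[w[1]])
  }
  a1 <- matrix(as.integer(substr(calls, 1, 1)), nrow(calls), ncol(calls))
  a2 <- matrix(as.integer(substr(calls, 3, 3)), nrow(calls), ncol(calls))
  o <- order(pos)
  if (anyDuplicated(pos)) stop("duplicate SNP positions in region")
  alleles <- matrix(0L, 2L * length(subjects), nrow(fix))
  alleles[seq(1, by = 2, length.out = length(subjects)), ] <- t(a1[o, , drop = FALSE])
  alleles[seq(2, by = 2, length.out = length(subjects)), ] <- t(a2[o, , drop = FALSE])
  haplotype_matrix(
    alleles,
    rep(subjects, each = 2),
    data.frame(chrom = fix$CHROM[o], pos = pos[o], id = fix$ID[o],
               ref = fix$REF[o], alt = fix$ALT[o],
               genotyped = TRUE, stringsAsFactors = FALSE))
}

#' Symmetric reduction of a region to a SNP cap
#'
#' When a region holds more than `max_snps` typed SNPs, SNPs are removed
#' alternately from the two ends (leftmost end first when an odd number must
#' go) until exactly `max_snps` remain, preserving the center of the region.
#'
#' @param matrix A [haplotype_matrix].
#' @param max_snps Positive integer cap.
#' @return A [haplotype_matrix] with at most `max_snps` columns.
#' @export
reduce_region_symmetric <- function(matrix, max_snps) {
  stopifnot(max_snps >= 1)
  m <- ncol(matrix$alleles)
  if (m <= max_snps) return(matrix)
  excess <- m - max_snps
  drop_left <- ceiling(excess / 2)
  drop_right <- floor(excess / 2)
  keep <- (drop_left + 1L):(m - drop_right)
  haplotype_matrix(matrix$alleles[, keep, drop = FALSE],
                   matrix$subject_ids,
                   matrix$snps[keep, , drop = FALSE])
}

#' Unique full-width haplotypes and their multiplicities
#'
#' Collapses the chromosome rows to the distinct contiguous haplotypes over
#' all m SNPs; these are the iteration-0 seeds of a mining run.
#'
#' @param matrix A [haplotype_matrix].
#' @return Data frame with `haplotype` (0/1 string, lexicographic order),
#'   `count`, and `first_row` (first chromosome row carrying it);
#'   counts sum to the chromosome total.
#' @export
unique_haplotypes <- function(matrix) {
  if (!nrow(matrix$alleles)) stop("empty haplotype matrix")
  keys <- do.call(paste0, as.data.frame(matrix$alleles))
  first <- !duplicated(keys)
  tab <- table(keys)
  out <- data.frame(haplotype = names(tab),
                    count = as.integer(tab),
                    first_row = which(first)[match(names(tab), keys[first])],
                    stringsAsFactors = FALSE)
  out[order(out$haplotype), , drop = FALSE]
}

#' Subject phenotype tables
#'
#' One row per subject: case status, age (onset for cases, end of follow-up
#' for controls) and a fixed-length numeric covariate vector (typically
#' genotype principal components).
#'
#' @param subject_id Character vector of unique subject ids.
#' @param case_status Logical vector.
#' @param age Positive numeric ages in years.
#' @param covariates Numeric matrix or data frame (may have zero columns).
#' @return Data frame of class `subject_table` with covariate columns
#'   `cov1`, `cov2`, ...
#' @export
subject_table <- function(subject_id, case_status, age, covariates = NULL) {
  subject_id <- as.character(subject_id)
  if (anyDuplicated(subject_id)) stop("duplicate subject ids")
  if (any(age <= 0) || anyNA(age)) stop("ages must be positive")
  case_status <- as.logical(case_status)
  if (anyNA(case_status)) stop("case status must be TRUE/FALSE")
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), length(subject_id), 0)
  }
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != length(subject_id)) {
    stop("covariates must have one row per subject")
  }
  if (anyNA(covariates)) stop("covariates must be complete")
  out <- data.frame(subject_id = subject_id, case_status = case_status,
                    age = as.numeric(age), stringsAsFactors = FALSE)
  if (ncol(covariates)) {
    colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    out <- cbind(out, as.data.frame(covariates))
  }
  class(out) <- c("subject_table", "data.frame")
  out
}

#' @rdname subject_table
#' @param x A `subject_table`.
#' @export
covariate_columns <- function(x) grep("^cov[0-9]+$", names(x), value = TRUE)

#' Read a phenotype TSV
#'
#' Expects columns `subject_id`, `case_status` (0/1 or TRUE/FALSE), `age`,
#' and any further numeric columns as covariates (e.g. PC1..PC10).
#'
#' @param path Path to a tab-separated phenotype file with header.
#' @return A [subject_table()].
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "case_status", "age")
  if (!all(need %in% names(df))) {
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  }
  covs <- df[, setdiff(names(df), need), drop = FALSE]
  subject_table(df$subject_id, as.logical(as.integer(df$case_status) != 0 |
                                          df$case_status == TRUE),
                df$age, if (ncol(covs)) as.matrix(covs) else NULL)
}

#' Write / read the tab-separated haplotype matrix dialect
#'
#' Plain-text intermediate format: a header row of SNP ids, then one row per
#' chromosome with the chromosome id in column 1 and 0/1 alleles after it.
#' SNP metadata travels in `#`-prefixed header lines so a round trip is
#' bit-exact.
#'
#' @param matrix A [haplotype_matrix].
#' @param path Output path.
#' @export
write_haplotype_tsv <- function(matrix, path) {
  con <- file(path, "w")
  on.exit(close(con))
  s <- matrix$snps
  meta <- paste0("#snp\t", s$chrom, "\t", s$pos, "\t", s$id, "\t", s$ref,
                 "\t", s$alt, "\t", as.integer(s$genotyped))
  writeLines(meta, con)
  writeLines(paste(c("chromosome_id", s$id), collapse = "\t"), con)
  body <- apply(matrix$alleles, 1, paste, collapse = "\t")
  writeLines(paste(matrix$chromosome_ids, body, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_haplotype_tsv
#' @param path Path of a file written by [write_haplotype_tsv()].
#' @export
read_haplotype_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#snp\t")]
  body <- lines[!startsWith(lines, "#")]
  sm <- do.call(rbind, strsplit(meta, "\t", fixed = TRUE))
  snps <- data.frame(chrom = sm[, 2], pos = as.numeric(sm[, 3]),
                     id = sm[, 4], ref = sm[, 5], alt = sm[, 6],
                     genotyped = sm[, 7] == "1", stringsAsFactors = FALSE)
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  ids <- vapply(rows, `[`, character(1), 1)
  alle <- t(vapply(rows, function(r) as.integer(r[-1]),
                   integer(nrow(snps))))
  # chromosome ids are subject ids suffixed with the haplotype index
  haplotype_matrix(alle, sub("_[12]$", "", ids), snps)
}
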