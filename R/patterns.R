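#' Haplotype patterns
#'
#' A pattern is an ordered set of (SNP index, allele) pairs on a common SNP
#' index space: the alleles a chromosome must carry, at the listed columns, to
#' "contain" the pattern.  Patterns are the unit mined by the overlap engine;
#' a full-width pattern is an ordinary contiguous haplotype, while patterns
#' touching a subset of columns are noncontiguous haplotypes.  SNP indices are
#' 0-based and strictly increasing, giving every pattern a unique canonical
#' form so equality and hashing are well defined.
#'
#' @param snp Integer vector of 0-based SNP (column) indices.
#' @param allele Integer vector of alleles (0 = reference, 1 = alternate).
#' @return An object of class `hap_pattern`.
#' @examples
#' p <- hap_pattern(c(0, 3), c(0, 1))
#' pattern_length(p)
#' @export
hap_pattern <- function(snp = integer(), allele = integer()) {
  snp <- as.integer(snp)
  allele <- as.integer(allele)
  if (length(snp) != length(allele)) {
    stop("snp and allele must have equal length")
  }
  if (length(snp)) {
    if (anyNA(snp) || anyNA(allele)) stop("pattern entries must be non-missing")
    if (any(snp < 0)) stop("SNP indices are 0-based and must be >= 0")
    if (!all(allele %in% c(0L, 1L))) stop("alleles must be 0 or 1")
    o <- order(snp)
    snp <- snp[o]
    allele <- allele[o]
    if (anyDuplicated(snp)) stop("duplicate SNP index in pattern")
  }
  structure(list(snp = snp, allele = allele), class = "hap_pattern")
}

#' @export
print.hap_pattern <- function(x, ...) {
  if (!length(x$snp)) {
    cat("<empty pattern>\n")
  } else {
    cat("<pattern of", length(x$snp), "alleles>", pattern_key(x), "\n")
  }
  invisible(x)
}

#' @rdname hap_pattern
#' @param x,a,b Patterns.
#' @export
pattern_length <- function(x) length(x$snp)

#' Canonical string key of a pattern
#'
#' "snp:allele" pairs joined by commas; the empty pattern maps to "".  Used
#' as the deduplication key throughout the mining engine.
#' @param x A `hap_pattern`.
#' @export
pattern_key <- function(x) {
  if (!length(x$snp)) return("")
  paste(x$snp, x$allele, sep = ":", collapse = ",")
}

#' @rdname pattern_key
#' @param key A key produced by [pattern_key()].
#' @export
pattern_from_key <- function(key) {
  if (identical(key, "")) return(hap_pattern())
  parts <- strsplit(strsplit(key, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  hap_pattern(vapply(parts, function(p) as.integer(p[1]), integer(1)),
              vapply(parts, function(p) as.integer(p[2]), integer(1)))
}

#' Dense representation of a pattern
#'
#' Length-`m` integer vector with the pattern's allele at its SNP columns and
#' `NA` elsewhere; the representation used internally by the overlap engine.
#'
#' @param x A `hap_pattern`.
#' @param m Number of SNP columns in the index space.
#' @export
pattern_to_dense <- function(x, m) {
  if (length(x$snp) && max(x$snp) >= m) {
    stop("pattern touches SNP index ", max(x$snp), " but m = ", m)
  }
  v <- rep(NA_integer_, m)
  v[x$snp + 1L] <- x$allele
  v
}

#' @rdname pattern_to_dense
#' @param v Dense integer vector (0/1/NA).
#' @export
dense_to_pattern <- function(v) {
  k <- which(!is.na(v))
  hap_pattern(k - 1L, v[k])
}

#' Overlap (intersection) of two patterns
#'
#' Keeps the (SNP, allele) pairs present in both patterns: the longest
#' pattern shared by every chromosome containing either input.  Commutative,
#' associative and idempotent; the result may be empty.
#'
#' @param a,b Patterns on the same SNP index space.
#' @return A `hap_pattern` (possibly empty).
#' @examples
#' a <- hap_pattern(0:3, c(0, 1, 0, 1))
#' b <- hap_pattern(0:3, c(0, 1, 1, 1))
#' pattern_overlap(a, b)  # keeps columns 0, 1, 3
#' @export
pattern_overlap <- function(a, b) {
  i <- match(a$snp, b$snp)
  keep <- !is.na(i) & a$allele == b$allele[i]
  hap_pattern(a$snp[keep], a$allele[keep])
}

#' Union of two compatible patterns
#'
#' Adjoins the entries of two patterns (e.g. a discovered haplotype and an
#' extra SNP-allele); errors if they disagree at a shared column.
#'
#' @inheritParams pattern_overlap
#' @export
pattern_union <- function(a, b) {
  i <- match(a$snp, b$snp)
  hit <- !is.na(i)
  if (any(a$allele[hit] != b$allele[i][hit])) {
    bad <- a$snp[hit][a$allele[hit] != b$allele[i][hit]]
    stop("allele conflict at SNP index ", paste(bad, collapse = ", "))
  }
  keep_b <- !(b$snp %in% a$snp)
  hap_pattern(c(a$snp, b$snp[keep_b]), c(a$allele, b$allele[keep_b]))
}

#' Does a chromosome (or every row of a matrix) contain a pattern?
#'
#' @param rows Either a single 0/1 allele vector of length `m` or a matrix of
#'   chromosome rows.
#' @param h A `hap_pattern`.
#' @return Logical scalar or one logical per row.  Every chromosome contains
#'   the empty pattern.
#' @export
pattern_contains <- function(rows, h) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  if (!length(h$snp)) return(rep(TRUE, nrow(rows)))
  if (max(h$snp) + 1L > ncol(rows)) {
    stop("pattern touches SNP index beyond the matrix width")
  }
  sub <- rows[, h$snp + 1L, drop = FALSE]
  rowSums(sub != rep(h$allele, each = nrow(sub))) == 0
}

#' Carrier rows of a pattern in a haplotype matrix
#'
#' @param h A `hap_pattern`.
#' @param matrix A [haplotype_matrix].
#' @return Logical vector over chromosome rows.
#' @export
pattern_carriers <- function(h, matrix) {
  pattern_contains(matrix$alleles, h)
}

#' Closure of a pattern
#'
#' The intersection of all chromosomes containing `h`: the shortest closed
#' pattern containing `h`.  Has exactly the same carriers as `h` and is a
#' fixed point of itself.
#'
#' @inheritParams pattern_carriers
#' @return A `hap_pattern` superset of `h`.
#' @export
pattern_closure <- function(h, matrix) {
  carr <- pattern_carriers(h, matrix)
  if (!any(carr)) stop("no chromosome contains the pattern; closure undefined")
  sub <- matrix$alleles[carr, , drop = FALSE]
  same <- colSums(sub != rep(sub[1, ], each = nrow(sub))) == 0
  hap_pattern(which(same) - 1L, sub[1, same])
}

#' Case/control support of a pattern
#'
#' Counts carrier chromosomes split by case status and tallies each subject's
#' copy number (0, 1 or 2): chromosomes are the units of the exact tests,
#' subject copy numbers the dosage modelled in regressions.
#'
#' @inheritParams pattern_carriers
#' @param subjects A subject table (see [subject_table()]).
#' @return List with `case_chrom`, `control_chrom` (carrier chromosome
#'   counts) and `copies`, a named integer vector of per-subject copy counts
#'   in `subjects$subject_id` order.
#' @export
pattern_support <- function(h, matrix, subjects) {
  carr <- pattern_carriers(h, matrix)
  copies <- tapply(carr, matrix$subject_ids, sum)
  copies <- as.integer(copies[as.character(subjects$subject_id)])
  if (anyNA(copies)) stop("subjects missing from the haplotype matrix")
  names(copies) <- subjects$subject_id
  is_case <- subjects$case_status[match(matrix$subject_ids,
                                        subjects$subject_id)]
  list(case_chrom = sum(carr & is_case),
       control_chrom = sum(carr & !is_case),
       copies = copies)
}

# Bulk containment: logical matrix (patterns x rows) via two BLAS products.
.contains_bulk <- function(P, X) {
  P1 <- (!is.na(P) & P == 1L) + 0
  P0 <- (!is.na(P) & P == 0L) + 0
  (tcrossprod(P1, X) == rowSums(P1)) & (tcrossprod(P0, 1 - X) == rowSums(P0))
}

# Bulk carrier counting for many dense patterns at once.
#
# P: k x m integer matrix of dense patterns (NA = column unused).
# X: u x m matrix of *unique* chromosome rows; w: list of weight vectors
# (e.g. case and control multiplicities per unique row).  Uses two BLAS
# products: a row carries a pattern iff it matches all allele-1 columns and
# all allele-0 columns.  Returns a matrix with one row per pattern and one
# weighted carrier-count column per weight vector.
.pattern_support_bulk <- function(P, X, w, chunk = NULL) {
  stopifnot(is.matrix(P), is.matrix(X), ncol(P) == ncol(X))
  if (is.null(chunk)) chunk <- max(512L, floor(2e7 / nrow(X)))
  W <- vapply(w, as.numeric, numeric(nrow(X)))
  out <- matrix(0, nrow(P), length(w))
  for (s in seq(1L, nrow(P), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(P))
    Pc <- P[s:e, , drop = FALSE]
    P1 <- (!is.na(Pc) & Pc == 1L) + 0
    P0 <- (!is.na(Pc) & Pc == 0L) + 0
    n1 <- rowSums(P1)
    n0 <- rowSums(P0)
    M1 <- tcrossprod(P1, X)        # matches at allele-1 columns
    M0 <- tcrossprod(P0, 1 - X)    # matches at allele-0 columns
    carries <- (M1 == n1) & (M0 == n0)   # patterns x unique rows
    out[s:e, ] <- (carries + 0) %*% W
  }
  colnames(out) <- names(w)
  out
}
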