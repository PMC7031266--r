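#' Binned contact matrices
#'
#' A `contact_matrix` wraps a tibble of non-zero pixels
#' (`chrom1`, `bin1`, `chrom2`, `bin2`, `count`) together with its
#' [binned_genome()], a balancing flag, the set of masked bins and the raw
#' library total. Pixels are stored once in canonical upper-triangular order
#' (chrom1 before or equal to chrom2 in genome order; `bin1 <= bin2` on the
#' same chromosome); the matrix is symmetric by construction.
#'
#' @param pixels Pixel tibble.
#' @param genome A [binned_genome()].
#' @param balanced Logical flag.
#' @param bin_mask Tibble (`chrom`, `bin`) of masked bins.
#' @param library_total Raw input pair count.
#' @return An object of class `contact_matrix`.
#' @keywords internal
new_contact_matrix <- function(pixels, genome, balanced = FALSE,
                               bin_mask = NULL, library_total = sum(pixels$count)) {
  if (is.null(bin_mask)) {
    bin_mask <- tibble::tibble(chrom = character(), bin = integer())
  }
  pixels <- canonical_pixels(pixels, genome)
  structure(
    list(pixels = pixels, genome = genome, balanced = balanced,
         bin_mask = bin_mask, library_total = library_total),
    class = "contact_matrix"
  )
}

canonical_pixels <- function(pixels, genome) {
  g1 <- global_bin(genome, pixels$chrom1, pixels$bin1)
  g2 <- global_bin(genome, pixels$chrom2, pixels$bin2)
  flip <- g1 > g2
  if (any(flip)) {
    tmp_c <- pixels$chrom1[flip]; tmp_b <- pixels$bin1[flip]
    pixels$chrom1[flip] <- pixels$chrom2[flip]
    pixels$bin1[flip] <- pixels$bin2[flip]
    pixels$chrom2[flip] <- tmp_c
    pixels$bin2[flip] <- tmp_b
    tmp <- g1[flip]; g1[flip] <- g2[flip]; g2[flip] <- tmp
  }
  pixels <- pixels[order(g1, g2), , drop = FALSE]
  key <- paste(pixels$chrom1, pixels$bin1, pixels$chrom2, pixels$bin2)
  if (anyDuplicated(key) > 0) {
    pixels <- dplyr::summarise(
      dplyr::group_by(pixels, .data$chrom1, .data$bin1, .data$chrom2, .data$bin2),
      count = sum(.data$count), .groups = "drop"
    )
    go1 <- global_bin(genome, pixels$chrom1, pixels$bin1)
    go2 <- global_bin(genome, pixels$chrom2, pixels$bin2)
    pixels <- pixels[order(go1, go2), , drop = FALSE]
  }
  tibble::as_tibble(pixels[pixels$count != 0, , drop = FALSE])
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", nrow(x$pixels), " pixels, bin size ",
      format(x$genome$bin_size, big.mark = ","), " bp, ",
      if (x$balanced) "balanced" else "raw",
      ", library total ", format(x$library_total, big.mark = ","),
      ", ", nrow(x$bin_mask), " masked bins\n", sep = "")
  print(x$pixels, n = 5)
  invisible(x)
}

#' Build a contact matrix from valid pairs
#'
#' Bins a valid-pair table (one ligation di-tag per row) onto a binned
#' genome. The matrix total (diagonal counted once) equals the number of
#' input pairs — counts are conserved before any filtering.
#'
#' @param valid_pairs Data frame with columns `chrom1`, `pos1`, `chrom2`,
#'   `pos2` (0-based positions).
#' @param genome A [binned_genome()].
#' @return A raw `contact_matrix`.
#' @export
build_matrix <- function(valid_pairs, genome) {
  stopifnot(all(c("chrom1", "pos1", "chrom2", "pos2") %in% names(valid_pairs)))
  b1 <- bin_of(genome, valid_pairs$chrom1, valid_pairs$pos1)
  b2 <- bin_of(genome, valid_pairs$chrom2, valid_pairs$pos2)
  px <- tibble::tibble(chrom1 = as.character(valid_pairs$chrom1), bin1 = b1,
                       chrom2 = as.character(valid_pairs$chrom2), bin2 = b2,
                       count = 1)
  new_contact_matrix(px, genome, library_total = nrow(valid_pairs))
}

#' Sum replicate contact matrices
#'
#' Elementwise sum of raw matrices on an identical binned genome, mirroring
#' the merge-replicates-then-analyse flow; library totals add.
#'
#' @param matrices A list of `contact_matrix` objects.
#' @return The summed `contact_matrix`.
#' @export
merge_replicates <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  g <- matrices[[1]]$genome
  for (m in matrices) {
    if (!identical(m$genome$bin_size, g$bin_size) ||
        !identical(m$genome$chrom_sizes$chrom, g$chrom_sizes$chrom) ||
        !identical(m$genome$chrom_sizes$length, g$chrom_sizes$length)) {
      stop("matrices must share an identical binned genome", call. = FALSE)
    }
    if (m$balanced) stop("merge raw matrices before balancing", call. = FALSE)
  }
  px <- dplyr::bind_rows(lapply(matrices, function(m) m$pixels))
  new_contact_matrix(px, g,
                     library_total = sum(vapply(matrices, function(m) m$library_total, 0)))
}

#' Read and write valid-pair tables
#'
#' Four-column TSV `chrom1 pos1 chrom2 pos2` without header; extra columns
#' (replicate, condition) are preserved when present in a headered file.
#'
#' @param path File path.
#' @return Tibble of pairs.
#' @export
read_pairs <- function(path) {
  first <- readr::read_lines(path, n_max = 1, progress = FALSE)
  if (grepl("^chrom1\t", first)) {
    readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  } else {
    readr::read_tsv(path, col_names = c("chrom1", "pos1", "chrom2", "pos2"),
                    col_types = "cdcd", progress = FALSE)
  }
}

#' @rdname read_pairs
#' @param pairs Pair tibble.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read and write contact matrices as bin-pair triplets
#'
#' Headered TSV `chrom1 start1 chrom2 start2 count`; counts are written with
#' full double precision (`%.17g`) so a write/read cycle is bit-exact.
#'
#' @param path File path.
#' @param genome A [binned_genome()] (needed to rebuild bin indices).
#' @return A `contact_matrix`.
#' @export
read_matrix <- function(path, genome) {
  x <- readr::read_tsv(path, col_types = "cdcdc", progress = FALSE)
  stopifnot(all(c("chrom1", "start1", "chrom2", "start2", "count") %in% names(x)))
  px <- tibble::tibble(
    chrom1 = x$chrom1, bin1 = as.integer(x$start1 / genome$bin_size),
    chrom2 = x$chrom2, bin2 = as.integer(x$start2 / genome$bin_size),
    count = as.numeric(x$count)
  )
  new_contact_matrix(px, genome)
}

#' @rdname read_matrix
#' @param matrix A `contact_matrix`.
#' @export
write_matrix <- function(matrix, path) {
  px <- matrix$pixels
  lines <- paste(px$chrom1,
                 format(bin_start(matrix$genome, px$bin1), scientific = FALSE, trim = TRUE),
                 px$chrom2,
                 format(bin_start(matrix$genome, px$bin2), scientific = FALSE, trim = TRUE),
                 sprintf("%.17g", px$count), sep = "\t")
  readr::write_lines(c("chrom1\tstart1\tchrom2\tstart2\tcount", lines), path)
  invisible(path)
}

#' Matrix total with the diagonal counted once
#' @param matrix A `contact_matrix`.
#' @return Numeric scalar.
#' @export
matrix_total <- function(matrix) sum(matrix$pixels$count)

#' Dense cis sub-matrix for one chromosome
#'
#' @param matrix A `contact_matrix`.
#' @param chrom Chromosome name.
#' @return A symmetric dense base matrix (`n_bins x n_bins`).
#' @export
cis_dense <- function(matrix, chrom) {
  g <- matrix$genome
  n <- g$chrom_sizes$n_bins[match(chrom, g$chrom_sizes$chrom)]
  if (is.na(n)) stop("unknown chromosome: ", chrom, call. = FALSE)
  px <- matrix$pixels
  sel <- px$chrom1 == chrom & px$chrom2 == chrom
  m <- base::matrix(0, n, n)
  i <- px$bin1[sel] + 1L; j <- px$bin2[sel] + 1L
  m[cbind(i, j)] <- px$count[sel]
  m[cbind(j, i)] <- px$count[sel]
  m
}

masked_bins_of <- function(matrix, chrom) {
  matrix$bin_mask$bin[matrix$bin_mask$chrom == chrom]
}

#' Per-bin genome-wide coverage
#'
#' Row sums of the full symmetric matrix (diagonal counted once per row).
#'
#' @param matrix A `contact_matrix`.
#' @return Tibble (`chrom`, `bin`, `coverage`) covering every bin.
#' @export
bin_coverage <- function(matrix) {
  g <- matrix$genome
  cov <- numeric(g$n_bins)
  px <- matrix$pixels
  g1 <- global_bin(g, px$chrom1, px$bin1) + 1
  g2 <- global_bin(g, px$chrom2, px$bin2) + 1
  add1 <- tapply(px$count, g1, sum)
  cov[as.integer(names(add1))] <- cov[as.integer(names(add1))] + add1
  off <- g1 != g2
  if (any(off)) {
    add2 <- tapply(px$count[off], g2[off], sum)
    cov[as.integer(names(add2))] <- cov[as.integer(names(add2))] + add2
  }
  cs <- g$chrom_sizes
  tibble::tibble(
    chrom = rep(cs$chrom, cs$n_bins),
    bin = unlist(lapply(cs$n_bins, function(n) seq_len(n) - 1L), use.names = FALSE),
    coverage = cov
  )
}
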