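#' Define a binned genome
#'
#' A binned genome couples a chromosome-size table with a fixed bin size and
#' fixes the bin indexing convention used throughout the package: position
#' `p` (0-based) falls in bin `floor(p / bin_size)`, bins tile each
#' chromosome exactly, and the last bin may be short.
#'
#' @param chrom_sizes A data frame with columns `chrom` and `length` (bp), or
#'   a named numeric vector of chromosome lengths.
#' @param bin_size Bin width in bp. The analyses here use 10 kb for contact
#'   matrices and loops, and 50 kb for compartments.
#'
#' @return An object of class `binned_genome`: a list with `chrom_sizes`
#'   (tibble `chrom`, `length`, `n_bins`, `bin_offset`), `bin_size`, and
#'   `n_bins` (total genome-wide bin count). `bin_offset` is the cumulative
#'   number of bins on preceding chromosomes, so `bin_offset + local_bin`
#'   is a genome-wide bin id.
#' @export
#' @examples
#' bg <- binned_genome(c(chr1 = 2e7, chr2 = 2e7), bin_size = 1e4)
#' bg$n_bins
binned_genome <- function(chrom_sizes, bin_size) {
  if (is.numeric(chrom_sizes) && !is.null(names(chrom_sizes))) {
    chrom_sizes <- tibble::tibble(chrom = names(chrom_sizes),
                                  length = unname(chrom_sizes))
  }
  stopifnot(is.data.frame(chrom_sizes),
            all(c("chrom", "length") %in% names(chrom_sizes)))
  if (anyDuplicated(chrom_sizes$chrom) > 0) {
    stop("duplicated chromosome names in `chrom_sizes`", call. = FALSE)
  }
  if (any(chrom_sizes$length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop("`bin_size` must be a single positive number", call. = FALSE)
  }
  cs <- tibble::tibble(
    chrom = as.character(chrom_sizes$chrom),
    length = as.numeric(chrom_sizes$length),
    n_bins = ceiling(as.numeric(chrom_sizes$length) / bin_size)
  )
  cs$bin_offset <- cumsum(c(0, cs$n_bins[-nrow(cs)]))
  structure(
    list(chrom_sizes = cs, bin_size = bin_size, n_bins = sum(cs$n_bins)),
    class = "binned_genome"
  )
}

#' @export
print.binned_genome <- function(x, ...) {
  cat("<binned_genome> ", nrow(x$chrom_sizes), " chromosome(s), bin size ",
      format(x$bin_size, big.mark = ","), " bp, ", x$n_bins, " bins\n",
      sep = "")
  print(x$chrom_sizes)
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom_sizes$chrom)
  if (anyNA(i)) {
    stop("unknown chromosome(s): ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  genome$chrom_sizes$length[i]
}

#' Map positions to bins and back
#'
#' `bin_of()` returns the 0-based bin index of 0-based positions;
#' `bin_start()` returns the bp start of a bin. Both are the elementary
#' binning convention used by every matrix-level operation.
#'
#' @param genome A [binned_genome()].
#' @param chrom,pos Character chromosome names and 0-based positions.
#' @param bin 0-based bin index within its chromosome.
#' @return Integer bin indices (`bin_of`) or bp starts (`bin_start`).
#' @export
bin_of <- function(genome, chrom, pos) {
  len <- chrom_length(genome, chrom)
  if (any(pos < 0 | pos >= len)) {
    stop("position outside chromosome bounds", call. = FALSE)
  }
  as.integer(floor(pos / genome$bin_size))
}

#' @rdname bin_of
#' @export
bin_start <- function(genome, bin) as.numeric(bin) * genome$bin_size

global_bin <- function(genome, chrom, bin) {
  i <- match(chrom, genome$chrom_sizes$chrom)
  genome$chrom_sizes$bin_offset[i] + as.numeric(bin)
}

#' Read a chromosome-sizes table
#'
#' Two-column headerless TSV (`chrom`, `length`).
#'
#' @param path File path.
#' @return Tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "cd", progress = FALSE)
  tibble::as_tibble(x)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes Tibble as returned by `read_chrom_sizes()`.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  readr::write_tsv(chrom_sizes[, c("chrom", "length")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}
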