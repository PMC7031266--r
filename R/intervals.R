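#' Validate a genomic-interval table
#'
#' Intervals are plain tibbles with columns `chrom`, `start`, `end` and
#' optionally `name`, `strand`. Coordinates are 0-based half-open
#' (`start` inclusive, `end` exclusive) everywhere in this package; BED is
#' therefore the native on-disk dialect.
#'
#' @param x A data frame of intervals.
#' @param chrom_sizes Optional chromosome-size table (`chrom`, `length`) or a
#'   [binned_genome()]; when given, chromosome names are checked and
#'   intervals must lie within bounds.
#' @param what Label used in error messages.
#' @return `x` as a tibble, invisibly validated.
#' @export
validate_intervals <- function(x, chrom_sizes = NULL, what = "interval set") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x))) {
    stop(what, " must be a data frame with columns chrom, start, end",
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad) > 0) {
    stop(what, ": invalid interval at row ", bad[1],
         " (need 0 <= start < end; got start=", x$start[bad[1]],
         ", end=", x$end[bad[1]], ")", call. = FALSE)
  }
  if (!is.null(chrom_sizes)) {
    if (inherits(chrom_sizes, "binned_genome")) {
      chrom_sizes <- chrom_sizes$chrom_sizes
    }
    i <- match(x$chrom, chrom_sizes$chrom)
    if (anyNA(i)) {
      stop(what, ": unknown chromosome '", x$chrom[which(is.na(i))[1]],
           "' at row ", which(is.na(i))[1], call. = FALSE)
    }
    over <- which(x$end > chrom_sizes$length[i])
    if (length(over) > 0) {
      stop(what, ": interval beyond chromosome end at row ", over[1],
           call. = FALSE)
    }
  }
  x
}

#' Read genomic intervals from BED or headered TSV
#'
#' BED input is parsed as BED3+ (columns beyond the sixth are ignored; the
#' fourth and sixth become `name` and `strand` when present). `tsv` input
#' must carry a header with at least `chrom`, `start`, `end`. Coordinates
#' are kept 0-based half-open. Malformed lines are reported with their line
#' number; unknown chromosomes are errors, never silent drops.
#'
#' @param path File path.
#' @param format `"bed"` or `"tsv"`.
#' @param chrom_sizes Optional chromosome table or [binned_genome()] to
#'   validate against.
#' @return A tibble of intervals in file order.
#' @export
read_intervals <- function(path, format = c("bed", "tsv"), chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    if (!all(c("chrom", "start", "end") %in% names(x))) {
      stop("TSV interval file must have columns chrom, start, end: ", path,
           call. = FALSE)
    }
  } else {
    lines <- readr::read_lines(path, progress = FALSE)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    idx <- which(keep)
    if (length(idx) == 0) {
      return(tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric()))
    }
    fields <- strsplit(lines[idx], "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 3)) {
      stop("malformed BED line ", idx[which(nf < 3)[1]], " in ", path,
           ": fewer than 3 fields", call. = FALSE)
    }
    start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    bad <- which(is.na(start) | is.na(end))
    if (length(bad) > 0) {
      stop("malformed BED line ", idx[bad[1]], " in ", path,
           ": non-numeric coordinates", call. = FALSE)
    }
    x <- tibble::tibble(chrom = vapply(fields, `[`, "", 1L),
                        start = start, end = end)
    if (all(nf >= 4)) x$name <- vapply(fields, `[`, "", 4L)
    if (all(nf >= 6)) x$strand <- vapply(fields, `[`, "", 6L)
  }
  validate_intervals(x, chrom_sizes, what = path)
}

#' Write intervals as BED
#'
#' Writes BED3 (or BED6 when `name`/`strand` are present; missing names are
#' filled with `.` and scores with 0). Round-trips losslessly through
#' [read_intervals()].
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @export
write_intervals <- function(x, path) {
  x <- validate_intervals(x)
  cols <- list(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
               format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$name) || !is.null(x$strand)) {
    nm <- if (is.null(x$name)) rep(".", nrow(x)) else x$name
    strand <- if (is.null(x$strand)) rep(".", nrow(x)) else x$strand
    cols <- c(cols, list(nm, rep("0", nrow(x)), strand))
  }
  readr::write_lines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' All sufficiently overlapping interval pairs between two sets
#'
#' Returns every pair `(a_index, b_index)` whose overlap is at least
#' `max(1, min_overlap_fraction * width(a))` bp. The fraction is taken
#' relative to the *query* (first) set's interval length — the convention
#' behind "at least 10% overlap" control-region comparisons. Output is
#' ordered by `a_index`, then `b_index`.
#'
#' @param set_a,set_b Interval tibbles (`chrom`, `start`, `end`).
#' @param min_overlap_fraction Required overlap as a fraction of the query
#'   interval's length, in `[0, 1]`. Zero means any overlap (>= 1 bp).
#' @return Tibble with columns `a_index`, `b_index`, `overlap_bp`.
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' b <- tibble::tibble(chrom = "chr1", start = 50, end = 150)
#' overlap_query(a, b, 0.1)
overlap_query <- function(set_a, set_b, min_overlap_fraction = 0) {
  set_a <- validate_intervals(set_a, what = "set_a")
  set_b <- validate_intervals(set_b, what = "set_b")
  stopifnot(min_overlap_fraction >= 0, min_overlap_fraction <= 1)
  if (nrow(set_a) == 0 || nrow(set_b) == 0) {
    return(tibble::tibble(a_index = integer(), b_index = integer(),
                          overlap_bp = numeric()))
  }
  # IRanges is 1-based closed: [start+1, end]
  ir_a <- IRanges::IRanges(start = set_a$start + 1, end = set_a$end)
  ir_b <- IRanges::IRanges(start = set_b$start + 1, end = set_b$end)
  hits <- IRanges::findOverlaps(ir_a, ir_b)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same_chrom <- set_a$chrom[qi] == set_b$chrom[si]
  qi <- qi[same_chrom]; si <- si[same_chrom]
  ov <- pmin(set_a$end[qi], set_b$end[si]) - pmax(set_a$start[qi], set_b$start[si])
  need <- pmax(1, min_overlap_fraction * (set_a$end[qi] - set_a$start[qi]))
  keep <- ov >= need
  out <- tibble::tibble(a_index = qi[keep], b_index = si[keep],
                        overlap_bp = ov[keep])
  out[order(out$a_index, out$b_index), ]
}

#' Does each query interval overlap the reference set?
#'
#' Convenience wrapper over [overlap_query()] returning one logical per
#' query interval (>= 1 bp overlap by default).
#'
#' @inheritParams overlap_query
#' @param query,reference Interval tibbles.
#' @return Logical vector of length `nrow(query)`.
#' @export
overlaps_any <- function(query, reference, min_overlap_fraction = 0) {
  hits <- overlap_query(query, reference, min_overlap_fraction)
  seq_len(nrow(query)) %in% hits$a_index
}

#' Promoter windows around TSSs
#'
#' One strand-symmetric window `[tss - flank, tss + flank)` per gene,
#' clipped at chromosome ends. The +/-2 kb default is the promoter
#' definition used when intersecting interactions with promoters.
#'
#' @param expression A data frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based bp); `strand` is ignored (the flank is symmetric).
#' @param chrom_sizes Chromosome-size table or [binned_genome()] used for
#'   clipping and validation.
#' @param flank_bp Half-width of the window in bp.
#' @return Interval tibble with columns `chrom`, `start`, `end`, `name`
#'   (the gene id).
#' @export
promoter_regions <- function(expression, chrom_sizes, flank_bp = 2000) {
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(expression)))
  if (inherits(chrom_sizes, "binned_genome")) {
    chrom_sizes <- chrom_sizes$chrom_sizes
  }
  i <- match(expression$chrom, chrom_sizes$chrom)
  if (anyNA(i)) {
    stop("unknown chromosome in expression table: ",
         expression$chrom[which(is.na(i))[1]], call. = FALSE)
  }
  len <- chrom_sizes$length[i]
  if (any(expression$tss < 0 | expression$tss >= len)) {
    stop("TSS outside chromosome bounds", call. = FALSE)
  }
  tibble::tibble(
    chrom = expression$chrom,
    start = pmax(0, expression$tss - flank_bp),
    end = pmin(len, expression$tss + flank_bp),
    name = expression$gene_id
  )
}
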