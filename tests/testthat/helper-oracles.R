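# Independent oracles used across tests. These deliberately use the most
# naive possible algorithms so they cannot share a bug with the package.

# quadratic all-pairs overlap scan
oracle_overlap <- function(a, b, frac = 0) {
  rows <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= max(1, frac * (a$end[i] - a$start[i]))) {
        rows[[length(rows) + 1]] <- data.frame(a_index = i, b_index = j,
                                               overlap_bp = ov)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(a_index = integer(), b_index = integer(),
                      overlap_bp = numeric())
  }
  out[order(out$a_index, out$b_index), , drop = FALSE]
}

# exhaustive two-sided Mann-Whitney by direct enumeration of assignments
oracle_mw <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# textbook BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- prev
  }
  adj
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                             max_len = 500) {
  start <- floor(stats::runif(n, 0, max_pos - max_len))
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + ceiling(stats::runif(n, 1, max_len)))
}

tiny_genome <- function(len = c(chr1 = 1e5, chr2 = 8e4), bin = 1e4) {
  binned_genome(len, bin)
}

# match loop/boundary calls to truth within a bin tolerance
match_rate <- function(called, truth, tol = 1) {
  if (length(truth) == 0) return(NA_real_)
  mean(vapply(truth, function(p) any(abs(called - p) <= tol), logical(1)))
}
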