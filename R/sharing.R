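#' Tenth-of-chromosome index of a shared proportion
#'
#' Discretizes a positive shared proportion onto the tenths grid: the index
#' is the smallest integer `t` with `total <= t/10`, i.e. `t = 1` covers
#' `0 < x <= 0.1`, `t = 2` covers `0.1 < x <= 0.2`, ..., `t = 10` covers
#' `0.9 < x <= 1`.  Boundary ties use exact floating-point comparison (a
#' measure-zero convention, fixed for bit-reproducibility).
#'
#' @param total Shared length as a proportion of the chromosome, in `(0, 1]`.
#' @return Integer index in `1:10`.
#' @examples
#' tenth_index(c(0.1, 0.1000001, 1))  # 1 2 10
#' @export
tenth_index <- function(total) {
  if (any(!is.finite(total)) || any(total <= 0) || any(total > 1))
    stop("total must lie in (0, 1]")
  t <- as.integer(ceiling(total * 10))
  t <- t - as.integer(total <= (t - 1) / 10)
  t <- t + as.integer(total > t / 10)
  t
}

#' Reduce a segment list to the per-chromosome sharing observable
#'
#' Computes the discrete observable used by the likelihood machinery from a
#' list of maximal shared segments on one chromosome: the segment count
#' `n_s`, the number of chromosome ends covered `p_s` (a segment touches an
#' end iff its endpoint equals 0 or `l` exactly), the total shared length as
#' a proportion of `l`, and its tenth index `t_s` ([tenth_index()]; 0 when
#' nothing is shared).
#'
#' @param segments Two-column matrix or data frame of segment `start`/`end`
#'   positions in Morgans; must be disjoint, sorted and within `[0, l]`.
#'   A zero-row matrix (or `NULL`) means no sharing.
#' @param l Chromosome map length in Morgans.
#' @return A list of class `"sharing_summary"` with elements `n_s`, `p_s`,
#'   `t_s`, `total`.
#' @examples
#' summarize_sharing(rbind(c(0.1256, 0.3659), c(0.5701, 0.9012)), 1)
#' @export
summarize_sharing <- function(segments, l) {
  if (!is.finite(l) || l <= 0) stop("map length must be > 0")
  if (is.null(segments)) segments <- matrix(numeric(), 0, 2)
  segments <- as.matrix(segments)
  if (nrow(segments) && ncol(segments) != 2L)
    stop("segments must have two columns (start, end)")
  if (nrow(segments)) {
    s <- segments[, 1]; e <- segments[, 2]
    if (any(!is.finite(s)) || any(!is.finite(e))) stop("non-finite segment endpoint")
    if (any(s < 0) || any(e > l)) stop("segment outside [0, l]")
    if (any(e <= s)) stop("segments must have positive length")
    if (nrow(segments) > 1L && any(s[-1L] < e[-nrow(segments)]))
      stop("segments must be disjoint and sorted")
  }
  n_s <- nrow(segments)
  if (n_s == 0L) {
    out <- list(n_s = 0L, p_s = 0L, t_s = 0L, total = 0)
  } else {
    p_s <- as.integer(segments[1, 1] == 0) + as.integer(segments[n_s, 2] == l)
    total <- sum(segments[, 2] - segments[, 1]) / l
    out <- list(n_s = n_s, p_s = p_s, t_s = tenth_index(min(total, 1)),
                total = total)
  }
  class(out) <- "sharing_summary"
  out
}

#' @export
print.sharing_summary <- function(x, ...) {
  cat(sprintf("sharing: n_s=%d p_s=%d t_s=%d total=%.4f\n",
              x$n_s, x$p_s, x$t_s, x$total))
  invisible(x)
}

#' Write replicate-level sharing summaries to a tab-separated file
#'
#' One row per replicate with columns `relationship`, `chrom_length` (cM),
#' `n_s`, `p_s`, `t_s`, `total`; header lines are prefixed with `#`.
#'
#' @param x Data frame as returned by [simulate_sharing()].
#' @param path Output file path.
#' @param l Chromosome map length in Morgans (recorded in the table).
#' @param seed Optional seed to record in the header.
#' @export
write_sharing <- function(x, path, l, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# segshare replicate summaries",
    sprintf("# version: %s", as.character(packageVersion("segshare"))),
    sprintf("# seed: %s", format(seed)),
    sprintf("# N: %d", nrow(x))), con)
  df <- data.frame(relationship = x$relationship, chrom_length = l * 100,
                   n_s = x$n_s, p_s = x$p_s, t_s = x$t_s, total = x$total)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
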