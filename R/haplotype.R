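#' Founder-labeled haplotype mosaics
#'
#' A haplotype represents one chromosome copy as an ordered mosaic of
#' intervals, each labeled by the founder haplotype it descends from.
#' Breakpoints are real-valued positions in Morgans, strictly increasing and
#' strictly inside `(0, length)`; there is one label per interval, so
#' `length(labels) == length(breakpoints) + 1`.
#'
#' @param length Chromosome map length in Morgans (> 0).
#' @param breakpoints Numeric vector of internal breakpoint positions
#'   (possibly empty).
#' @param labels Integer founder labels, one per interval.
#' @param simplify Merge adjacent intervals with equal labels (default TRUE).
#' @return An object of class `"haplotype"`.
#' @examples
#' h <- haplotype(1, c(0.1256, 0.5701, 0.9012), c(1, 2, 1, 3))
#' haplotype_label(h, 0.7)  # 1
#' @export
haplotype <- function(length, breakpoints = numeric(), labels = 1L,
                      simplify = TRUE) {
  breakpoints <- as.numeric(breakpoints)
  labels <- as.integer(labels)
  if (!is.finite(length) || length <= 0) stop("chromosome length must be > 0")
  if (base::length(labels) != base::length(breakpoints) + 1L)
    stop("need one label per interval: length(labels) == length(breakpoints) + 1")
  if (base::length(breakpoints)) {
    if (any(diff(breakpoints) <= 0)) stop("breakpoints must be strictly increasing")
    if (breakpoints[1] <= 0 || breakpoints[base::length(breakpoints)] >= length)
      stop("breakpoints must lie strictly inside (0, length)")
  }
  h <- structure(list(length = length, breakpoints = breakpoints,
                      labels = labels), class = "haplotype")
  if (simplify) simplify_haplotype(h) else h
}

#' @export
print.haplotype <- function(x, ...) {
  cat("Haplotype on (0,", format(x$length), ") M: ",
      length(x$labels), " interval(s)\n", sep = "")
  bounds <- c(0, x$breakpoints, x$length)
  for (i in seq_along(x$labels))
    cat(sprintf("  (%g, %g] -> %d\n", bounds[i], bounds[i + 1], x$labels[i]))
  invisible(x)
}

#' Merge adjacent intervals carrying the same founder label
#'
#' Idempotent; the label at every interior position is preserved.
#'
#' @param hap A [haplotype()] object.
#' @return A simplified haplotype.
#' @export
simplify_haplotype <- function(hap) {
  stopifnot(inherits(hap, "haplotype"))
  lab <- hap$labels
  if (length(lab) > 1L) {
    keep <- c(TRUE, lab[-1L] != lab[-length(lab)])
    hap$labels <- lab[keep]
    hap$breakpoints <- hap$breakpoints[keep[-1L]]
  }
  hap
}

#' Founder label at a position
#'
#' @param hap A [haplotype()] object.
#' @param pos Position(s) in `(0, length)`, Morgans.  Intervals are treated
#'   as `(b[i-1], b[i]]`; querying exactly at a breakpoint returns the label
#'   to its left (a measure-zero convention).
#' @return Integer label(s).
#' @export
haplotype_label <- function(hap, pos) {
  stopifnot(inherits(hap, "haplotype"))
  idx <- vapply(pos, function(p) sum(hap$breakpoints < p), 0L) + 1L
  hap$labels[idx]
}

#' Sample crossover positions for one meiosis
#'
#' The number of crossovers is Poisson with mean equal to the map length
#' (Haldane model, no interference); positions are i.i.d. uniform on
#' `(0, l)`, returned sorted.  Coincident positions are resolved by
#' resampling.  Draws come from R's global RNG, so `set.seed()` makes the
#' result reproducible.
#'
#' @param l Chromosome map length in Morgans (> 0).
#' @return Sorted numeric vector of crossover positions (possibly empty).
#' @export
sample_crossovers <- function(l) {
  if (!is.finite(l) || l <= 0) stop("map length must be > 0")
  cpp_sample_crossovers(l)
}

#' Form a gamete from two parental haplotypes
#'
#' One meiosis: crossovers are sampled via [sample_crossovers()], the
#' starting parental haplotype is chosen with probability 1/2 each, and the
#' source alternates at every crossover.  The output is simplified.  For
#' testing, crossover positions and phase can be injected.
#'
#' @param hapA,hapB Parental [haplotype()]s of equal length.
#' @param crossovers Optional numeric vector of crossover positions; if
#'   `NULL` (default) they are sampled.
#' @param start Optional phase: `"A"` or `"B"` to force the starting
#'   haplotype, `NULL` (default) to sample it.
#' @return A [haplotype()] of the same length.
#' @export
form_gamete <- function(hapA, hapB, crossovers = NULL, start = NULL) {
  stopifnot(inherits(hapA, "haplotype"), inherits(hapB, "haplotype"))
  if (hapA$length != hapB$length)
    stop("parental haplotypes must have the same chromosome length")
  st <- if (is.null(start)) -1L else match(match.arg(start, c("A", "B")), c("A", "B")) - 1L
  g <- cpp_gamete(unclass(hapA), unclass(hapB), hapA$length, crossovers, st)
  haplotype(hapA$length, g$breakpoints, g$labels, simplify = FALSE)
}

#' Maximal IBD-shared segments between two individuals
#'
#' Returns the maximal intervals on which some haplotype of `a` and some
#' haplotype of `b` carry the same founder label.  Maximality is positional:
#' adjacent regions shared through different founder haplotypes of the same
#' ancestor merge into a single segment.
#'
#' @param a,b Individual genomes: a single [haplotype()] or a list of one or
#'   two haplotypes (a diploid endpoint), all of one chromosome length.
#' @return Two-column matrix (`start`, `end`) of disjoint sorted segment
#'   endpoints in Morgans; zero rows when nothing is shared.
#' @examples
#' a <- haplotype(1, c(0.1256, 0.5701, 0.9012), c(1, 2, 1, 3))
#' b <- haplotype(1, 0.3659, c(2, 1))
#' shared_segments(a, b)  # (0.1256, 0.3659) and (0.5701, 0.9012)
#' @export
shared_segments <- function(a, b) {
  a <- as_genome_haps(a)
  b <- as_genome_haps(b)
  la <- a[[1]]$length
  if (any(vapply(c(a, b), function(h) h$length, 0) != la))
    stop("all haplotypes must share one chromosome length")
  out <- cpp_shared_segments(lapply(a, unclass), lapply(b, unclass), la)
  segs <- out$segments
  colnames(segs) <- c("start", "end")
  segs
}

as_genome_haps <- function(x) {
  if (inherits(x, "haplotype")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "haplotype"))) return(x)
  stop("expected a haplotype or a list of haplotypes")
}
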