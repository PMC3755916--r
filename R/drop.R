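#' Gene-drop a relative pair on one chromosome
#'
#' Simulates the tracked genomes of a relative pair by dropping labeled
#' founder haplotypes through the pedigree: a full-sib founder couple (four
#' founder haplotypes) for full-sib-based relationships, or a single diploid
#' common ancestor for half-sib-based and lineal ones.  Each collateral
#' individual is tracked through the single haplotype descending from the
#' shared ancestry (unrelated in-marrying mates contribute fresh unique
#' labels, so spurious sharing is impossible); the uncle in UN/GUGN and the
#' ancestor in lineal pairs are diploid endpoints retaining both haplotypes.
#'
#' @param rel A relationship abbreviation or [relationship()] spec.
#' @param l Chromosome map length in Morgans.
#' @return List with elements `a` and `b`, each a list of one or two
#'   [haplotype()]s, plus attribute `"rel"`.
#' @seealso [shared_segments()], [simulate_sharing()]
#' @export
drop_pair <- function(rel, l) {
  rel <- relationship(rel)
  if (!is.finite(l) || l <= 0) stop("map length must be > 0")
  idx <- .chain_index(rel)
  fs <- rel$base == "full-sib"

  single <- function(label) haplotype(l, labels = label)
  if (fs) {
    F1 <- single(1L); F2 <- single(2L); M1 <- single(3L); M2 <- single(4L)
    sib1 <- list(form_gamete(F1, F2), form_gamete(M1, M2))
    sib2 <- list(form_gamete(F1, F2), form_gamete(M1, M2))
    fresh <- 5L
  } else {
    anc <- list(single(1L), single(2L))
    fresh <- 3L
  }
  chain <- function(top, depth) {
    if (depth == 0L) return(NULL)
    h <- form_gamete(top[[1]], top[[2]])
    if (depth > 1L) for (k in 2:depth) {
      h <- form_gamete(h, single(fresh))
      fresh <<- fresh + 1L
    }
    h
  }
  top1 <- if (fs) sib1 else anc
  top2 <- if (fs) sib2 else anc
  c1 <- chain(top1, idx[1])
  c2 <- chain(top2, idx[2])
  a <- if (idx[1] == 0L) top1 else list(c1)
  b <- if (idx[2] == 0L) top2 else list(c2)
  structure(list(a = a, b = b), rel = rel$abbrev)
}

#' Monte-Carlo replicates of per-chromosome sharing summaries
#'
#' Runs `n` independent gene-dropping replicates for one or more
#' relationships on a chromosome of length `l` and reduces each replicate to
#' its sharing summary (`n_s`, `p_s`, `t_s`, `total`).  Relationships with
#' the same family base are scored on one pedigree instance per replicate
#' (as independent replicates are numerous, the induced within-replicate
#' correlation across relationships is immaterial); different bases use
#' independent draws.
#'
#' @param rels Character vector of catalog abbreviations, or a list of
#'   [relationship()] specs (all bases allowed; grouped internally).
#' @param l Chromosome map length in Morgans.
#' @param n Number of replicates.
#' @return Data frame with columns `relationship`, `rep`, `n_s`, `p_s`,
#'   `t_s`, `total` (`total` is a proportion of `l`).
#' @examples
#' set.seed(1)
#' x <- simulate_sharing("HS", 1.632, 1000)
#' mean(x$total)  # close to 2R = 0.5
#' @export
simulate_sharing <- function(rels, l, n) {
  if (!is.finite(l) || l <= 0) stop("map length must be > 0")
  n <- as.integer(n)
  stopifnot(n >= 1L)
  specs <- if (is.list(rels) && !is.data.frame(rels))
    lapply(rels, relationship) else lapply(rels, relationship)
  bases <- vapply(specs, function(s) s$base, "")
  groups <- split(seq_along(specs),
                  factor(ifelse(bases == "full-sib", "full-sib", "single"),
                         levels = c("full-sib", "single")))
  out <- vector("list", length(specs))
  for (g in groups) {
    if (!length(g)) next
    base_code <- .base_code(specs[[g[1]]]$base)
    pairs <- t(vapply(specs[g], .chain_index, integer(2)))
    res <- cpp_simulate_base(base_code, l, n, pairs)
    for (j in seq_along(g)) {
      r <- res[[j]]
      ts <- integer(n)
      pos <- r$n_s > 0L
      ts[pos] <- tenth_index(r$total[pos])
      out[[g[j]]] <- data.frame(
        relationship = specs[[g[j]]]$abbrev, rep = seq_len(n),
        n_s = r$n_s, p_s = r$p_s, t_s = ts, total = r$total)
    }
  }
  do.call(rbind, out)
}
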