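# Outcome keys and empirical multinomial distributions.
#
# A per-chromosome outcome is the triple (n_s, p_s, t_s) with the collapse
# rule: n_s = 0 carries no position/length information; for 1 <= n_s <= 4
# all three components are kept; for n_s > 4 the length tenth t_s is
# dropped (cells would otherwise be too sparse at feasible replicate
# numbers).  Keys are packed into one integer:
#   code = n_s + 100*(p_s+1) + 10000*(t_s+1), with 0 encoding "absent".

key_code <- function(n_s, p_s = NA, t_s = NA) {
  n_s <- as.integer(n_s)
  pp <- ifelse(n_s == 0L | is.na(p_s), 0L, as.integer(p_s) + 1L)
  tt <- ifelse(n_s == 0L | n_s > 4L | is.na(t_s), 0L, as.integer(t_s) + 1L)
  n_s + 100L * pp + 10000L * tt
}

key_decode <- function(code) {
  n_s <- code %% 100L
  pp <- (code %/% 100L) %% 100L
  tt <- code %/% 10000L
  data.frame(n_s = n_s,
             p_s = ifelse(pp == 0L, NA_integer_, pp - 1L),
             t_s = ifelse(tt == 0L, NA_integer_, tt - 1L))
}

# drop components of already-coded keys; levels of information are nested
marginalize_code <- function(code, use) {
  switch(use,
         nspsts = code,
         nsps = code %% 10000L,
         ns = code %% 100L,
         stop("use must be one of 'ns', 'nsps', 'nspsts'"))
}

#' Empirical outcome distribution for one relationship and chromosome length
#'
#' Tallies replicate-level sharing summaries into the multinomial outcome
#' distribution P(k) over collapsed outcome classes, or wraps a ready-made
#' count table (e.g. a published count distribution over `n_s` only).
#'
#' @param x Either a data frame of replicates with columns `n_s`, `p_s`,
#'   `t_s` (as from [simulate_sharing()]), or a count table with columns
#'   `n_s`, optionally `p_s` and `t_s`, and `count`.
#' @param l Chromosome map length in Morgans.
#' @param rel Relationship label (informational).
#' @return Object of class `"ibd_distribution"`: list with `rel`, `l`, `N`,
#'   `use` (the information level present: `"ns"`, `"nsps"` or `"nspsts"`)
#'   and `counts` (data frame `code`, `count`).
#' @export
empirical_distribution <- function(x, l, rel = "?") {
  stopifnot(is.data.frame(x))
  if ("count" %in% names(x)) {
    use <- if ("t_s" %in% names(x)) "nspsts" else if ("p_s" %in% names(x)) "nsps" else "ns"
    code <- key_code(x$n_s,
                     if ("p_s" %in% names(x)) x$p_s else NA,
                     if ("t_s" %in% names(x)) x$t_s else NA)
    cnt <- tapply(as.integer(x$count), code, sum)
  } else {
    use <- "nspsts"
    code <- key_code(x$n_s, x$p_s, x$t_s)
    cnt <- table(code)
  }
  counts <- data.frame(code = as.integer(names(cnt)),
                       count = as.integer(cnt))
  counts <- counts[counts$count > 0L, , drop = FALSE]
  counts <- counts[order(counts$code), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(rel = rel, l = l, N = sum(counts$count), use = use,
                 counts = counts),
            class = "ibd_distribution")
}

#' @export
print.ibd_distribution <- function(x, ...) {
  cat(sprintf("Empirical sharing distribution: %s on %g M (%d replicates, %s, %d classes)\n",
              x$rel, x$l, x$N, x$use, nrow(x$counts)))
  invisible(x)
}

# counts of a distribution at an information level (<= its native level)
dist_counts <- function(dist, use) {
  lv <- c(ns = 1L, nsps = 2L, nspsts = 3L)
  if (lv[[use]] > lv[[dist$use]])
    stop("distribution holds only '", dist$use, "' information; cannot use '",
         use, "'")
  code <- marginalize_code(dist$counts$code, use)
  cnt <- tapply(dist$counts$count, code, sum)
  data.frame(code = as.integer(names(cnt)), count = as.integer(cnt))
}

# probabilities keyed by code
dist_probs <- function(dist, use = dist$use) {
  d <- dist_counts(dist, use)
  d$prob <- d$count / dist$N
  d
}
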