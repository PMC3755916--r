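# Report tables over a fitted distribution bank, mirroring the layouts used
# for segment-count distributions, KL-distance/SD matrices and the
# Poisson-approximation comparison.

#' Summary tables over a fitted distribution bank
#'
#' @param fit An [ibd_fit()].
#' @param which Table type:
#'   \describe{
#'     \item{`"counts"`}{Replicate counts of `n_s` values (rows) per
#'       relationship (columns) at one chromosome length `l`.}
#'     \item{`"moments"`}{Square matrices of E(lambda) and SD(lambda) over
#'       `rels` (rows = true, columns = hypothesized).}
#'     \item{`"ratios"`}{Square matrix of E(lambda)/SD(lambda).}
#'     \item{`"poisson"`}{Long table comparing simulated vs
#'       Poisson-approximate E and E/SD from segment numbers only.}
#'     \item{`"misclassification"`}{Pairwise normal-approximation
#'       misclassification probabilities.}
#'   }
#' @param rels Relationships to include (default: all in the fit).
#' @param l Chromosome length for `"counts"` (default: first length class).
#' @inheritParams lr_moments
#' @return A data frame (`"counts"`, `"poisson"`, `"misclassification"`) or
#'   a list of matrices (`"moments"`), or a matrix (`"ratios"`).
#' @export
lr_table <- function(fit, which = c("counts", "moments", "ratios", "poisson",
                                    "misclassification"),
                     rels = fit$relationships, l = NULL,
                     use = c("nspsts", "nsps", "ns")) {
  which <- match.arg(which)
  use <- match.arg(use)
  if (which == "counts") {
    if (is.null(l)) l <- fit$genome$specs$length_M[1]
    cols <- lapply(rels, function(r) {
      d <- dist_probs(get_dist(fit, r, l), "ns")
      setNames(d$count, d$code)
    })
    nmax <- max(vapply(cols, function(cc) max(as.integer(names(cc))), 0L))
    out <- data.frame(n_s = 0:nmax)
    for (i in seq_along(rels))
      out[[rels[i]]] <- as.integer(cols[[i]][as.character(0:nmax)])
    out[is.na(out)] <- 0L
    return(out)
  }
  if (which %in% c("moments", "ratios")) {
    E <- SD <- matrix(NA_real_, length(rels), length(rels),
                      dimnames = list(true = rels, hyp = rels))
    for (a in rels) for (b in rels) {
      m <- lr_moments(fit, a, b, use)
      E[a, b] <- m$mean
      SD[a, b] <- m$sd
    }
    if (which == "moments") return(list(E = E, SD = SD))
    R <- E / SD
    diag(R) <- NA_real_
    return(R)
  }
  if (which == "poisson") {
    rows <- list()
    for (a in rels) for (b in rels) {
      if (a == b) next
      sim <- lr_moments(fit, a, b, "ns")
      poi <- poisson_lr_moments(fit, a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        true = a, hyp = b, E_sim = sim$mean, EoverSD_sim = sim$ratio,
        E_poisson = poi$mean, EoverSD_poisson = poi$ratio)
    }
    return(do.call(rbind, rows))
  }
  # misclassification
  rows <- list()
  for (i in seq_along(rels)) for (j in seq_along(rels)) {
    if (i >= j) next
    a <- rels[i]; b <- rels[j]
    mis <- misclassification_prob(lr_moments(fit, a, b, use),
                                  lr_moments(fit, b, a, use))
    rows[[length(rows) + 1L]] <- data.frame(
      relA = a, relB = b,
      P_misassign_truth_A = mis[["truth_A"]],
      P_misassign_truth_B = mis[["truth_B"]])
  }
  do.call(rbind, rows)
}

#' Write a report table with a commented header
#'
#' Tab-separated output with `#`-prefixed header lines recording the seed,
#' replicate count, genome model and package version, so any table can be
#' regenerated byte-for-byte from the same configuration.
#'
#' @param x Data frame or matrix.
#' @param path Output path.
#' @param fit The [ibd_fit()] the table came from (for header metadata).
#' @param title Short description line.
#' @export
write_report_table <- function(x, path, fit = NULL, title = "segshare table") {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- paste("#", title)
  if (!is.null(fit)) {
    hdr <- c(hdr,
             sprintf("# genome: %s", fit$genome$name),
             sprintf("# N: %d", fit$N),
             sprintf("# seed: %s", if (is.null(fit$seed)) "NA" else format(fit$seed)),
             sprintf("# version: %s", fit$version))
  }
  writeLines(hdr, con)
  if (is.matrix(x)) x <- data.frame(true = rownames(x), x, check.names = FALSE)
  write.table(format(x, digits = 6), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write one bank file per relationship and chromosome length
#'
#' Splits an [ibd_fit()] into per-(relationship, length) bank files named
#' `bank_<rel>_<length-cM>.tsv` under `dir`, each in the [write_bank()]
#' format.  [read_bank()] on the directory reassembles the fit.
#'
#' @param fit An [ibd_fit()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_bank_dir <- function(fit, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (cls in fit$bank) {
    for (d in cls$dists) {
      sub <- fit
      sub$relationships <- d$rel
      sub$bank <- setNames(list(list(l = cls$l, dists = setNames(list(d), d$rel))),
                           len_key(cls$l))
      write_bank(sub, file.path(dir, sprintf("bank_%s_%s.tsv",
                                             d$rel, len_key(cls$l))))
    }
  }
  invisible(dir)
}
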