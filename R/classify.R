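#' Read an observed shared-segment file
#'
#' Tab-separated with columns `chrom`, `start_cM`, `end_cM` (`#`-prefixed
#' header lines ignored).  Coordinates are centimorgans, 0-based, half-open
#' `[start, end)`; whether a segment touches the upper chromosome end is
#' judged against the configured chromosome length.
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `start_cM`, `end_cM`.
#' @export
read_segments <- function(path) {
  x <- read.delim(path, comment.char = "#")
  need <- c("chrom", "start_cM", "end_cM")
  if (!all(need %in% names(x)))
    stop("segment file needs columns: ", paste(need, collapse = ", "))
  x[, need]
}

#' Classify an observed pair between two candidate relationships
#'
#' Converts the observed shared segments of a single pair of individuals
#' into per-chromosome outcomes, scores the genome-wide log-likelihood
#' ratio lambda(A:B) against the fitted distribution bank, and reports the
#' sign decision together with both normal-approximation misclassification
#' probabilities.
#'
#' Chromosomes are identified by the integer ids of
#' [chromosome_table()] for the fit's genome model; every chromosome of the
#' model contributes an outcome (no segments on a chromosome is itself
#' informative: `n_s = 0`).  A segment endpoint within `1e-9` cM of 0 or of
#' the chromosome length is treated as touching that end (cM coordinates in
#' files carry decimal rounding; simulation-internal arithmetic is exact).
#'
#' @param fit An [ibd_fit()] containing both relationships.
#' @param segments Data frame as from [read_segments()], or a file path.
#' @param relA,relB The two candidate relationships (A first).
#' @inheritParams lr_moments
#' @return Object of class `"pair_classification"`: list with the
#'   per-chromosome `profile`, `lambda` (nats), `decision`,
#'   `misclassification` (both directions) and the two moment objects.
#' @export
classify_pair <- function(fit, segments, relA, relB,
                          use = c("nspsts", "nsps", "ns")) {
  use <- match.arg(use)
  if (is.character(segments)) segments <- read_segments(segments)
  chroms <- chromosome_table(fit$genome)
  bad <- setdiff(unique(segments$chrom), chroms$chrom)
  if (length(bad))
    stop("unknown chromosome id(s): ", paste(bad, collapse = ", "))
  eps <- 1e-9
  prof <- vector("list", nrow(chroms))
  for (i in seq_len(nrow(chroms))) {
    l_cM <- chroms$length_M[i] * 100
    seg <- segments[segments$chrom == chroms$chrom[i], , drop = FALSE]
    if (nrow(seg)) {
      seg <- seg[order(seg$start_cM), , drop = FALSE]
      s <- seg$start_cM
      e <- seg$end_cM
      if (any(s < -eps) || any(e > l_cM + eps))
        stop("segment outside chromosome ", chroms$chrom[i],
             " bounds [0, ", l_cM, "] cM")
      s[abs(s) <= eps] <- 0
      e[abs(e - l_cM) <= eps] <- l_cM
      sm <- summarize_sharing(cbind(s, e), l_cM)
    } else {
      sm <- summarize_sharing(NULL, l_cM)
    }
    prof[[i]] <- data.frame(chrom = chroms$chrom[i],
                            length_M = chroms$length_M[i],
                            n_s = sm$n_s, p_s = sm$p_s, t_s = sm$t_s,
                            total = sm$total)
  }
  prof <- do.call(rbind, prof)
  lam <- genome_loglr(prof, fit, relA, relB, use)
  if (relA == relB) {
    decision <- "indistinguishable"
    mis <- c(truth_A = NA_real_, truth_B = NA_real_)
    mAB <- mBA <- NULL
  } else {
    decision <- if (lam > 0) relA else if (lam < 0) relB else "indistinguishable"
    mAB <- lr_moments(fit, relA, relB, use)
    mBA <- lr_moments(fit, relB, relA, use)
    mis <- misclassification_prob(mAB, mBA)
  }
  structure(list(relA = relA, relB = relB, use = use, profile = prof,
                 lambda = as.numeric(lam),
                 n_uninformative = attr(lam, "n_uninformative"),
                 decision = decision, misclassification = mis,
                 momentsAB = mAB, momentsBA = mBA),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("Pair classification: %s vs %s (%s)\n", x$relA, x$relB, x$use))
  cat(sprintf("  lambda(%s : %s) = %.3f nats -> decision: %s\n",
              x$relA, x$relB, x$lambda, x$decision))
  if (!is.null(x$n_uninformative) && x$n_uninformative > 0)
    cat("  uninformative chromosomes (outcome unseen in bank):",
        x$n_uninformative, "\n")
  if (!all(is.na(x$misclassification)))
    cat(sprintf("  misclassification: %.4f if truth is %s, %.4f if truth is %s\n",
                x$misclassification[["truth_A"]], x$relA,
                x$misclassification[["truth_B"]], x$relB))
  cat("  per-chromosome outcomes:\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' @export
predict.ibd_fit <- function(object, segments, relA, relB,
                            use = c("nspsts", "nsps", "ns"), ...) {
  classify_pair(object, segments, relA, relB, use)
}
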