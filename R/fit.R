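len_key <- function(l) sprintf("%.6g", l * 100)

#' Fit empirical IBD-sharing distributions over a genome model
#'
#' The central estimator: runs Monte-Carlo gene-dropping for each requested
#' relationship at every chromosome length class of a genome model and
#' tallies the per-chromosome outcome distributions P(n_s, p_s, t_s) used by
#' the likelihood machinery.  The result (a "distribution bank") feeds
#' [lr_moments()], [genome_loglr()], [assignment_experiment()],
#' [lr_sample()], [poisson_lr_moments()] and [classify_pair()].
#'
#' @param genome A [genome_model()] object or the name of a built-in model.
#' @param relationships Character vector of catalog abbreviations (default:
#'   all 19).
#' @param nrep Replicates per relationship and chromosome length.
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called
#'   first and recorded, making the fit (and files written from it)
#'   reproducible.
#' @return Object of class `"ibd_fit"`.
#' @examples
#' \donttest{
#' fit <- ibd_fit("equal22", c("UN", "HS"), nrep = 20000, seed = 1)
#' lr_moments(fit, "UN", "HS")
#' }
#' @export
ibd_fit <- function(genome, relationships = segshare::relationships()$abbrev,
                    nrep = 1e5, seed = NULL) {
  if (is.character(genome)) genome <- genome_model(genome)
  stopifnot(inherits(genome, "genome_model"))
  nrep <- as.integer(nrep)
  stopifnot(nrep >= 1L)
  if (!is.null(seed)) set.seed(seed)
  bank <- list()
  for (i in seq_len(nrow(genome$specs))) {
    l <- genome$specs$length_M[i]
    key <- len_key(l)
    if (!is.null(bank[[key]])) next
    sim <- simulate_sharing(relationships, l, nrep)
    dists <- lapply(split(sim, sim$relationship)[unique(sim$relationship)],
                    function(d) empirical_distribution(d[, c("n_s", "p_s", "t_s")],
                                                       l, d$relationship[1]))
    names(dists) <- vapply(dists, function(d) d$rel, "")
    bank[[key]] <- list(l = l, dists = dists)
  }
  structure(list(genome = genome, relationships = relationships,
                 N = nrep, seed = seed, bank = bank,
                 version = as.character(packageVersion("segshare"))),
            class = "ibd_fit")
}

#' @export
print.ibd_fit <- function(x, ...) {
  cat("IBD sharing distribution bank\n")
  cat("  genome: ", x$genome$name, " (", x$genome$n_chrom, " chromosomes, ",
      format(x$genome$total_M), " M)\n", sep = "")
  cat("  relationships:", paste(x$relationships, collapse = " "), "\n")
  cat("  replicates per length class:", x$N, "\n")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
summary.ibd_fit <- function(object, ...) {
  rows <- list()
  for (cls in object$bank) {
    for (d in cls$dists) {
      nn <- key_decode(d$counts$code)$n_s
      rows[[length(rows) + 1L]] <- data.frame(
        relationship = d$rel, length_M = cls$l,
        mean_ns = sum(nn * d$counts$count) / d$N,
        p_zero = sum(d$counts$count[nn == 0L]) / d$N)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate genome-wide outcome profiles under a relationship
#'
#' Draws `nsim` fresh genomes (one outcome per chromosome of the fit's
#' genome model) under the given relationship.  Draws are independent of
#' the replicates stored in the bank.
#'
#' @param object An [ibd_fit()].
#' @param nsim Number of genome profiles.
#' @param seed Optional seed.
#' @param rel Relationship abbreviation.
#' @param ... Unused.
#' @return Data frame with columns `sim`, `chrom`, `length_M`, `n_s`,
#'   `p_s`, `t_s`, `total`.
#' @importFrom stats simulate
#' @export
simulate.ibd_fit <- function(object, nsim = 1, seed = NULL, rel, ...) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- chromosome_table(object$genome)
  out <- vector("list", nrow(object$genome$specs))
  specs <- object$genome$specs
  for (i in seq_len(nrow(specs))) {
    l <- specs$length_M[i]
    cnt <- specs$count[i]
    sim <- simulate_sharing(rel, l, nsim * cnt)
    ids <- chroms$chrom[chroms$length_M == l]
    out[[i]] <- data.frame(sim = rep(seq_len(nsim), each = cnt),
                           chrom = rep(ids, times = nsim),
                           length_M = l, n_s = sim$n_s, p_s = sim$p_s,
                           t_s = sim$t_s, total = sim$total)
  }
  out <- do.call(rbind, out)
  out[order(out$sim, out$chrom), ]
}

# fetch the distribution for (relationship, length)
get_dist <- function(fit, rel, l) {
  key <- len_key(l)
  cls <- fit$bank[[key]]
  if (is.null(cls)) stop("no distributions for chromosome length ", l, " M")
  d <- cls$dists[[rel]]
  if (is.null(d)) stop("no distribution for relationship '", rel,
                       "' at length ", l, " M")
  d
}

#' Write / read a distribution bank as a tab-separated file
#'
#' One record per outcome class with columns `relationship`, `length_cM`,
#' `n_s`, `p_s`, `t_s`, `count`; `#`-prefixed header lines record the genome
#' model, replicate count, seed and package version.  The round trip
#' `read_bank(write_bank(fit, f))` restores the bank bit-exactly.
#'
#' @param fit An [ibd_fit()] object.
#' @param path File path.
#' @return `write_bank` returns `path` invisibly; `read_bank` returns an
#'   `"ibd_fit"` object.
#' @export
write_bank <- function(fit, path) {
  stopifnot(inherits(fit, "ibd_fit"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# segshare distribution bank",
    sprintf("# version: %s", fit$version),
    sprintf("# genome: %s", fit$genome$name),
    sprintf("# chromosomes: %s", format(fit$genome)),
    sprintf("# N: %d", fit$N),
    sprintf("# seed: %s", if (is.null(fit$seed)) "NA" else format(fit$seed))),
    con)
  rows <- list()
  for (cls in fit$bank) {
    for (d in cls$dists) {
      k <- key_decode(d$counts$code)
      rows[[length(rows) + 1L]] <- data.frame(
        relationship = d$rel, length_cM = len_key(cls$l),
        n_s = k$n_s, p_s = k$p_s, t_s = k$t_s, count = d$counts$count)
    }
  }
  write.table(do.call(rbind, rows), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    if (!length(files)) stop("no bank files found in ", path)
    all <- lapply(files, readLines)
    extra <- unlist(lapply(all[-1], function(ln) {
      body <- ln[!grepl("^#", ln)]
      body[-1]  # drop the repeated column header
    }))
    lines <- c(all[[1]], extra)
  } else {
    lines <- readLines(path)
  }
  hdr <- grep("^#", lines, value = TRUE)
  getf <- function(field) {
    ln <- grep(paste0("^# ", field, ": "), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    sub(paste0("^# ", field, ": "), "", ln[1])
  }
  chrom_spec <- getf("chromosomes")
  parts <- strsplit(strsplit(chrom_spec, ",")[[1]], "\\*")
  gm <- genome_model(getf("genome"),
                     lengths = vapply(parts, function(p) as.numeric(p[1]), 0),
                     counts = vapply(parts, function(p) as.integer(p[2]), 0L))
  N <- as.integer(getf("N"))
  seed <- suppressWarnings(as.integer(getf("seed")))
  tab <- read.delim(textConnection(lines[!grepl("^#", lines)]), sep = "\t")
  bank <- list()
  for (key in unique(tab$length_cM)) {
    sub <- tab[tab$length_cM == key, ]
    l <- as.numeric(key) / 100
    dists <- lapply(split(sub, sub$relationship)[unique(sub$relationship)],
                    function(d) empirical_distribution(
                      d[, c("n_s", "p_s", "t_s", "count")], l, d$relationship[1]))
    names(dists) <- vapply(dists, function(d) d$rel, "")
    bank[[len_key(l)]] <- list(l = l, dists = dists)
  }
  rels <- unique(tab$relationship)
  structure(list(genome = gm, relationships = rels, N = N,
                 seed = if (is.na(seed)) NULL else seed, bank = bank,
                 version = getf("version")),
            class = "ibd_fit")
}
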