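#' Genome models: sets of chromosome map lengths
#'
#' A genome model is an ordered set of chromosome length classes over which
#' per-chromosome results are aggregated.  Lengths are stored in Morgans;
#' centimorgans appear only at I/O boundaries (segment files, bank files).
#'
#' Built-in models:
#' \describe{
#'   \item{`"human5"`}{Model human autosomal genome with map lengths
#'     simplified into five classes: 2 x 0.75 M, 8 x 1.25 M, 6 x 1.75 M,
#'     4 x 2.1 M, 2 x 2.75 M; 22 chromosomes totaling 35.9 M.}
#'   \item{`"equal22"`}{22 chromosomes each of 1.632 M, the mean length of
#'     `"human5"`.}
#'   \item{`"many72"`}{72 chromosomes each of 0.5 M (total 36 M).}
#'   \item{`"few12"`}{12 chromosomes each of 3 M (total 36 M).}
#' }
#'
#' @param name Name of a built-in model, or an arbitrary identifier when
#'   `lengths` is supplied.
#' @param lengths Numeric vector of chromosome map lengths in Morgans (one
#'   entry per length class), for a user-defined model.
#' @param counts Integer vector of the number of chromosomes in each length
#'   class; recycled to `length(lengths)`.
#' @return An object of class `"genome_model"`: a list with elements
#'   `name`, `specs` (data frame with columns `length_M`, `count`),
#'   `n_chrom` and `total_M`.
#' @examples
#' gm <- genome_model("human5")
#' gm$total_M  # 35.9
#' genome_model("toy", lengths = c(1, 2), counts = c(3, 1))
#' @export
genome_model <- function(name = "human5", lengths = NULL, counts = NULL) {
  if (is.null(lengths)) {
    builtin <- list(
      human5 = list(lengths = c(0.75, 1.25, 1.75, 2.10, 2.75),
                    counts = c(2L, 8L, 6L, 4L, 2L)),
      equal22 = list(lengths = 1.632, counts = 22L),
      many72 = list(lengths = 0.5, counts = 72L),
      few12 = list(lengths = 3.0, counts = 12L)
    )
    if (!name %in% names(builtin))
      stop("unknown genome model '", name, "'; built-ins are: ",
           paste(names(builtin), collapse = ", "),
           " (or supply 'lengths' for a custom model)")
    lengths <- builtin[[name]]$lengths
    counts <- builtin[[name]]$counts
  }
  if (is.null(counts)) counts <- 1L
  counts <- as.integer(rep_len(counts, length(lengths)))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome map lengths must be positive and finite (Morgans)")
  if (any(counts < 1L))
    stop("chromosome counts must be >= 1")
  specs <- data.frame(length_M = as.numeric(lengths), count = counts)
  out <- list(name = name, specs = specs,
              n_chrom = sum(counts),
              total_M = sum(lengths * counts))
  class(out) <- "genome_model"
  out
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Genome model '", x$name, "': ", x$n_chrom, " chromosomes, ",
      format(x$total_M), " M total\n", sep = "")
  for (i in seq_len(nrow(x$specs)))
    cat(sprintf("  %d x %g M\n", x$specs$count[i], x$specs$length_M[i]))
  invisible(x)
}

#' @export
format.genome_model <- function(x, ...) {
  paste(sprintf("%g*%d", x$specs$length_M, x$specs$count), collapse = ",")
}

#' Per-chromosome table of a genome model
#'
#' Expands the length classes of a genome model into one row per chromosome,
#' in the order the classes are listed, with identifiers `1:n`.  This fixes
#' the chromosome-id convention used when classifying observed segment
#' files.
#'
#' @param genome A [genome_model()] object.
#' @return Data frame with columns `chrom` (integer id) and `length_M`.
#' @export
chromosome_table <- function(genome) {
  stopifnot(inherits(genome, "genome_model"))
  len <- rep(genome$specs$length_M, genome$specs$count)
  data.frame(chrom = seq_along(len), length_M = len)
}

#' Read a genome model from a JSON config file
#'
#' The config is a JSON object with a `genome` entry that is either
#' `{"name": "human5"}` (a built-in) or
#' `{"chromosomes": [{"length_M": 1.5, "count": 4}, ...]}`; lengths may be
#' given as `length_cM` instead, in which case they are divided by 100.
#' Class order in the file is preserved for reporting.
#'
#' @param path Path to the JSON file.
#' @return A [genome_model()] object.
#' @export
read_genome_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- if (!is.null(cfg$genome)) cfg$genome else cfg
  if (!is.null(g$name) && is.null(g$chromosomes))
    return(genome_model(g$name))
  ch <- g$chromosomes
  if (is.null(ch)) stop("config must contain genome$name or genome$chromosomes")
  ch <- as.data.frame(ch)
  len <- if (!is.null(ch$length_M)) ch$length_M else ch$length_cM / 100
  if (is.null(len)) stop("each chromosome entry needs length_M or length_cM")
  cnt <- if (!is.null(ch$count)) ch$count else 1L
  nm <- if (!is.null(g$name)) g$name else "custom"
  genome_model(nm, lengths = len, counts = cnt)
}
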