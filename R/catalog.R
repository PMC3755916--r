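# The 19 uniparental relationships, organised by family base.
#
# g1, g2 count meioses on the path from the common ancestor(s) to each
# individual, so d = g1 + g2 is the total number of meioses separating the
# pair through the shared ancestry.  For the full-sib base the individual at
# g = 1 is a sib of the founder couple and is tracked as a diploid (both
# haplotypes are founder gametes); for the half-sib base and lineal chains
# there is a single diploid common ancestor and g = 0 denotes the ancestor
# itself.  a is the number of common ancestors (2 for the full-sib base).
.catalog <- local({
  df <- rbind(
    data.frame(abbrev = c("UN", "GUGN", "C", "C1R", "2C", "2C1R", "3C"),
               base = "full-sib",
               g1 = c(1L, 1L, 2L, 2L, 3L, 3L, 4L),
               g2 = c(2L, 3L, 2L, 3L, 3L, 4L, 4L),
               a = 2L,
               description = c("uncle-nephew", "great-uncle-great-nephew",
                               "full cousins", "cousins once removed",
                               "second cousins", "second cousins once removed",
                               "third cousins")),
    data.frame(abbrev = c("HS", "HUN", "HC", "HC1R", "H2C", "H2C1R"),
               base = "half-sib",
               g1 = c(1L, 1L, 2L, 2L, 3L, 3L),
               g2 = c(1L, 2L, 2L, 3L, 3L, 4L),
               a = 1L,
               description = c("half-sibs", "half-uncle-nephew",
                               "half-cousins", "half-cousins once removed",
                               "half second cousins",
                               "half second cousins once removed")),
    data.frame(abbrev = c("GPO", "GGPO", "G3PO", "G4PO", "G5PO", "G6PO"),
               base = "lineal",
               g1 = 0L,
               g2 = 2:7,
               a = 1L,
               description = c("grandparent-grandoffspring",
                               paste0(vapply(1:5, function(k)
                                 paste(rep("great-", k), collapse = ""),
                                 character(1)),
                                 "grandparent-offspring")))
  )
  df$d <- df$g1 + df$g2
  df$R <- ifelse(df$base == "full-sib", 2, 1) * 0.5^df$d
  rownames(df) <- df$abbrev
  df[, c("abbrev", "base", "R", "g1", "g2", "d", "a", "description")]
})

#' Catalog of the 19 uniparental pedigree relationships
#'
#' Returns the full catalog of relationships handled by the simulator:
#' seven with a full-sib family base (UN, GUGN, C, C1R, 2C, 2C1R, 3C), six
#' with a half-sib base (HS, HUN, HC, HC1R, H2C, H2C1R) and six lineal
#' ancestor-descendant chains (GPO through G6PO).  `R` is Wright's numerator
#' relationship; `g1`/`g2` are the meiosis counts from the common
#' ancestor(s) to each individual and `d = g1 + g2` the total path length;
#' `a` is the number of common ancestors.
#'
#' @return Data frame with columns `abbrev`, `base`, `R`, `g1`, `g2`, `d`,
#'   `a`, `description`; one row per relationship.
#' @examples
#' relationships()[c("HS", "C", "3C"), ]
#' @export
relationships <- function() .catalog

#' Look up (or construct) a relationship specification
#'
#' `relationship("HS")` fetches a catalog entry.  A non-catalog uniparental
#' relationship can be constructed by giving the family base and meiosis
#' counts, e.g. `relationship(base = "half-sib", g1 = 1, g2 = 3)` for a
#' half-great-uncle--great-nephew pair; such specs are accepted everywhere a
#' catalog entry is (simulation, closed-form counts).
#'
#' @param abbrev Catalog abbreviation (see [relationships()]).
#' @param base One of `"full-sib"`, `"half-sib"`, `"lineal"`.
#' @param g1,g2 Meioses from the common ancestor(s) to each individual.
#'   For the full-sib base both must be >= 1 (g = 1 is a sib of the founder
#'   couple, kept diploid); for the half-sib base both >= 1; for lineal
#'   `g1 = 0` and `g2 >= 1`.
#' @return A one-row data frame with the catalog columns (class
#'   `"relationship_spec"` prepended).
#' @export
relationship <- function(abbrev = NULL, base = NULL, g1 = NULL, g2 = NULL) {
  if (!is.null(abbrev)) {
    if (inherits(abbrev, "relationship_spec")) return(abbrev)
    if (is.data.frame(abbrev) && nrow(abbrev) == 1L) {
      out <- abbrev
      class(out) <- c("relationship_spec", "data.frame")
      return(out)
    }
    if (!abbrev %in% .catalog$abbrev)
      stop("unknown relationship '", abbrev, "'; see relationships()")
    out <- .catalog[abbrev, ]
  } else {
    base <- match.arg(base, c("full-sib", "half-sib", "lineal"))
    g1 <- as.integer(g1); g2 <- as.integer(g2)
    if (base == "lineal") {
      if (g1 != 0L || g2 < 1L) stop("lineal relationships need g1 = 0, g2 >= 1")
    } else if (g1 < 1L || g2 < 1L) {
      stop("collateral relationships need g1 >= 1 and g2 >= 1")
    }
    a <- if (base == "full-sib") 2L else 1L
    d <- g1 + g2
    out <- data.frame(abbrev = sprintf("%s(%d,%d)", base, g1, g2),
                      base = base, R = a * 0.5^d, g1 = g1, g2 = g2,
                      d = d, a = a, description = "custom")
  }
  class(out) <- c("relationship_spec", "data.frame")
  out
}

# chain indices used by the C++ simulator: index 0 is the diploid endpoint
# (sib of the founder couple, or the single common ancestor); index k >= 1
# is the tracked haplotype k meioses below it.
.chain_index <- function(rel) {
  rel <- relationship(rel)
  if (rel$base == "full-sib") c(rel$g1 - 1L, rel$g2 - 1L)
  else c(rel$g1, rel$g2)
}

.base_code <- function(base) if (base == "full-sib") 1L else 2L
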