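#' Gene-name alias table for the growth-plate network
#'
#' The growth-plate literature mixes spellings for several regulators
#' (NF-κB / NFκB / NFkB; HIF-2α / HIF-α2 / HIF-2a;
#' δ-EF1 / delta-EF1; Atf2 / ATF2 ...).  The package stores one ASCII
#' canonical spelling per gene and maps every accepted alias onto it, so that
#' networks, priors and expression matrices read from different sources line
#' up on the same node set.
#'
#' @return A named character vector mapping each accepted alias to its
#'   canonical gene name.  Alias sets are pairwise disjoint and the mapping is
#'   idempotent (every canonical name maps to itself).
#' @seealso [canonical_gene_names()]
#' @export
#' @examples
#' head(gene_alias_table())
gene_alias_table <- function() {
  tab <- c(
    # NF-kappa-B
    "NF-κB" = "NFkB", "NFκB" = "NFkB", "NF-kB" = "NFkB",
    "NFKB" = "NFkB", "NFkb" = "NFkB", "NFkB" = "NFkB",
    # delta-EF1 (ZEB1)
    "δ-EF1" = "dEF1", "d-EF1" = "dEF1", "delta-EF1" = "dEF1",
    "deltaEF1" = "dEF1", "dEF-1" = "dEF1", "dEF1" = "dEF1",
    # HIF-2alpha (EPAS1); the literature also writes HIF-alpha2
    "HIF-2α" = "HIF2a", "HIF-α2" = "HIF2a", "HIF-2a" = "HIF2a",
    "HIF-a2" = "HIF2a", "HIF2A" = "HIF2a", "HIF-2A" = "HIF2a",
    "HIF2a" = "HIF2a",
    # case variants seen across tables and figures
    "Atf2" = "ATF2", "ATF2" = "ATF2",
    "Stat1" = "STAT1", "STAT1" = "STAT1",
    "Mef2c" = "MEF2C", "MEF2C" = "MEF2C",
    "Ccnd1" = "CCND1", "CCND1" = "CCND1",
    "Ets-1" = "Ets1", "Ets1" = "Ets1",
    "Gli2" = "Gli2", "Tcf7" = "Tcf7", "Runx2" = "Runx2",
    "Sox9" = "Sox9", "Dlx5" = "Dlx5"
  )
  tab
}

#' Canonicalize gene names
#'
#' Trims whitespace and maps known aliases onto their canonical spelling;
#' names without a registered alias pass through unchanged, so the function is
#' idempotent.
#'
#' @param x Character vector of gene names.
#' @return Character vector of the same length with canonical names.
#' @export
#' @examples
#' canonical_gene_names(c("NF-κB", "HIF-α2", "Sox9", "Foo"))
canonical_gene_names <- function(x) {
  stopifnot(is.character(x))
  x <- trimws(x)
  tab <- gene_alias_table()
  hit <- x %in% names(tab)
  x[hit] <- unname(tab[x[hit]])
  x
}
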