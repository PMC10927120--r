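#' Pipeline thresholds
#'
#' Collects every tunable cutoff of the parsing and classification pipeline
#' in one validated list, so a whole run is reproducible from a single
#' configuration object.
#'
#' @param plddt_min Per-residue confidence cutoff (pLDDT units, 0-100) below
#'   which a region is demoted to low-confidence. Default 70.
#' @param sse_min_for_globular Minimum number of secondary-structure elements
#'   for a domain to count as non-simple topology; regions with fewer than
#'   this (i.e. 2 or fewer SSEs by default) are "simple". Default 3.
#' @param segment_len Length (residues) of the segments clustered into
#'   domains. Default 5.
#' @param pair_prob_cut Average-linkage threshold on the same-domain pair
#'   probability at which segment clusters stop merging. Default 0.5.
#' @param min_domain_len Candidates shorter than this (residues) are merged
#'   into a neighbour or dropped. Default 25.
#' @param conf_min Minimum hit confidence for a homology-based assignment.
#'   Default 0.8.
#' @param cov_assign Minimum reference coverage for a full assignment.
#'   Default 0.7.
#' @param cov_partial Reference coverage below which a confident hit is only
#'   a partial-domain link. Default 0.5.
#' @param flex_partner_pae PAE cutoff (Angstrom) defining a low-error
#'   long-range partner when flagging flexible residues. Default 10.
#' @param flex_min_partners Minimum number of such partners for a residue to
#'   count as globular. Default 5.
#' @param flex_seq_sep Minimum sequence separation for a partner to count as
#'   long-range. Default 10.
#' @param alpha Significance level for enrichment testing (before Bonferroni
#'   correction). Default 0.05.
#' @return A named list of class `afd_thresholds`.
#' @examples
#' t <- default_thresholds()
#' t$plddt_min
#' @export
default_thresholds <- function(plddt_min = 70,
                               sse_min_for_globular = 3L,
                               segment_len = 5L,
                               pair_prob_cut = 0.5,
                               min_domain_len = 25L,
                               conf_min = 0.8,
                               cov_assign = 0.7,
                               cov_partial = 0.5,
                               flex_partner_pae = 10,
                               flex_min_partners = 5L,
                               flex_seq_sep = 10L,
                               alpha = 0.05) {
  t <- list(plddt_min = plddt_min,
            sse_min_for_globular = as.integer(sse_min_for_globular),
            segment_len = as.integer(segment_len),
            pair_prob_cut = pair_prob_cut,
            min_domain_len = as.integer(min_domain_len),
            conf_min = conf_min,
            cov_assign = cov_assign,
            cov_partial = cov_partial,
            flex_partner_pae = flex_partner_pae,
            flex_min_partners = as.integer(flex_min_partners),
            flex_seq_sep = as.integer(flex_seq_sep),
            alpha = alpha)
  stopifnot(t$plddt_min >= 0, t$plddt_min <= 100,
            t$pair_prob_cut >= 0, t$pair_prob_cut <= 1,
            t$conf_min >= 0, t$conf_min <= 1,
            t$cov_assign >= 0, t$cov_assign <= 1,
            t$cov_partial >= 0, t$cov_partial <= 1,
            t$alpha > 0, t$alpha <= 1,
            t$segment_len >= 1L, t$min_domain_len >= 1L,
            t$sse_min_for_globular >= 1L,
            t$flex_min_partners >= 1L, t$flex_seq_sep >= 1L,
            t$flex_partner_pae >= 0)
  class(t) <- "afd_thresholds"
  t
}

#' The six region categories
#'
#' Every residue of every classified model receives exactly one of these
#' labels: `ASSIGNED` (globular domain with a well-defined homologous link to
#' a reference domain), `UNASSIGNED` (globular but no confident reference
#' link), `PARTIAL` (confident link but no high-coverage alignment),
#' `SIMPLE` (2 or fewer secondary-structure elements), `FLEXIBLE`
#' (linker/disordered by PAE, adequate confidence), and `LOW_CONFIDENCE`
#' (pLDDT below the confidence cutoff).
#'
#' @return Character vector of the six labels, in reporting order.
#' @export
region_labels <- function() {
  c("ASSIGNED", "UNASSIGNED", "PARTIAL", "SIMPLE", "FLEXIBLE",
    "LOW_CONFIDENCE")
}
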