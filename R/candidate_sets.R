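#' Reported candidate-position sets for the Fm1 desaturase
#'
#' The per-category candidate lists from the original comparative analysis of
#' Fm1 against delta-12 desaturases (AtFAD2, DesA, AtFAD6) and omega-3
#' desaturases (AtFAD8, AtFAD7, AtFAD3, DesB), in Fm1 residue numbering.
#' Shipped for bookkeeping checks and as the worked example of the Venn
#' category scheme.
#'
#' Category semantics follow [classify_column()]: `shared_delta12` (category
#' 1) positions conserved in the delta-12 group and shared by Fm1;
#' `delta12_only` (2) conserved in the delta-12 group only; `shared_omega3`
#' (3) conserved in the omega-3 group and shared by Fm1; `omega3_only` (4)
#' conserved in the omega-3 group. As published, the omega-3 listing subsumes
#' the shared-omega3 subset, positions 98 and 99 appear in both delta-12
#' categories, and 318 appears only under `shared_delta12`; the lists are
#' reproduced verbatim, overlaps included — [merge_category_lists()] resolves
#' them to the 44 unique candidate positions.
#'
#' @return Named list of four integer vectors: `shared_delta12`,
#'   `delta12_only`, `shared_omega3`, `omega3_only`.
#' @examples
#' length(merge_category_lists(fm1_candidate_sets()))  # 44
#' @export
fm1_candidate_sets <- function() {
  list(
    shared_delta12 = c(98L, 99L, 318L),
    delta12_only = c(98L, 99L, 120L, 298L, 350L, 377L),
    shared_omega3 = c(110L, 162L, 229L, 235L, 238L, 240L, 273L, 280L),
    omega3_only = c(36L, 97L, 110L, 136L, 139L, 143L, 156L, 162L, 165L,
                    198L, 199L, 206L, 207L, 208L, 228L, 229L, 235L, 237L,
                    238L, 240L, 248L, 250L, 273L, 280L, 284L, 288L, 290L,
                    302L, 304L, 305L, 327L, 330L, 335L, 367L, 380L, 391L,
                    398L)
  )
}

#' Reported paralog-divergent positions between Fm1 and Fm2
#'
#' The 14 positions (Fm1 numbering) where the paralogs Fm1 and Fm2 differ
#' from each other while neither the delta-12 nor the omega-3 group is
#' conserved — the scan implemented by [divergent_sites()].
#'
#' @return Integer vector of 14 positions.
#' @export
fm1_fm2_divergent_positions <- function() {
  c(25L, 67L, 121L, 153L, 164L, 190L, 194L, 207L, 210L, 240L, 264L, 271L,
    345L, 396L)
}
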