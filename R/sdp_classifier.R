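# Column classification: group consensus, the four-category Venn scheme,
# candidate scanning, and paralog-divergence scanning.
#
# Category semantics (query = the bifunctional enzyme under study):
#   1 = delta12 group conserved AND query matches its consensus
#   2 = delta12 group conserved AND query differs
#   3 = omega3 group conserved AND query matches its consensus
#   4 = omega3 group conserved AND query differs
# A column is a candidate only when the two groups actually differ (one
# group's consensus absent, or the two consensuses unequal); a column that is
# identically conserved across both groups carries no signal about
# specificity and is never called. Both group sides are evaluated
# independently, so one site may carry a delta12-side and an omega3-side flag
# simultaneously.

AA_CLASSES <- c(
  A = "hydrophobic", V = "hydrophobic", L = "hydrophobic", I = "hydrophobic",
  M = "hydrophobic",
  F = "aromatic", W = "aromatic", Y = "aromatic",
  S = "polar", T = "polar", N = "polar", Q = "polar",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative",
  G = "special", P = "special", C = "special",
  X = "unknown"
)

#' Consensus residue of one group at one alignment column
#'
#' A residue is the consensus when its frequency among the column's non-gap
#' entries reaches `threshold`; with the default `threshold = 1` this is
#' strict unanimity. Columns with more than `max_gap_frac` gaps in the group
#' return no consensus (too little evidence), as do all-gap columns.
#'
#' @param residues Character vector of one group's residues at one column
#'   (single letters, `-` for gap).
#' @param threshold Consensus frequency threshold, in `(0.5, 1]`. The lower
#'   bound guarantees at most one consensus residue per column.
#' @param max_gap_frac Maximum tolerated gap fraction in the group column
#'   (default 0.25) before the column is declared uninformative.
#' @param mode `"identity"`: consensus over residue identities.
#'   `"property"`: consensus over physico-chemical classes (hydrophobic,
#'   aromatic, polar, positive, negative, special); the returned residue is
#'   the most frequent residue of the consensus class and carries the class
#'   as attribute `"aa_class"`.
#' @return A single residue character, or `NA_character_` when no consensus.
#' @examples
#' group_consensus(c("W", "W", "W"))            # "W"
#' group_consensus(c("W", "W", "F"))            # NA
#' group_consensus(c("W", "W", "F"), 0.66)      # "W"
#' @export
group_consensus <- function(residues, threshold = 1, max_gap_frac = 0.25,
                            mode = c("identity", "property")) {
  mode <- match.arg(mode)
  if (length(residues) == 0) stop("empty group column", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1) {
    stop("`threshold` must lie in (0.5, 1]", call. = FALSE)
  }
  gaps <- residues == GAP
  if (all(gaps)) return(NA_character_)
  if (mean(gaps) > max_gap_frac) return(NA_character_)
  obs <- residues[!gaps]
  if (mode == "identity") {
    freq <- table(obs) / length(obs)
    top <- names(freq)[which.max(freq)]
    if (freq[[top]] >= threshold) return(top)
    return(NA_character_)
  }
  cls <- AA_CLASSES[obs]
  cls[is.na(cls) | cls == "unknown"] <- NA
  cfreq <- table(cls) / length(obs)
  if (length(cfreq) == 0) return(NA_character_)
  topc <- names(cfreq)[which.max(cfreq)]
  if (cfreq[[topc]] < threshold) return(NA_character_)
  members <- obs[!is.na(cls) & cls == topc]
  rep_res <- names(sort(table(members), decreasing = TRUE))
  rep_res <- sort(rep_res[table(members)[rep_res] == max(table(members))])[1]
  structure(rep_res, aa_class = topc)
}

#' @noRd
consensus_differs <- function(a, b, mode) {
  if (is.na(a) || is.na(b)) return(TRUE)
  if (mode == "property") {
    return(!identical(attr(a, "aa_class"), attr(b, "aa_class")))
  }
  unname(a) != unname(b)
}

#' Per-column residue profile of a grouped alignment
#'
#' @param ga A [grouped_alignment()].
#' @param column 1-based alignment column.
#' @inheritParams group_consensus
#' @return List with the column index, each group's residues, each group's
#'   consensus (or `NA`) and the query residue.
#' @export
column_profile <- function(ga, column, threshold = 1, max_gap_frac = 0.25,
                           mode = c("identity", "property")) {
  stopifnot(inherits(ga, "grouped_alignment"))
  mode <- match.arg(mode)
  if (column < 1 || column > ga$width) {
    stop("column ", column, " outside alignment width ", ga$width,
         call. = FALSE)
  }
  col_res <- vapply(ga$aligned, function(s) substr(s, column, column),
                    character(1))
  d12 <- col_res[ga$groups == "delta12"]
  w3 <- col_res[ga$groups == "omega3"]
  if (length(d12) == 0 || length(w3) == 0) {
    stop("alignment must contain at least one delta12 and one omega3 row",
         call. = FALSE)
  }
  qid <- ga$reference_id
  if (is.null(qid)) stop("no reference (query) row designated", call. = FALSE)
  list(column = column,
       delta12 = d12,
       omega3 = w3,
       delta12_consensus = group_consensus(d12, threshold, max_gap_frac, mode),
       omega3_consensus = group_consensus(w3, threshold, max_gap_frac, mode),
       query_residue = unname(col_res[qid]),
       mode = mode)
}

#' Classify one column profile into Venn categories
#'
#' @param profile A [column_profile()].
#' @return Integer vector of applicable categories (subset of 1:4, possibly
#'   empty). Columns where the query has a gap return an empty classification
#'   with a notice; so do columns where both groups share one consensus.
#' @examples
#' ga <- grouped_alignment(
#'   ids = c("d1", "d2", "w1", "w2", "q"),
#'   aligned = c("V", "V", "I", "I", "I"),
#'   groups = c("delta12", "delta12", "omega3", "omega3", "query")
#' )
#' classify_column(column_profile(ga, 1))  # 2 (delta side) and 3 (omega side)
#' @export
classify_column <- function(profile) {
  q <- profile$query_residue
  if (is.na(q) || q == GAP) {
    message("Note: query has a gap at column ", profile$column,
            "; column skipped")
    return(integer(0))
  }
  dc <- profile$delta12_consensus
  wc <- profile$omega3_consensus
  if (!consensus_differs(dc, wc, profile$mode) ||
      (is.na(dc) && is.na(wc))) {
    return(integer(0))
  }
  out <- integer(0)
  if (!is.na(dc)) out <- c(out, if (unname(dc) == q) 1L else 2L)
  if (!is.na(wc)) out <- c(out, if (unname(wc) == q) 3L else 4L)
  out
}

#' Scan a grouped alignment for candidate specificity-determining positions
#'
#' Walks every alignment column, computes the delta12 and omega3 group
#' consensuses, classifies the column into the four-category Venn scheme, and
#' reports candidate sites in the ungapped numbering of the query sequence.
#'
#' @param ga A [grouped_alignment()] with at least one `delta12` row, one
#'   `omega3` row, and a designated query row.
#' @inheritParams group_consensus
#' @return A data frame, one row per candidate reference position, sorted by
#'   `ref_position`, with columns `ref_position`, `column`, `categories`
#'   (comma-joined sorted category flags, e.g. `"3"` or `"2,3"`),
#'   `query_residue`, `delta12_consensus`, `omega3_consensus` (NA when the
#'   group has no consensus).
#' @export
scan_candidates <- function(ga, threshold = 1, max_gap_frac = 0.25,
                            mode = c("identity", "property")) {
  stopifnot(inherits(ga, "grouped_alignment"))
  mode <- match.arg(mode)
  if (sum(ga$groups == "delta12") == 0 || sum(ga$groups == "omega3") == 0) {
    stop("alignment must contain at least one delta12 and one omega3 row",
         call. = FALSE)
  }
  if (is.null(ga$reference_id)) {
    stop("no reference (query) row designated", call. = FALSE)
  }
  cm <- build_column_map(ga, ga$reference_id)
  rows <- vector("list", ga$width)
  qchars <- chars(ga$aligned[[ga$reference_id]])
  for (j in seq_len(ga$width)) {
    if (qchars[j] == GAP) next
    prof <- column_profile(ga, j, threshold, max_gap_frac, mode)
    cats <- classify_column(prof)
    if (length(cats) == 0) next
    rows[[j]] <- data.frame(
      ref_position = cm$col_to_res[j],
      column = j,
      categories = paste(sort(cats), collapse = ","),
      query_residue = prof$query_residue,
      delta12_consensus = unname(prof$delta12_consensus),
      omega3_consensus = unname(prof$omega3_consensus),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(ref_position = integer(0), column = integer(0),
                      categories = character(0), query_residue = character(0),
                      delta12_consensus = character(0),
                      omega3_consensus = character(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$ref_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positions where neither a paralog pair nor the functional groups agree
#'
#' Scans two homologous query-role sequences (e.g. the paralogs Fm1 and Fm2)
#' for positions where the paralogs differ from each other while neither the
#' delta12 nor the omega3 group reaches consensus — positions free to drift
#' between paralogs yet unconstrained in either monofunctional group, hence
#' candidate paralog-specificity sites.
#'
#' @param ga A [grouped_alignment()] containing both paralogs.
#' @param query1_id,query2_id Row ids of the two paralogs. Positions are
#'   reported in `query1_id`'s ungapped numbering.
#' @inheritParams group_consensus
#' @return Data frame with `ref_position`, `column`, `query1_residue`,
#'   `query2_residue`, sorted by position.
#' @export
divergent_sites <- function(ga, query1_id, query2_id, threshold = 1,
                            max_gap_frac = 0.25) {
  stopifnot(inherits(ga, "grouped_alignment"))
  if (!query1_id %in% ga$ids) stop("unknown id '", query1_id, "'", call. = FALSE)
  if (!query2_id %in% ga$ids) stop("unknown id '", query2_id, "'", call. = FALSE)
  if (identical(query1_id, query2_id)) {
    stop("query1_id and query2_id must differ", call. = FALSE)
  }
  if (sum(ga$groups == "delta12") == 0 || sum(ga$groups == "omega3") == 0) {
    stop("alignment must contain at least one delta12 and one omega3 row",
         call. = FALSE)
  }
  cm <- build_column_map(ga, query1_id)
  q1 <- chars(ga$aligned[[query1_id]])
  q2 <- chars(ga$aligned[[query2_id]])
  d12_rows <- ga$ids[ga$groups == "delta12"]
  w3_rows <- ga$ids[ga$groups == "omega3"]
  d12_mat <- do.call(rbind, lapply(ga$aligned[d12_rows], chars))
  w3_mat <- do.call(rbind, lapply(ga$aligned[w3_rows], chars))
  keep <- logical(ga$width)
  for (j in seq_len(ga$width)) {
    if (q1[j] == GAP || q2[j] == GAP || q1[j] == q2[j]) next
    dc <- group_consensus(d12_mat[, j], threshold, max_gap_frac)
    if (!is.na(dc)) next
    wc <- group_consensus(w3_mat[, j], threshold, max_gap_frac)
    if (!is.na(wc)) next
    keep[j] <- TRUE
  }
  cols <- which(keep)
  out <- data.frame(ref_position = cm$col_to_res[cols],
                    column = cols,
                    query1_residue = q1[cols],
                    query2_residue = q2[cols],
                    stringsAsFactors = FALSE)
  out <- out[order(out$ref_position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-category position lists into one unique candidate set
#'
#' Bookkeeping helper: categories in the Venn scheme overlap (one position
#' may be flagged on both group sides), so the total candidate count is the
#' size of the union, not the sum of the per-category list lengths.
#'
#' @param category_positions A list of integer vectors of reference
#'   positions, one per category.
#' @return Sorted unique integer vector of all positions.
#' @export
merge_category_lists <- function(category_positions) {
  stopifnot(is.list(category_positions))
  sort(unique(unlist(category_positions, use.names = FALSE)))
}
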