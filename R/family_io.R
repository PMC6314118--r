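# Alignment ingestion, group labelling, and column/residue numbering.
#
# All numbering is 1-based, for both alignment columns and ungapped residue
# positions, matching standard protein mutation nomenclature (e.g. "F157H"
# refers to the 157th residue of the ungapped query sequence).

#' Construct a group-labelled multiple sequence alignment
#'
#' The central container of the package: an alignment whose rows carry
#' functional group labels (`delta12`, `omega3`, `query`, `other`) and which
#' designates one row as the reference (query) sequence in whose ungapped
#' numbering all candidate positions are reported.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param aligned Character vector of aligned sequences (same length as
#'   `ids`), all of equal width, using `-` for gaps (`.` is normalized to
#'   `-` with a notice). Case-insensitive; ambiguity codes other than `X`
#'   are rejected.
#' @param groups Group label per sequence: either a character vector parallel
#'   to `ids` or a named vector/list keyed by id. Labels must be one of
#'   `delta12`, `omega3`, `query`, `other`.
#' @param reference_id Id of the query-role sequence. Defaults to the unique
#'   row labelled `query` when there is exactly one.
#' @param descriptions Optional free-text description per sequence.
#'
#' @return An object of class `grouped_alignment`: a list with elements
#'   `ids`, `aligned` (named character), `groups` (named character),
#'   `reference_id`, `width`.
#' @examples
#' ga <- grouped_alignment(
#'   ids = c("a", "b", "q"),
#'   aligned = c("ACD-", "AC-E", "ACDE"),
#'   groups = c("delta12", "omega3", "query"),
#'   reference_id = "q"
#' )
#' ga$width
#' @export
grouped_alignment <- function(ids, aligned, groups, reference_id = NULL,
                              descriptions = NULL) {
  stopifnot(is.character(ids), is.character(aligned),
            length(ids) == length(aligned))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(ids) == 0) stop("alignment must contain at least one row",
                             call. = FALSE)
  if (is.list(groups)) groups <- unlist(groups)
  if (!is.null(names(groups))) {
    missing_ids <- setdiff(ids, names(groups))
    if (length(missing_ids) > 0) {
      stop("no group label for sequence(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    groups <- unname(groups[ids])
  } else if (length(groups) != length(ids)) {
    stop("`groups` must be named by id or parallel to `ids`", call. = FALSE)
  }
  check_group_labels(groups)

  aligned <- vapply(seq_along(aligned),
                    function(i) normalize_residues(aligned[i], ids[i]),
                    character(1))
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1) {
    off <- ids[widths != widths[1]][1]
    stop("ragged alignment: row '", off, "' has width ",
         nchar(aligned[ids == off]), " but row '", ids[1], "' has width ",
         widths[1], call. = FALSE)
  }
  if (any(degap(aligned) == "")) {
    stop("row '", ids[degap(aligned) == ""][1], "' is all gaps", call. = FALSE)
  }

  if (is.null(reference_id)) {
    qi <- ids[groups == "query"]
    if (length(qi) == 1) reference_id <- qi
  }
  if (!is.null(reference_id) && !reference_id %in% ids) {
    stop("reference_id '", reference_id, "' is not a row of the alignment",
         call. = FALSE)
  }

  structure(
    list(ids = ids,
         aligned = setNames(aligned, ids),
         groups = setNames(groups, ids),
         reference_id = reference_id,
         descriptions = if (is.null(descriptions)) setNames(rep("", length(ids)), ids)
                        else setNames(descriptions, ids),
         width = unname(widths[1])),
    class = "grouped_alignment"
  )
}

#' @export
print.grouped_alignment <- function(x, ...) {
  cat("grouped_alignment: ", length(x$ids), " sequences, width ", x$width,
      "\n", sep = "")
  tab <- table(factor(x$groups, levels = VALID_GROUPS))
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  if (!is.null(x$reference_id))
    cat("  reference: ", x$reference_id, "\n", sep = "")
  invisible(x)
}

#' Ungapped residue string of one alignment row
#' @param ga A [grouped_alignment()].
#' @param id Sequence id.
#' @return Character scalar, the ungapped residues.
#' @export
ungapped_sequence <- function(ga, id) {
  stopifnot(inherits(ga, "grouped_alignment"))
  if (!id %in% ga$ids) stop("unknown sequence id '", id, "'", call. = FALSE)
  degap(ga$aligned[[id]])
}

#' Read a group-labelled alignment from FASTA or Clustal
#'
#' Ingests the output of any external aligner (e.g. PROMALS3D, MAFFT) and
#' attaches group labels. The aligner itself is deliberately external: point
#' this reader at whichever alignment file your aligner produced.
#'
#' @param path Path to the alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param groups Group labels: a named character vector (id -> group), a
#'   data frame with columns `id` and `group`, or the path to a two-column
#'   TSV (`id<TAB>group`, no header required; a header line `id<TAB>group`
#'   is tolerated) or JSON file (an object mapping id to group).
#' @param reference_id Optional id of the query-role row; defaults to the
#'   unique row labelled `query`.
#' @return A [grouped_alignment()] with row order preserved from the file.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"), groups,
                           reference_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "fasta") {
    aa <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(aa))
    desc <- sub("^\\S+\\s*", "", names(aa))
    aligned <- as.character(aa)
    widths <- nchar(aligned)
    if (length(unique(widths)) != 1) {
      stop("ragged alignment in ", path, ": row '",
           ids[widths != widths[1]][1], "' has a different width",
           call. = FALSE)
    }
  } else {
    msa <- Biostrings::readAAMultipleAlignment(path, format = "clustal")
    aligned <- as.character(msa)
    ids <- names(aligned)
    desc <- rep("", length(ids))
  }
  groups <- resolve_group_table(groups, ids)
  grouped_alignment(ids = ids, aligned = unname(aligned), groups = groups,
                    reference_id = reference_id, descriptions = desc)
}

#' @noRd
resolve_group_table <- function(groups, ids) {
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    if (grepl("\\.json$", groups, ignore.case = TRUE)) {
      groups <- unlist(jsonlite::read_json(groups, simplifyVector = TRUE))
    } else {
      tab <- read.delim(groups, header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("id", "group"))
      if (nrow(tab) > 0 && tab$id[1] == "id" && tab$group[1] == "group")
        tab <- tab[-1, , drop = FALSE]
      groups <- setNames(tab$group, tab$id)
    }
  }
  if (is.data.frame(groups)) {
    stopifnot(all(c("id", "group") %in% names(groups)))
    groups <- setNames(groups$group, groups$id)
  }
  if (is.null(names(groups))) {
    stop("`groups` must map sequence ids to group labels", call. = FALSE)
  }
  unknown <- setdiff(ids, names(groups))
  if (length(unknown) > 0) {
    stop("sequence id(s) missing from the groups table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  groups[ids]
}

#' Write an alignment to FASTA or Clustal
#'
#' @param ga A [grouped_alignment()].
#' @param path Output path.
#' @param format `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(ga, path, format = c("fasta", "clustal")) {
  stopifnot(inherits(ga, "grouped_alignment"))
  format <- match.arg(format)
  if (format == "fasta") {
    aa <- Biostrings::AAStringSet(ga$aligned)
    Biostrings::writeXStringSet(aa, path)
  } else {
    write_clustal(ga$aligned, path)
  }
  invisible(path)
}

# Minimal CLUSTAL-format writer (60-column blocks); readable by
# Biostrings::readAAMultipleAlignment(format = "clustal").
#' @noRd
write_clustal <- function(aligned, path, block = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("CLUSTAL W multiple sequence alignment", "", ""), con)
  width <- nchar(aligned[1])
  namew <- max(nchar(names(aligned))) + 3
  for (start in seq(1, width, by = block)) {
    end <- min(start + block - 1, width)
    for (i in seq_along(aligned)) {
      writeLines(sprintf("%-*s%s", namew, names(aligned)[i],
                         substr(aligned[i], start, end)), con)
    }
    writeLines("", con)
  }
}

#' Map alignment columns to ungapped residue numbers
#'
#' Builds the two-way map between 1-based alignment column indices and
#' 1-based ungapped residue numbers for one row, so that candidate sites can
#' be reported in the query sequence's own numbering.
#'
#' @param ga A [grouped_alignment()].
#' @param seq_id Row to map; defaults to the reference sequence.
#' @return An object of class `column_map`: list with `col_to_res` (integer
#'   vector of length `ga$width`, `NA` at gap columns) and `res_to_col`
#'   (integer vector of length = ungapped sequence length).
#' @examples
#' ga <- grouped_alignment(c("a", "b"), c("AC-E", "ACDE"),
#'                         c("query", "other"), "a")
#' cm <- build_column_map(ga, "a")
#' cm$col_to_res  # 1 2 NA 3
#' @export
build_column_map <- function(ga, seq_id = ga$reference_id) {
  stopifnot(inherits(ga, "grouped_alignment"))
  if (is.null(seq_id) || !seq_id %in% ga$ids) {
    stop("unknown seq_id '", seq_id, "'", call. = FALSE)
  }
  cc <- chars(ga$aligned[[seq_id]])
  nongap <- cc != GAP
  col_to_res <- rep(NA_integer_, length(cc))
  col_to_res[nongap] <- seq_len(sum(nongap))
  res_to_col <- which(nongap)
  structure(list(seq_id = seq_id, col_to_res = col_to_res,
                 res_to_col = res_to_col),
            class = "column_map")
}

#' Write candidate sites to a tab-separated file
#'
#' @param sites Candidate site data frame as returned by [scan_candidates()]
#'   (columns `ref_position`, `categories`, `query_residue`,
#'   `delta12_consensus`, `omega3_consensus`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_candidates()]
#' @export
write_candidates <- function(sites, path) {
  cols <- c("ref_position", "categories", "query_residue",
            "delta12_consensus", "omega3_consensus")
  stopifnot(is.data.frame(sites), all(cols %in% names(sites)))
  out <- sites[order(sites$ref_position), cols, drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Read candidate sites written by [write_candidates()]
#' @param path Path to the TSV.
#' @return Candidate site data frame.
#' @export
read_candidates <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE, na.strings = ".",
                    colClasses = c(ref_position = "integer",
                                   categories = "character",
                                   query_residue = "character",
                                   delta12_consensus = "character",
                                   omega3_consensus = "character"))
  out
}
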