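# Substitution planning, near-adjacent site merging, and variant stacking.
#
# The planning rule mirrors the comparative-mutagenesis logic: when one
# functional group is conserved at a residue that differs from the query,
# the query is mutated to that group's consensus; when the conserved residue
# is shared with the query, the query is mutated to the equivalent residue
# of a named representative of the other group (e.g. AtFAD2 for delta12,
# AtFAD3 for omega3).

#' Construct a point mutation
#'
#' @param wild_type Single wild-type residue letter.
#' @param position 1-based residue position in the reference sequence.
#' @param substitute Single replacement residue letter; must differ from
#'   `wild_type`.
#' @return Object of class `mutation` with fields `wild_type`, `position`,
#'   `substitute` and canonical name (e.g. `"F157W"`).
#' @export
mutation <- function(wild_type, position, substitute) {
  wild_type <- toupper(wild_type)
  substitute <- toupper(substitute)
  stopifnot(nchar(wild_type) == 1, nchar(substitute) == 1)
  position <- as.integer(position)
  if (!wild_type %in% AA_STANDARD || !substitute %in% AA_STANDARD) {
    stop("residues must be standard one-letter amino acid codes",
         call. = FALSE)
  }
  if (is.na(position) || position < 1) {
    stop("position must be a positive integer", call. = FALSE)
  }
  if (wild_type == substitute) {
    stop("synonymous change ", wild_type, position, substitute,
         " is not a mutation", call. = FALSE)
  }
  structure(list(wild_type = wild_type, position = position,
                 substitute = substitute),
            class = "mutation")
}

#' Canonical name of a mutation
#' @param m A [mutation()].
#' @return Character scalar such as `"F157W"`.
#' @export
mutation_name <- function(m) {
  stopifnot(inherits(m, "mutation"))
  paste0(m$wild_type, m$position, m$substitute)
}

#' @export
print.mutation <- function(x, ...) {
  cat(mutation_name(x), "\n")
  invisible(x)
}

#' Parse a canonical mutation name
#' @param name String such as `"F157W"`.
#' @return A [mutation()].
#' @export
parse_mutation <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", name))[[1]]
  if (length(m) != 4) {
    stop("cannot parse mutation name '", name,
         "' (expected e.g. \"F157W\")", call. = FALSE)
  }
  mutation(m[2], as.integer(m[3]), m[4])
}

#' Stack mutations into a multi-site variant
#'
#' @param mutations A list of [mutation()] objects, or a character vector of
#'   canonical names (also accepts one `/`-joined string).
#' @return Object of class `variant`: mutations ordered by ascending
#'   position, named by joining the mutation names with `/`
#'   (e.g. `"K36R/L153R/F157H"`).
#' @examples
#' variant_name(stack_mutations(c("F157H", "L153R", "K36R")))
#' @export
stack_mutations <- function(mutations) {
  if (is.character(mutations)) {
    mutations <- unlist(strsplit(mutations, "/", fixed = TRUE))
    mutations <- lapply(mutations, parse_mutation)
  }
  stopifnot(length(mutations) >= 0,
            all(vapply(mutations, inherits, logical(1), "mutation")))
  pos <- vapply(mutations, function(m) m$position, integer(1))
  if (anyDuplicated(pos)) {
    stop("duplicate position(s) in variant: ",
         paste(unique(pos[duplicated(pos)]), collapse = ", "), call. = FALSE)
  }
  structure(list(mutations = mutations[order(pos)]), class = "variant")
}

#' Parse a `/`-joined variant name
#' @param name String such as `"K36R/L153R/F157H"`.
#' @return A `variant`.
#' @export
parse_variant <- function(name) stack_mutations(name)

#' Canonical name of a variant
#' @param v A `variant`.
#' @return Mutation names joined with `/` in ascending-position order.
#' @export
variant_name <- function(v) {
  stopifnot(inherits(v, "variant"))
  paste(vapply(v$mutations, mutation_name, character(1)), collapse = "/")
}

#' @export
print.variant <- function(x, ...) {
  cat("variant:", if (length(x$mutations) == 0) "<identity>"
      else variant_name(x), "\n")
  invisible(x)
}

#' Plan the substitution for one candidate site
#'
#' Applies the group-comparison substitution rule. Category 2 or 4 (one
#' group conserved, query differs): mutate the query to that group's
#' consensus. Category 1 or 3 (conservation shared with the query): mutate
#' the query to the equivalent residue of a single named representative of
#' the opposite group. When a site carries several category flags, the
#' "other group's consensus" rules (4, then 2) take precedence over the
#' representative rules (3, then 1); pass `category` to override.
#'
#' @param site One row of the data frame returned by [scan_candidates()].
#' @param ga The [grouped_alignment()] the site came from (supplies the
#'   representative sequences' residues at the site's column).
#' @param donor_delta12,donor_omega3 Row ids of the representative sequences
#'   used as substitution donors for the shared-consensus categories.
#' @param category Optional category (1-4) to plan under; defaults to the
#'   highest-precedence flag carried by the site.
#' @return A [mutation()].
#' @export
plan_substitution <- function(site, ga, donor_delta12, donor_omega3,
                              category = NULL) {
  stopifnot(is.data.frame(site), nrow(site) == 1,
            inherits(ga, "grouped_alignment"))
  cats <- as.integer(strsplit(site$categories, ",", fixed = TRUE)[[1]])
  if (is.null(category)) {
    category <- c(4L, 2L, 3L, 1L)[match(TRUE, c(4L, 2L, 3L, 1L) %in% cats)]
    if (is.na(category)) stop("site carries no category flag", call. = FALSE)
  } else if (!category %in% cats) {
    stop("site at position ", site$ref_position, " does not carry category ",
         category, call. = FALSE)
  }
  donor_residue <- function(donor_id) {
    if (!donor_id %in% ga$ids) {
      stop("donor sequence '", donor_id, "' not in alignment", call. = FALSE)
    }
    r <- substr(ga$aligned[[donor_id]], site$column, site$column)
    if (r == GAP) {
      stop("planning error at position ", site$ref_position, ": donor '",
           donor_id, "' has a gap at alignment column ", site$column,
           call. = FALSE)
    }
    r
  }
  sub <- switch(as.character(category),
                "2" = site$delta12_consensus,
                "4" = site$omega3_consensus,
                "1" = donor_residue(donor_omega3),
                "3" = donor_residue(donor_delta12))
  if (is.na(sub)) {
    stop("planning error at position ", site$ref_position,
         ": required consensus is absent", call. = FALSE)
  }
  if (sub == site$query_residue) {
    stop("planning error at position ", site$ref_position,
         ": planned substitute equals the wild-type residue (", sub, ")",
         call. = FALSE)
  }
  mutation(site$query_residue, site$ref_position, sub)
}

#' Plan substitutions for a whole candidate list
#'
#' Runs [plan_substitution()] over every row of a candidate table, merging
#' near-adjacent sites into mutagenesis units via [merge_adjacent()]. Sites
#' that cannot be planned (donor gap, absent consensus) are reported in the
#' `note` column with `substitute = NA`, never silently dropped.
#'
#' @inheritParams plan_substitution
#' @param candidates Data frame from [scan_candidates()].
#' @param merge_window Residue distance within which consecutive sites share
#'   one mutagenesis unit (default 3).
#' @return Data frame: `ref_position`, `wild_type`, `substitute`, `name`,
#'   `category_used`, `unit`, `note`.
#' @export
plan_candidates <- function(candidates, ga, donor_delta12, donor_omega3,
                            merge_window = 3) {
  stopifnot(is.data.frame(candidates))
  units <- merge_adjacent(candidates$ref_position, merge_window)
  out <- lapply(seq_len(nrow(candidates)), function(i) {
    site <- candidates[i, , drop = FALSE]
    cats <- as.integer(strsplit(site$categories, ",", fixed = TRUE)[[1]])
    used <- c(4L, 2L, 3L, 1L)[match(TRUE, c(4L, 2L, 3L, 1L) %in% cats)]
    res <- tryCatch(plan_substitution(site, ga, donor_delta12, donor_omega3),
                    error = function(e) conditionMessage(e))
    if (inherits(res, "mutation")) {
      data.frame(ref_position = site$ref_position, wild_type = res$wild_type,
                 substitute = res$substitute, name = mutation_name(res),
                 category_used = used, note = "", stringsAsFactors = FALSE)
    } else {
      data.frame(ref_position = site$ref_position,
                 wild_type = site$query_residue, substitute = NA_character_,
                 name = NA_character_, category_used = used, note = res,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  out$unit <- units$unit[match(out$ref_position, units$position)]
  rownames(out) <- NULL
  out[, c("ref_position", "wild_type", "substitute", "name",
          "category_used", "unit", "note")]
}

#' Merge near-adjacent positions into mutagenesis units
#'
#' Greedy left-to-right grouping: a position joins the current unit when it
#' lies within `window` residues of the previous position, otherwise it
#' starts a new unit. Sites merged into one unit are intended to be mutated
#' together in a single construct.
#'
#' @param positions Integer vector of residue positions (sorted ascending;
#'   unsorted input is sorted with a warning).
#' @param window Maximum residue gap between consecutive members of a unit
#'   (default 3).
#' @return Data frame with `position` and `unit` (1-based unit index);
#'   every input position appears in exactly one unit.
#' @examples
#' merge_adjacent(c(206, 207, 208), 3)  # one unit
#' merge_adjacent(c(36, 97), 3)         # two units
#' @export
merge_adjacent <- function(positions, window = 3) {
  positions <- as.integer(positions)
  if (is.unsorted(positions)) {
    warning("positions were not sorted; sorting ascending")
    positions <- sort(positions)
  }
  if (length(positions) == 0) {
    return(data.frame(position = integer(0), unit = integer(0)))
  }
  unit <- cumsum(c(1L, as.integer(diff(positions) > window)))
  data.frame(position = positions, unit = unit)
}

#' Apply a variant to a protein sequence
#'
#' @param residues Protein string.
#' @param v A `variant` (or anything [stack_mutations()] accepts).
#' @return The mutated protein string; differs from the input at exactly the
#'   variant's positions.
#' @export
apply_variant <- function(residues, v) {
  if (!inherits(v, "variant")) v <- stack_mutations(v)
  cc <- chars(toupper(residues))
  for (m in v$mutations) {
    if (m$position > length(cc)) {
      stop("position ", m$position, " beyond sequence length ", length(cc),
           call. = FALSE)
    }
    if (cc[m$position] != m$wild_type) {
      stop("wild-type mismatch at position ", m$position, ": expected ",
           m$wild_type, ", observed ", cc[m$position], call. = FALSE)
    }
    cc[m$position] <- m$substitute
  }
  paste(cc, collapse = "")
}

#' Reverse a variant (swap wild-type and substitute at every site)
#' @param v A `variant`.
#' @return The reversing `variant`; applying a variant and then its reverse
#'   restores the original sequence.
#' @export
reverse_variant <- function(v) {
  stopifnot(inherits(v, "variant"))
  stack_mutations(lapply(v$mutations, function(m) {
    mutation(m$substitute, m$position, m$wild_type)
  }))
}
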