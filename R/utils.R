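# shared low-level helpers

AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALLOWED <- c(AA_STANDARD, "X")
GAP <- "-"

VALID_GROUPS <- c("delta12", "omega3", "query", "other")

#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' @noRd
degap <- function(x) gsub("-", "", x, fixed = TRUE)

# Normalize a raw aligned/ungapped string: upper case, '.' -> '-'.
# Rejects ambiguity codes other than X so miscounts fail loudly.
#' @noRd
normalize_residues <- function(x, id = "<sequence>", allow_gap = TRUE) {
  x <- toupper(x)
  if (grepl(".", x, fixed = TRUE)) {
    message("Note: '.' gap characters in '", id, "' normalized to '-'")
    x <- gsub(".", "-", x, fixed = TRUE)
  }
  ok <- AA_ALLOWED
  if (allow_gap) ok <- c(ok, GAP)
  bad <- setdiff(unique(chars(x)), ok)
  if (length(bad) > 0) {
    stop("sequence '", id, "' contains unsupported residue code(s): ",
         paste(bad, collapse = ", "),
         " (only the 20 standard amino acids plus X are accepted)",
         call. = FALSE)
  }
  x
}

#' @noRd
check_group_labels <- function(groups) {
  bad <- setdiff(unique(groups), VALID_GROUPS)
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(VALID_GROUPS, collapse = ", "),
         call. = FALSE)
  }
  invisible(groups)
}
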