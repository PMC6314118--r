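# Histidine-box motif detection and di-iron coordination-shell analysis.
#
# Membrane desaturases ligate their catalytic di-iron centre through
# histidines arranged in conserved boxes (HxxxH, HxxHH). Shell analysis
# reports every residue with at least one atom within a radius of any
# selected metal atom of a structural model; distance is measured to ANY
# atom of the residue (the inclusive reading of a "within r angstrom"
# criterion), not to the C-beta or the centroid.

METAL_ELEMENTS <- c("FE", "ZN", "MN", "CU")

#' Find histidine-box motifs in a protein sequence
#'
#' Reports every occurrence of the two iron-ligating box motifs: `HxxxH`
#' (His, three non-His, His) and `HxxHH` (His, two non-His, His, His).
#' Interior `x` positions are required to be non-His so the two motifs stay
#' disjoint and an `HxxHH` box is not double-counted as `HxxxH`. Overlapping
#' occurrences are all reported.
#'
#' @param residues Protein string (one-letter upper-case).
#' @return Data frame with `motif`, `start` (1-based), and `his_positions`
#'   (comma-joined residue numbers of the histidines the box contributes),
#'   sorted by `start`.
#' @examples
#' find_his_boxes("AHAAAHA")  # HxxxH at 2
#' find_his_boxes("HAAHH")    # HxxHH at 1
#' @export
find_his_boxes <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1,
            nchar(residues) > 0)
  residues <- toupper(residues)
  hits <- list()
  scan_motif <- function(pattern, motif, his_offsets) {
    m <- gregexpr(pattern, residues, perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0])
    lapply(starts, function(s) {
      data.frame(motif = motif, start = s,
                 his_positions = paste(s + his_offsets, collapse = ","),
                 stringsAsFactors = FALSE)
    })
  }
  hits <- c(scan_motif("(?=H[^H]{3}H)", "HxxxH", c(0L, 4L)),
            scan_motif("(?=H[^H]{2}HH)", "HxxHH", c(0L, 3L, 4L)))
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(motif = character(0), start = integer(0),
                      his_positions = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histidine residue numbers contributed by a set of boxes
#' @param boxes Data frame from [find_his_boxes()].
#' @param extra Additional ligand histidine positions to include (membrane
#'   desaturases carry one ligand His outside the boxes, e.g. His295 of Fm1).
#' @return Sorted unique integer vector.
#' @export
his_box_positions <- function(boxes, extra = integer(0)) {
  pos <- unlist(lapply(strsplit(boxes$his_positions, ","), as.integer))
  sort(unique(c(pos, as.integer(extra))))
}

#' Read a PDB-format structure model
#'
#' Parses ATOM/HETATM records (via bio3d), keeps the highest-occupancy
#' alternate conformer per atom, and flags metal atoms by element symbol
#' (FE, ZN, MN, CU by default).
#'
#' @param path Path to a PDB-format file.
#' @param metal_elements Element symbols treated as catalytic metals.
#' @return An object of class `structure_model`: list with `atoms` (data
#'   frame: `chain`, `resno`, `insert`, `resid`, `elety`, `elesy`, `x`, `y`,
#'   `z`, `o`, `is_metal`) and `path`.
#' @export
read_structure <- function(path, metal_elements = METAL_ELEMENTS) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop("failed to parse PDB file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("no ATOM/HETATM records in '", path, "'", call. = FALSE)
  }
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))[1]
    stop("malformed coordinates at atom record ", bad, " of '", path, "'",
         call. = FALSE)
  }
  # highest-occupancy alternate conformer only
  if (!all(is.na(at$alt)) && any(at$alt != "", na.rm = TRUE)) {
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  elesy <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                 substr(trimws(at$elety), 1, 2), at$elesy)))
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    elesy = elesy,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  atoms$is_metal <- atoms$elesy %in% toupper(metal_elements) |
    atoms$resid %in% toupper(metal_elements)
  structure(list(atoms = atoms, path = path), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model: ", nrow(x$atoms), " atoms, ",
      sum(x$atoms$is_metal), " metal atom(s)\n", sep = "")
  invisible(x)
}

#' Write a structure model in PDB format
#'
#' Fixed-column ATOM/HETATM writer (coordinates at 3 decimals, the PDB
#' field precision). Metal atoms are written as HETATM records.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  writeLines(pdb_lines(model$atoms), path)
  invisible(path)
}

#' @noRd
pdb_lines <- function(atoms) {
  n <- nrow(atoms)
  rec <- ifelse(atoms$is_metal, "HETATM", "ATOM  ")
  elety <- atoms$elety
  # PDB convention: atom names of <4 chars start in column 14
  name_field <- ifelse(nchar(elety) >= 4, substr(elety, 1, 4),
                       sprintf(" %-3s", elety))
  c(sprintf("%s%5d %s %-3s %s%4d%-1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, seq_len(n), name_field, atoms$resid, atoms$chain,
            atoms$resno, atoms$insert, atoms$x, atoms$y, atoms$z,
            atoms$o, 0, atoms$elesy),
    "END")
}

#' Residues within a radius shell of the catalytic metal atoms
#'
#' For every residue with at least one atom within `radius` angstrom
#' (Euclidean) of at least one selected metal atom, reports the minimum
#' atom-to-metal distance. Histidines belonging to detected His boxes (or a
#' user-supplied ligand list) are flagged so that "all shell residues apart
#' from the conserved ligand histidines" is a single filter away.
#'
#' @param model A `structure_model` from [read_structure()].
#' @param radius Shell radius in angstrom (default 5).
#' @param metal_selection Optional logical/integer index into `model$atoms`
#'   selecting the metal atoms; defaults to the auto-flagged metals.
#' @param ligand_his Integer vector of residue numbers to flag as metal
#'   ligand histidines (e.g. `his_box_positions(find_his_boxes(seq), 295)`).
#' @return Data frame sorted by ascending `min_distance`: `chain`, `resno`,
#'   `insert`, `resid`, `min_distance`, `is_metal_ligand_his`.
#' @export
shell_residues <- function(model, radius = 5, metal_selection = NULL,
                           ligand_his = integer(0)) {
  stopifnot(inherits(model, "structure_model"), is.numeric(radius),
            radius > 0)
  at <- model$atoms
  if (is.null(metal_selection)) {
    metal_idx <- which(at$is_metal)
  } else {
    metal_idx <- seq_len(nrow(at))[metal_selection]
  }
  if (length(metal_idx) == 0) {
    stop("no metal atoms selected for shell analysis", call. = FALSE)
  }
  metals <- as.matrix(at[metal_idx, c("x", "y", "z")])
  others <- at[-metal_idx, , drop = FALSE]
  if (nrow(others) == 0) {
    return(empty_shell_df())
  }
  xyz <- as.matrix(others[, c("x", "y", "z")])
  # per-atom min distance over all metals
  d2min <- rep(Inf, nrow(xyz))
  for (m in seq_len(nrow(metals))) {
    d2 <- (xyz[, 1] - metals[m, 1])^2 + (xyz[, 2] - metals[m, 2])^2 +
      (xyz[, 3] - metals[m, 3])^2
    d2min <- pmin(d2min, d2)
  }
  dmin <- sqrt(d2min)
  key <- paste(others$chain, others$resno, others$insert, sep = "|")
  res_min <- tapply(dmin, key, min)
  first <- !duplicated(key)
  info <- others[first, c("chain", "resno", "insert", "resid"), drop = FALSE]
  info$min_distance <- as.numeric(res_min[paste(info$chain, info$resno,
                                                info$insert, sep = "|")])
  info <- info[info$min_distance <= radius, , drop = FALSE]
  if (nrow(info) == 0) return(empty_shell_df())
  info$is_metal_ligand_his <- info$resno %in% ligand_his &
    toupper(info$resid) %in% c("HIS", "H")
  info <- info[order(info$min_distance), , drop = FALSE]
  rownames(info) <- NULL
  info
}

#' @noRd
empty_shell_df <- function() {
  data.frame(chain = character(0), resno = integer(0), insert = character(0),
             resid = character(0), min_distance = numeric(0),
             is_metal_ligand_his = logical(0), stringsAsFactors = FALSE)
}

#' Map model residue numbering onto a reference sequence
#'
#' Model coordinates often carry author numbering that is shifted relative to
#' the full-length sequence. This detects (or verifies) a constant offset
#' such that `sequence position = model resno + offset`, and reports the
#' residue-identity mismatches under that offset.
#'
#' @param model A `structure_model`.
#' @param residues Reference protein string (one-letter).
#' @param offset Integer offset, or `NULL` to detect the offset that
#'   maximizes residue-identity matches.
#' @param max_mismatch_frac Error out when more than this fraction of mapped
#'   residues mismatch (default 0.05), advising the user to renumber.
#' @return List with `offset`, `n_mapped`, `mismatches` (data frame:
#'   `resno`, `model_residue`, `sequence_residue`).
#' @export
map_model_to_sequence <- function(model, residues, offset = NULL,
                                  max_mismatch_frac = 0.05) {
  stopifnot(inherits(model, "structure_model"))
  residues <- toupper(residues)
  seq_chars <- chars(residues)
  at <- model$atoms[!model$atoms$is_metal, , drop = FALSE]
  first <- !duplicated(paste(at$chain, at$resno, at$insert))
  res <- at[first, c("resno", "resid"), drop = FALSE]
  one <- suppressWarnings(bio3d::aa321(res$resid))
  known <- !is.na(one) & one != "X" | res$resid %in% c("UNK")
  res$letter <- one
  res <- res[!is.na(res$letter), , drop = FALSE]
  score_offset <- function(d) {
    pos <- res$resno + d
    ok <- pos >= 1 & pos <= length(seq_chars)
    if (!any(ok)) return(-1)
    sum(res$letter[ok] == seq_chars[pos[ok]])
  }
  if (is.null(offset)) {
    cand <- seq(1 - max(res$resno), length(seq_chars) - min(res$resno))
    scores <- vapply(cand, score_offset, numeric(1))
    offset <- cand[which.max(scores)]
  }
  pos <- res$resno + offset
  ok <- pos >= 1 & pos <= length(seq_chars)
  mapped <- res[ok, , drop = FALSE]
  seq_res <- seq_chars[pos[ok]]
  mism <- mapped$letter != seq_res
  mismatches <- data.frame(resno = mapped$resno[mism],
                           model_residue = mapped$letter[mism],
                           sequence_residue = seq_res[mism],
                           stringsAsFactors = FALSE)
  if (nrow(mapped) == 0 ||
      nrow(mismatches) / nrow(mapped) > max_mismatch_frac) {
    stop("model-to-sequence mapping failed: ", nrow(mismatches), " of ",
         nrow(mapped), " mapped residues mismatch at offset ", offset,
         "; renumber the model or supply the correct offset", call. = FALSE)
  }
  list(offset = offset, n_mapped = nrow(mapped), mismatches = mismatches)
}
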