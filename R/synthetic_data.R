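# Ground-truth simulators: grouped alignments with planted signal columns,
# toy metal-site structures, and GC-FAME peak tables. Every generator is
# deterministic under its seed, so the whole pipeline is testable offline
# against known truth.

# run `expr` under a temporary RNG seed, restoring global RNG state after
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default planted-site layout for a simulated family
#'
#' Spreads `n` planted specificity sites evenly over the four Venn
#' categories and assigns consistent residues: the conserved group's residue
#' (equal to the planted query residue for categories 1 and 3, different for
#' 2 and 4) and two distinct residues cycled through the non-conserved
#' group, all drawn so no accidental consensus or accidental agreement with
#' the query can arise.
#'
#' @param n Number of planted sites (default 12).
#' @param width Alignment width the columns are drawn from.
#' @param seed Integer seed.
#' @return Data frame with `column`, `category`, `delta12_residues`,
#'   `omega3_residues` (comma-joined pools; a single residue means the group
#'   is conserved there), `query_residue`.
#' @export
plant_default_sites <- function(n = 12, width = 400, seed = 1) {
  if (n == 0) {
    return(data.frame(column = integer(0), category = integer(0),
                      delta12_residues = character(0),
                      omega3_residues = character(0),
                      query_residue = character(0), stringsAsFactors = FALSE))
  }
  with_local_seed(seed, {
    columns <- sort(sample.int(width, n))
    category <- rep(1:4, length.out = n)
    rows <- lapply(seq_len(n), function(i) {
      aa <- sample(AA_STANDARD)
      q <- aa[1]
      other <- aa[-1]
      if (category[i] == 1) {        # delta conserved = query
        d <- q; w <- other[1:2]
      } else if (category[i] == 2) { # delta conserved != query
        d <- other[1]; w <- other[2:3]
      } else if (category[i] == 3) { # omega conserved = query
        w <- q; d <- other[1:2]
      } else {                       # omega conserved != query
        w <- other[1]; d <- other[2:3]
      }
      data.frame(column = columns[i], category = category[i],
                 delta12_residues = paste(d, collapse = ","),
                 omega3_residues = paste(w, collapse = ","),
                 query_residue = q, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' @noRd
validate_planted <- function(planted) {
  need <- c("column", "category", "delta12_residues", "omega3_residues",
            "query_residue")
  stopifnot(is.data.frame(planted), all(need %in% names(planted)))
  if (anyDuplicated(planted$column)) {
    stop("planted columns must be distinct", call. = FALSE)
  }
  for (i in seq_len(nrow(planted))) {
    d <- strsplit(planted$delta12_residues[i], ",")[[1]]
    w <- strsplit(planted$omega3_residues[i], ",")[[1]]
    q <- planted$query_residue[i]
    cat <- planted$category[i]
    conserved <- if (cat %in% 1:2) d else w
    varied <- if (cat %in% 1:2) w else d
    if (length(conserved) != 1) {
      stop("planted site at column ", planted$column[i],
           ": the conserved group needs exactly one residue", call. = FALSE)
    }
    if (length(unique(varied)) < 2) {
      stop("planted site at column ", planted$column[i],
           ": the non-conserved group needs >= 2 distinct residues",
           call. = FALSE)
    }
    if (cat %in% c(1, 3) && conserved != q) {
      stop("planted site at column ", planted$column[i], ": category ", cat,
           " requires the consensus to equal the query residue",
           call. = FALSE)
    }
    if (cat %in% c(2, 4) && conserved == q) {
      stop("planted site at column ", planted$column[i], ": category ", cat,
           " requires the consensus to differ from the query residue",
           call. = FALSE)
    }
    if (conserved %in% varied) {
      stop("planted site at column ", planted$column[i],
           ": non-conserved pool may not contain the consensus residue",
           call. = FALSE)
    }
  }
  invisible(planted)
}

#' Simulate a grouped family alignment with planted signal columns
#'
#' Background columns draw each group's residues from disjoint two-residue
#' pools, cycled so that each group shows at least two distinct residues —
#' the maximum within-group frequency is 0.5, below any valid consensus
#' threshold, so background columns can never be called. Planted columns
#' are unanimous in their conserved group exactly per their category's
#' definition. Optional gap columns in the query row exercise the
#' column-to-residue renumbering; a small indel rate adds gaps to group
#' rows (never the query, never planted columns) within the tolerated gap
#' fraction.
#'
#' @param n_delta12,n_omega3 Sequences per functional group (default 4
#'   each; at least 2 so non-consensus can be planted).
#' @param width Alignment width in columns (default 400).
#' @param planted Planted-site layout as from [plant_default_sites()]; pass
#'   a zero-row data frame for a pure background family.
#' @param n_query_gaps Number of background columns where the query row
#'   carries a gap (default 10).
#' @param indel_rate Per-cell gap probability in group rows at background
#'   columns, at most one gap per group per column (default 0.02).
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return List with `alignment` (a [grouped_alignment()]; rows `d1..`,
#'   `w1..`, `query1`) and `truth` (list: `planted` augmented with the
#'   expected `ref_position`, consensus fields and expected substitution
#'   under the first-row donor policy; `sequences`, the ungapped residue
#'   strings; `donor_delta12`, `donor_omega3`).
#' @export
simulate_family <- function(n_delta12 = 4, n_omega3 = 4, width = 400,
                            planted = plant_default_sites(12, width, seed),
                            n_query_gaps = 10, indel_rate = 0.02, seed = 1) {
  stopifnot(n_delta12 >= 2, n_omega3 >= 2, width >= 1)
  validate_planted(planted)
  if (nrow(planted) > 0 && max(planted$column) > width) {
    stop("planted column beyond alignment width", call. = FALSE)
  }
  ids <- c(paste0("d", seq_len(n_delta12)), paste0("w", seq_len(n_omega3)),
           "query1")
  groups <- c(rep("delta12", n_delta12), rep("omega3", n_omega3), "query")
  with_local_seed(seed, {
    mat <- matrix("", nrow = length(ids), ncol = width,
                  dimnames = list(ids, NULL))
    background <- setdiff(seq_len(width), planted$column)
    for (j in background) {
      pools <- sample(AA_STANDARD, 5)
      mat[seq_len(n_delta12), j] <- rep(pools[1:2], length.out = n_delta12)
      mat[n_delta12 + seq_len(n_omega3), j] <-
        rep(pools[3:4], length.out = n_omega3)
      mat["query1", j] <- pools[5]
    }
    for (i in seq_len(nrow(planted))) {
      j <- planted$column[i]
      d <- strsplit(planted$delta12_residues[i], ",")[[1]]
      w <- strsplit(planted$omega3_residues[i], ",")[[1]]
      mat[seq_len(n_delta12), j] <- rep(d, length.out = n_delta12)
      mat[n_delta12 + seq_len(n_omega3), j] <- rep(w, length.out = n_omega3)
      mat["query1", j] <- planted$query_residue[i]
    }
    # query gaps: background columns only, so planted positions stay callable
    gap_cols <- if (n_query_gaps > 0)
      sort(sample(background, min(n_query_gaps, length(background))))
    else integer(0)
    mat["query1", gap_cols] <- GAP
    # indels in group rows: at most one gap per group per column
    if (indel_rate > 0) {
      for (j in background) {
        if (runif(1) < indel_rate * n_delta12) {
          mat[sample.int(n_delta12, 1), j] <- GAP
        }
        if (runif(1) < indel_rate * n_omega3) {
          mat[n_delta12 + sample.int(n_omega3, 1), j] <- GAP
        }
      }
    }
    aligned <- apply(mat, 1, paste, collapse = "")
    ga <- grouped_alignment(ids = ids, aligned = unname(aligned),
                            groups = groups, reference_id = "query1")
    cm <- build_column_map(ga, "query1")
    donor_delta12 <- ids[1]
    donor_omega3 <- ids[n_delta12 + 1]
    truth <- planted
    if (nrow(truth) > 0) {
      truth$ref_position <- cm$col_to_res[truth$column]
      truth$delta12_consensus <- ifelse(
        truth$category %in% 1:2,
        truth$delta12_residues, NA_character_)
      truth$omega3_consensus <- ifelse(
        truth$category %in% 3:4,
        truth$omega3_residues, NA_character_)
      # expected substitution under the first-row donor policy
      truth$expected_substitute <- vapply(seq_len(nrow(truth)), function(i) {
        switch(as.character(truth$category[i]),
               "2" = truth$delta12_consensus[i],
               "4" = truth$omega3_consensus[i],
               "1" = substr(ga$aligned[[donor_omega3]], truth$column[i],
                            truth$column[i]),
               "3" = substr(ga$aligned[[donor_delta12]], truth$column[i],
                            truth$column[i]))
      }, character(1))
      truth$expected_name <- paste0(truth$query_residue, truth$ref_position,
                                    truth$expected_substitute)
    }
    list(alignment = ga,
         truth = list(planted = truth,
                      sequences = vapply(ga$aligned, degap, character(1)),
                      donor_delta12 = donor_delta12,
                      donor_omega3 = donor_omega3))
  })
}

#' Simulate a toy metal-site structure in PDB format
#'
#' Places one iron atom at the origin and one C-alpha atom per requested
#' residue at an exact Euclidean distance from it, along a supplied or
#' random direction — a minimal structure whose coordination shell is known
#' by construction.
#'
#' @param layout Data frame with `resid` (three-letter residue name),
#'   `resno` (unique residue numbers) and `distance` (angstrom, >= 0);
#'   optional columns `dx`, `dy`, `dz` give the placement direction
#'   (normalized internally), otherwise directions are drawn uniformly on
#'   the sphere.
#' @param metal Element symbol of the central metal (default `"FE"`).
#' @param seed Integer seed for random directions.
#' @param path Optional output path; when given the PDB text is written
#'   there.
#' @return A `structure_model` (as from [read_structure()]) with attribute
#'   `"pdb_text"` carrying the PDB-format lines.
#' @export
simulate_structure <- function(layout, metal = "FE", seed = 1, path = NULL) {
  stopifnot(is.data.frame(layout),
            all(c("resid", "resno", "distance") %in% names(layout) |
                  nrow(layout) == 0))
  if (nrow(layout) > 0) {
    if (anyDuplicated(layout$resno)) {
      stop("duplicate residue numbers in layout", call. = FALSE)
    }
    if (any(layout$distance < 0)) {
      stop("distances must be >= 0", call. = FALSE)
    }
  }
  with_local_seed(seed, {
    if (nrow(layout) > 0) {
      if (!all(c("dx", "dy", "dz") %in% names(layout))) {
        v <- matrix(rnorm(3 * nrow(layout)), ncol = 3)
        v <- v / sqrt(rowSums(v^2))
        layout$dx <- v[, 1]; layout$dy <- v[, 2]; layout$dz <- v[, 3]
      } else {
        nrm <- sqrt(layout$dx^2 + layout$dy^2 + layout$dz^2)
        layout$dx <- layout$dx / nrm
        layout$dy <- layout$dy / nrm
        layout$dz <- layout$dz / nrm
      }
    }
    atoms <- data.frame(
      chain = "A",
      resno = c(if (nrow(layout) > 0) layout$resno, 999L),
      insert = "",
      resid = c(if (nrow(layout) > 0) toupper(layout$resid), toupper(metal)),
      elety = c(rep("CA", nrow(layout)), toupper(metal)),
      elesy = c(rep("C", nrow(layout)), toupper(metal)),
      x = c(if (nrow(layout) > 0) layout$dx * layout$distance, 0),
      y = c(if (nrow(layout) > 0) layout$dy * layout$distance, 0),
      z = c(if (nrow(layout) > 0) layout$dz * layout$distance, 0),
      o = 1,
      stringsAsFactors = FALSE
    )
    atoms$is_metal <- atoms$elesy %in% METAL_ELEMENTS
    model <- structure(list(atoms = atoms, path = NA_character_),
                       class = "structure_model")
    txt <- pdb_lines(atoms)
    if (!is.null(path)) writeLines(txt, path)
    attr(model, "pdb_text") <- txt
    model
  })
}

#' Simulate GC-FAME peak tables from known yields
#'
#' Inverts the quantification model: for true yield y (micrograms per A600),
#' `area = y * A600 / ISTD mass * ISTD area`, multiplied by lognormal noise
#' `exp(N(0, sigma))`. Three replicates per sample by default; the internal
#' standard row receives independent noise of the same magnitude.
#'
#' @param truth Data frame with `sample_id`, `a600`, `species`, `yield`
#'   (micrograms per A600).
#' @param noise_sigma Log-scale multiplicative noise SD (default 0.05;
#'   0 gives exact inversion).
#' @param n_replicates Replicates per sample (default 3).
#' @param istd_mass Internal standard mass in micrograms (default 5).
#' @param istd_area Nominal internal-standard peak area (default 1e4).
#' @param seed Integer seed.
#' @return Named list of [peak_table()] objects, one per sample x replicate
#'   (`"<sample_id>_rep<k>"`).
#' @export
simulate_peaks <- function(truth, noise_sigma = 0.05, n_replicates = 3,
                           istd_mass = 5, istd_area = 1e4, seed = 1) {
  need <- c("sample_id", "a600", "species", "yield")
  stopifnot(is.data.frame(truth), all(need %in% names(truth)))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (any(truth$yield < 0)) stop("yields must be >= 0", call. = FALSE)
  with_local_seed(seed, {
    out <- list()
    for (sid in unique(truth$sample_id)) {
      d <- truth[truth$sample_id == sid, , drop = FALSE]
      for (k in seq_len(n_replicates)) {
        noise <- exp(rnorm(nrow(d) + 1, 0, noise_sigma))
        areas <- d$yield * d$a600[1] / istd_mass * istd_area *
          noise[seq_len(nrow(d))]
        rep_id <- paste0(sid, "_rep", k)
        out[[rep_id]] <- peak_table(
          sample_id = rep_id, a600 = d$a600[1],
          species = c(d$species, ISTD_SPECIES),
          area = c(areas, istd_area * noise[nrow(d) + 1]),
          istd_flag = c(rep(FALSE, nrow(d)), TRUE),
          istd_mass = istd_mass)
      }
    }
    out
  })
}

#' Average quantification over replicate peak tables
#'
#' @param tables List of [peak_table()] replicates of one biological sample.
#' @param ... Passed to [quantify()].
#' @return A `phenotype_result` whose yields are replicate means.
#' @export
quantify_replicates <- function(tables, ...) {
  results <- lapply(tables, quantify, ...)
  species <- unique(unlist(lapply(results, function(r) names(r$yields))))
  yields <- setNames(vapply(species, function(s) {
    mean(vapply(results, function(r)
      if (s %in% names(r$yields)) r$yields[[s]] else 0, numeric(1)))
  }, numeric(1)), species)
  pa <- mean(vapply(results, function(r) r$product_activity, numeric(1)))
  af_ala <- if (ALA %in% species) yields[[ALA]] else 0
  af_la <- if (LA %in% species) yields[[LA]] else 0
  af <- if (ALA %in% species || LA %in% species) ala_fraction(af_ala, af_la)
  else NA_real_
  structure(list(sample_id = sub("_rep[0-9]+$", "",
                                 results[[1]]$sample_id),
                 yields = yields, product_activity = pa, ala_fraction = af),
            class = "phenotype_result")
}

#' Demo phenotype dataset for the Fm1 narrative
#'
#' A small simulated GC-FAME experiment parameterized at the reported
#' phenotypes of Fm1 and three informative variants: the reference enzyme
#' with product ratio ALA/(ALA+LA) = 0.86; F157H at 2.5x the reference
#' activity and unchanged ratio; Y280L with ratio 0.4 and compromised
#' activity; the triple F157W/Y280L/L287T with ratio 0.06 and raised
#' activity; and an empty-vector control with no desaturation products.
#' This parameterization reproduces the narrative classifications, not the
#' wet-lab measurements themselves.
#'
#' @param seed Integer seed.
#' @param noise_sigma Multiplicative noise SD (default 0.05).
#' @return List with `truth` (yield table) and `tables`
#'   (replicate [peak_table()] list from [simulate_peaks()]).
#' @export
fm1_demo <- function(seed = 1, noise_sigma = 0.05) {
  sample_row <- function(id, total_product, ala_frac) {
    data.frame(sample_id = id, a600 = 2,
               species = c("16:0", "18:1Δ9", LA, ALA),
               yield = c(30, 20, total_product * (1 - ala_frac),
                         total_product * ala_frac),
               stringsAsFactors = FALSE)
  }
  truth <- rbind(
    sample_row("Fm1", 10, 0.86),
    sample_row("F157H", 25, 0.86),
    sample_row("Y280L", 6, 0.40),
    sample_row("F157W/Y280L/L287T", 18, 0.06),
    sample_row("EV", 0, 0)
  )
  list(truth = truth,
       tables = simulate_peaks(truth, noise_sigma = noise_sigma,
                               seed = seed))
}
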