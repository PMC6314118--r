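# GC-FAME phenotype quantification and regiochemistry inference.
#
# Activity is expressed as fatty acid yield in micrograms per A600 unit of
# cells, quantified against a 17:0 (heptadecanoate) internal standard of
# known mass. FAME response factors are assumed equal across species (area
# ratio = mass ratio) unless a per-species response-factor table is given.
# The product ratio ALA/(ALA+LA) measures the second (omega-3/v+3)
# desaturation relative to the first, since all ALA derives from a second
# desaturation of LA.

#' Parse or construct a fatty acid species
#'
#' Shorthand grammar: `<chain>:<n_bonds>` optionally followed by
#' `Δ<p1>,<p2>,...` giving the double-bond positions in carboxyl-end
#' (delta) numbering. An ASCII `d` or `D` is accepted in place of the Greek
#' delta. Positions must be strictly increasing and at most `chain - 1`; the
#' position count must equal `n_bonds`.
#'
#' @param x Shorthand string, e.g. `"18:2Δ9,12"` or `"17:0"`.
#' @return Object of class `fatty_acid`: list with `chain` (carbon count),
#'   `bonds` (sorted integer vector of delta positions) and `shorthand`.
#' @examples
#' fatty_acid("18:3Δ9,12,15")
#' fatty_acid("16:1d9")
#' @export
fatty_acid <- function(x) {
  if (inherits(x, "fatty_acid")) return(x)
  stopifnot(is.character(x), length(x) == 1)
  m <- regmatches(x, regexec("^([0-9]+):([0-9]+)(?:[ΔdD]([0-9,]+))?$",
                             x))[[1]]
  if (length(m) == 0) {
    stop("cannot parse fatty acid shorthand '", x, "'", call. = FALSE)
  }
  chain <- as.integer(m[2])
  n_bonds <- as.integer(m[3])
  bonds <- if (m[4] == "") integer(0) else as.integer(strsplit(m[4], ",")[[1]])
  if (length(bonds) != n_bonds) {
    stop("'", x, "': bond count ", n_bonds, " does not match ",
         length(bonds), " listed position(s)", call. = FALSE)
  }
  new_fatty_acid(chain, bonds, x)
}

#' @noRd
new_fatty_acid <- function(chain, bonds, label = NULL) {
  bonds <- as.integer(bonds)
  if (length(bonds) > 0) {
    if (is.unsorted(bonds, strictly = TRUE)) {
      stop("double-bond positions must be strictly increasing", call. = FALSE)
    }
    if (max(bonds) > chain - 1 || min(bonds) < 2) {
      stop("double-bond position outside 2..", chain - 1, call. = FALSE)
    }
  }
  shorthand <- paste0(chain, ":", length(bonds),
                      if (length(bonds) > 0)
                        paste0("Δ", paste(bonds, collapse = ",")))
  structure(list(chain = chain, bonds = bonds, shorthand = shorthand),
            class = "fatty_acid")
}

#' @export
print.fatty_acid <- function(x, ...) {
  cat(x$shorthand, "\n")
  invisible(x)
}

# canonical species used for the product-ratio metric
ALA <- "18:3Δ9,12,15"
LA <- "18:2Δ9,12"
ISTD_SPECIES <- "17:0"

#' Construct a GC-FAME peak table for one sample
#'
#' @param sample_id Sample identifier.
#' @param a600 Culture optical density at harvest (A600 units); must be > 0.
#' @param species Character vector of species shorthands (one entry must be
#'   the internal standard).
#' @param area Numeric vector of integrated peak areas (arbitrary units,
#'   all >= 0).
#' @param istd_flag Logical vector marking the internal-standard row
#'   (exactly one `TRUE`); defaults to `species == "17:0"`.
#' @param istd_mass Internal standard mass in micrograms (default 5).
#' @return Object of class `peak_table`.
#' @export
peak_table <- function(sample_id, a600, species, area,
                       istd_flag = species == ISTD_SPECIES, istd_mass = 5) {
  stopifnot(length(species) == length(area),
            length(istd_flag) == length(species))
  if (!is.numeric(a600) || length(a600) != 1 || is.na(a600) || a600 <= 0) {
    stop("A600 must be a single positive number", call. = FALSE)
  }
  if (any(area < 0)) stop("peak areas must be >= 0", call. = FALSE)
  if (sum(istd_flag) != 1) {
    stop("exactly one internal-standard row required, found ",
         sum(istd_flag), call. = FALSE)
  }
  structure(list(sample_id = sample_id, a600 = a600,
                 rows = data.frame(species = species, area = area,
                                   istd = istd_flag,
                                   stringsAsFactors = FALSE),
                 istd_mass = istd_mass),
            class = "peak_table")
}

#' Read peak tables from CSV
#'
#' Expects columns `sample_id`, `a600`, `species`, `area`, `istd_flag`
#' (0/1 or TRUE/FALSE). Returns one [peak_table()] per distinct sample.
#'
#' @param path CSV path.
#' @param istd_mass Internal standard mass in micrograms (default 5).
#' @return Named list of `peak_table` objects.
#' @export
read_peak_tables <- function(path, istd_mass = 5) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "a600", "species", "area", "istd_flag")
  if (!all(need %in% names(df))) {
    stop("peak CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(df, df$sample_id), function(d) {
    peak_table(d$sample_id[1], d$a600[1], d$species, d$area,
               as.logical(d$istd_flag), istd_mass)
  })
  out[unique(df$sample_id)]
}

#' Write peak tables to CSV
#' @param tables A list of [peak_table()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peak_tables <- function(tables, path) {
  if (inherits(tables, "peak_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, function(pt) {
    data.frame(sample_id = pt$sample_id, a600 = pt$a600,
               species = pt$rows$species, area = pt$rows$area,
               istd_flag = as.integer(pt$rows$istd),
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Quantify a peak table into per-species yields and product activity
#'
#' Yield of a species is `area(species) / area(ISTD) * ISTD mass / A600`,
#' in micrograms per A600 unit. Product activity sums the yields of the
#' species counted as enzymatic products — by default every species with at
#' least `product_min_bonds = 2` double bonds, i.e. everything downstream of
#' the first desaturation the enzyme performs.
#'
#' @param peaks A [peak_table()].
#' @param product_min_bonds Minimum double-bond count for a species to count
#'   toward product activity (default 2).
#' @param response_factors Optional named numeric vector of per-species
#'   response factors; the area of species `s` is divided by
#'   `response_factors[s]` before mass conversion (absent species default
#'   to 1).
#' @param ala_species,la_species Shorthands of the species entering the
#'   product ratio (defaults: ALA `18:3Δ9,12,15`, LA `18:2Δ9,12`).
#' @return Object of class `phenotype_result`: list with `sample_id`,
#'   `yields` (named numeric, micrograms per A600), `product_activity`,
#'   `ala_fraction` (`NA` when neither ratio species was recovered).
#' @export
quantify <- function(peaks, product_min_bonds = 2, response_factors = NULL,
                     ala_species = ALA, la_species = LA) {
  stopifnot(inherits(peaks, "peak_table"))
  rows <- peaks$rows
  istd_area <- rows$area[rows$istd]
  if (istd_area <= 0) {
    stop("internal-standard area is zero; cannot quantify sample '",
         peaks$sample_id, "'", call. = FALSE)
  }
  an <- rows[!rows$istd, , drop = FALSE]
  area <- an$area
  if (!is.null(response_factors)) {
    rf <- response_factors[an$species]
    rf[is.na(rf)] <- 1
    area <- area / rf
  }
  yields <- setNames(area / istd_area * peaks$istd_mass / peaks$a600,
                     an$species)
  n_bonds <- vapply(an$species,
                    function(s) length(fatty_acid(s)$bonds), integer(1))
  product_activity <- sum(yields[n_bonds >= product_min_bonds])
  ala_y <- if (ala_species %in% names(yields)) yields[[ala_species]] else 0
  la_y <- if (la_species %in% names(yields)) yields[[la_species]] else 0
  af <- if (ala_species %in% names(yields) || la_species %in% names(yields))
    ala_fraction(ala_y, la_y) else NA_real_
  structure(list(sample_id = peaks$sample_id, yields = yields,
                 product_activity = product_activity, ala_fraction = af),
            class = "phenotype_result")
}

#' @export
print.phenotype_result <- function(x, ...) {
  cat("phenotype_result [", x$sample_id, "]\n", sep = "")
  cat("  product activity: ", format(x$product_activity, digits = 4),
      " ug/A600\n", sep = "")
  cat("  ALA/(ALA+LA): ",
      if (is.na(x$ala_fraction)) "undefined"
      else format(x$ala_fraction, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Product ratio ALA/(ALA+LA)
#'
#' @param ala_yield,la_yield Non-negative yields of the trienoic (ALA) and
#'   dienoic (LA) product.
#' @return `ala / (ala + la)` in `[0, 1]`; `NA` (undefined, distinct from 0)
#'   when both yields are zero.
#' @examples
#' ala_fraction(86, 14)  # 0.86
#' @export
ala_fraction <- function(ala_yield, la_yield) {
  stopifnot(ala_yield >= 0, la_yield >= 0)
  if (ala_yield + la_yield == 0) return(NA_real_)
  ala_yield / (ala_yield + la_yield)
}

#' Activity of a sample relative to a reference
#' @param result,reference [quantify()] results; the reference must have
#'   positive product activity.
#' @return `result$product_activity / reference$product_activity`.
#' @export
relative_activity <- function(result, reference) {
  stopifnot(inherits(result, "phenotype_result"),
            inherits(reference, "phenotype_result"))
  if (reference$product_activity <= 0) {
    stop("reference product activity must be positive", call. = FALSE)
  }
  result$product_activity / reference$product_activity
}

#' Classify a variant phenotype against a reference
#'
#' @param result,reference [quantify()] results for the variant and the
#'   reference enzyme.
#' @param increased_threshold Relative activity above which a variant is
#'   labelled `increased_activity` (default 1.25, i.e. >125% of reference).
#' @param lof_floor Fraction of reference activity below which the variant
#'   is labelled `loss_of_function` (default 0.01).
#' @param ratio_margin Absolute change in ALA/(ALA+LA) beyond which the
#'   variant is labelled `ratio_shifted` (default 0.15).
#' @return Character vector, a subset of `{"increased_activity",
#'   "loss_of_function", "ratio_shifted"}` (possibly empty).
#' @export
classify_variant <- function(result, reference, increased_threshold = 1.25,
                             lof_floor = 0.01, ratio_margin = 0.15) {
  rel <- relative_activity(result, reference)
  labels <- character(0)
  if (rel > increased_threshold) labels <- c(labels, "increased_activity")
  if (result$product_activity <=
      lof_floor * reference$product_activity) {
    labels <- c(labels, "loss_of_function")
  }
  if (!is.na(result$ala_fraction) && !is.na(reference$ala_fraction) &&
      abs(result$ala_fraction - reference$ala_fraction) > ratio_margin) {
    labels <- c(labels, "ratio_shifted")
  }
  labels
}
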