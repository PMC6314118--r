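# Regiochemistry of desaturation: v+3 versus omega-3 counting.
#
# A delta-x desaturase inserts a double bond x carbons from the carboxyl
# end; an omega-x desaturase counts x carbons from the methyl end (delta
# position chain - x); a v+x desaturase counts x carbons toward the methyl
# end from an existing double bond. On an 18-carbon substrate with a
# delta-12 bond the two counting rules coincide (12 + 3 = 18 - 3 = 15), so
# only a chain length where they diverge — e.g. C16, where v+3 predicts
# delta-15 but omega-3 predicts delta-13 — can discriminate them.

#' Predict the product of one desaturation under a counting rule
#'
#' @param substrate A [fatty_acid()] (or shorthand string).
#' @param rule `"v_plus_3"` (new bond three carbons methyl-ward of the last
#'   existing bond) or `"omega3"` (new bond three carbons from the methyl
#'   end, i.e. delta position `chain - 3`).
#' @return The product [fatty_acid()] with one additional double bond.
#'   Infeasible predictions (position already occupied, or beyond
#'   `chain - 1`) raise an error of class `fadscan_infeasible`.
#' @examples
#' predict_product("18:1Δ9", "v_plus_3")$shorthand  # "18:2Δ9,12"
#' predict_product("16:2Δ9,12", "omega3")$shorthand # "16:3Δ9,12,13"
#' @export
predict_product <- function(substrate, rule = c("v_plus_3", "omega3")) {
  substrate <- fatty_acid(substrate)
  rule <- match.arg(rule)
  if (rule == "v_plus_3") {
    if (length(substrate$bonds) == 0) {
      stop("v+3 desaturation needs an existing double bond as reference",
           call. = FALSE)
    }
    new_pos <- max(substrate$bonds) + 3L
  } else {
    new_pos <- substrate$chain - 3L
  }
  if (new_pos %in% substrate$bonds || new_pos > substrate$chain - 1L) {
    stop(structure(class = c("fadscan_infeasible", "error", "condition"),
                   list(message = paste0("infeasible ", rule,
                                         " desaturation of ",
                                         substrate$shorthand,
                                         ": predicted position ", new_pos),
                        call = NULL)))
  }
  new_fatty_acid(substrate$chain, sort(c(substrate$bonds, new_pos)))
}

#' Infer the counting rule from an observed desaturation product
#'
#' Given a substrate and the observed single-desaturation product, compares
#' the observation against both the v+3 and the omega-3 prediction.
#'
#' @param substrate,observed_product [fatty_acid()] objects or shorthand
#'   strings; the product must equal the substrate plus exactly one new
#'   double bond.
#' @return One of `"v_plus_3"`, `"omega3"`, `"ambiguous"` (both rules
#'   predict the observation — exactly when the substrate's last bond sits
#'   at `chain - 6`), or `"none"` (neither rule predicts it).
#' @examples
#' infer_rule("16:2Δ9,12", "16:3Δ9,12,15")  # "v_plus_3"
#' infer_rule("18:2Δ9,12", "18:3Δ9,12,15")  # "ambiguous"
#' @export
infer_rule <- function(substrate, observed_product) {
  substrate <- fatty_acid(substrate)
  observed_product <- fatty_acid(observed_product)
  if (observed_product$chain != substrate$chain ||
      length(observed_product$bonds) != length(substrate$bonds) + 1 ||
      !all(substrate$bonds %in% observed_product$bonds)) {
    stop("product ", observed_product$shorthand,
         " is not a single-desaturation derivative of ",
         substrate$shorthand, call. = FALSE)
  }
  matches <- function(rule) {
    pred <- tryCatch(predict_product(substrate, rule),
                     fadscan_infeasible = function(e) NULL)
    !is.null(pred) && identical(pred$bonds, observed_product$bonds)
  }
  v3 <- matches("v_plus_3")
  w3 <- matches("omega3")
  if (v3 && w3) "ambiguous"
  else if (v3) "v_plus_3"
  else if (w3) "omega3"
  else "none"
}
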