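# Shared fixtures: tiny alignments and brute-force oracles kept deliberately
# independent of the implementation paths they check.

tiny_alignment <- function() {
  grouped_alignment(
    ids = c("d1", "d2", "w1", "w2", "q"),
    aligned = c("VAW-C", "VAWKC", "IGW-C", "IGWKC", "IAWKC"),
    groups = c("delta12", "delta12", "omega3", "omega3", "query"),
    reference_id = "q"
  )
}

# brute-force consensus: count non-gap frequencies with table(), no shortcuts
oracle_consensus <- function(residues, threshold) {
  obs <- residues[residues != "-"]
  if (length(obs) == 0) return(NA_character_)
  if (mean(residues == "-") > 0.25) return(NA_character_)
  for (r in unique(obs)) {
    if (sum(obs == r) / length(obs) >= threshold) return(r)
  }
  NA_character_
}

# brute-force all-pairs shell scan over raw atom records
oracle_shell <- function(atoms, radius) {
  metals <- atoms[atoms$is_metal, , drop = FALSE]
  rest <- atoms[!atoms$is_metal, , drop = FALSE]
  out <- list()
  for (rn in unique(rest$resno)) {
    sub <- rest[rest$resno == rn, , drop = FALSE]
    dmin <- Inf
    for (i in seq_len(nrow(sub))) {
      for (m in seq_len(nrow(metals))) {
        d <- sqrt((sub$x[i] - metals$x[m])^2 + (sub$y[i] - metals$y[m])^2 +
                    (sub$z[i] - metals$z[m])^2)
        dmin <- min(dmin, d)
      }
    }
    if (dmin <= radius) {
      out[[length(out) + 1]] <- data.frame(resno = rn, min_distance = dmin)
    }
  }
  if (length(out) == 0) {
    return(data.frame(resno = integer(0), min_distance = numeric(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$min_distance), , drop = FALSE]
}

random_structure <- function(n_res = 20, seed = 1) {
  set.seed(seed)
  layout <- data.frame(
    resid = sample(c("ALA", "PHE", "HIS", "LEU", "TRP"), n_res,
                   replace = TRUE),
    resno = seq_len(n_res),
    distance = runif(n_res, 0.5, 10)
  )
  simulate_structure(layout, seed = seed + 1000)
}
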