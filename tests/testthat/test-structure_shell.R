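test_that("find_his_boxes reports both motifs with overlaps", {
  b <- find_his_boxes("AHAAAHA")
  expect_equal(b$motif, "HxxxH")
  expect_equal(b$start, 2L)
  expect_equal(b$his_positions, "2,6")

  b <- find_his_boxes("HAAHH")
  expect_equal(b$motif, "HxxHH")  # not double-counted as HxxxH
  expect_equal(b$start, 1L)
  expect_equal(b$his_positions, "1,4,5")

  # overlapping occurrences are all reported
  b <- find_his_boxes("HAAAHAAAH")
  expect_equal(b$start, c(1L, 5L))
  expect_equal(nrow(find_his_boxes("AAAA")), 0)

  # combined positions, plus a supplied lone ligand His
  seqs <- "AHAAAHAAAAHAAHHAAA"
  pos <- his_box_positions(find_his_boxes(seqs), extra = 99)
  expect_equal(pos, c(2L, 6L, 11L, 14L, 15L, 99L))
})

test_that("read_structure parses toy files and flags metals", {
  lay <- data.frame(resid = c("PHE", "ILE"), resno = c(10, 20),
                    distance = c(3, 6))
  path <- withr::local_tempfile(fileext = ".pdb")
  simulate_structure(lay, seed = 4, path = path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(sum(m$atoms$is_metal), 1)
  expect_equal(m$atoms$resid[m$atoms$is_metal], "FE")
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")),
               "not found")
})

test_that("PDB round trip preserves coordinates to 3 decimals", {
  m <- random_structure(30, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(m$atoms))
  expect_lt(max(abs(as.matrix(back$atoms[, c("x", "y", "z")]) -
                      as.matrix(m$atoms[, c("x", "y", "z")]))), 5.1e-4)
})

test_that("shell_residues returns exact minimum distances", {
  lay <- data.frame(resid = c("ALA", "GLY"), resno = c(1, 2),
                    distance = c(3, 6),
                    dx = c(1, 1), dy = c(0, 0), dz = c(0, 0))
  m <- simulate_structure(lay, seed = 1)
  got <- shell_residues(m, 5)
  expect_equal(got$resno, 1)
  expect_equal(got$min_distance, 3, tolerance = 1e-12)
  expect_equal(nrow(shell_residues(m, 0.5)), 0)
  expect_error(shell_residues(m, 5, metal_selection = integer(0)),
               "no metal atoms")
})

test_that("shell matches the brute-force all-pairs oracle on random structures", {
  for (seed in 1:25) {
    m <- random_structure(n_res = 15, seed = seed)
    radius <- runif(1, 2, 9)
    got <- shell_residues(m, radius)
    want <- oracle_shell(m$atoms, radius)
    expect_equal(got$resno, want$resno, info = paste("seed", seed))
    expect_equal(got$min_distance, want$min_distance, tolerance = 1e-9,
                 info = paste("seed", seed))
  }
})

test_that("shell membership is monotone in the radius", {
  m <- random_structure(40, seed = 77)
  radii <- c(1, 2.5, 4, 5, 7, 11)
  sets <- lapply(radii, function(r) shell_residues(m, r)$resno)
  for (i in seq_len(length(radii) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("shell distances are invariant under rigid motion", {
  m <- random_structure(25, seed = 31)
  base <- shell_residues(m, 6)
  set.seed(32)
  for (rep in 1:5) {
    # random rotation via QR of a gaussian matrix, plus translation
    qr_ <- qr(matrix(rnorm(9), 3))
    R <- qr.Q(qr_)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    t_ <- rnorm(3, sd = 20)
    m2 <- m
    xyz <- as.matrix(m$atoms[, c("x", "y", "z")]) %*% t(R)
    m2$atoms$x <- xyz[, 1] + t_[1]
    m2$atoms$y <- xyz[, 2] + t_[2]
    m2$atoms$z <- xyz[, 3] + t_[3]
    got <- shell_residues(m2, 6)
    expect_equal(got$resno, base$resno)
    expect_equal(got$min_distance, base$min_distance, tolerance = 1e-6)
  }
})

test_that("ligand histidines are flagged in the shell", {
  lay <- data.frame(resid = c("HIS", "HIS", "PHE"), resno = c(105, 141, 157),
                    distance = c(2.1, 2.2, 4.4))
  m <- simulate_structure(lay, seed = 6)
  got <- shell_residues(m, 5, ligand_his = c(105, 141))
  expect_equal(got$is_metal_ligand_his[match(c(105, 141, 157), got$resno)],
               c(TRUE, TRUE, FALSE))
  # the "besides the conserved histidines" filter
  nonhis <- got[!got$is_metal_ligand_his, ]
  expect_equal(nonhis$resno, 157)
})

test_that("map_model_to_sequence detects offsets and lists mismatches", {
  seqs <- paste(rep(c("A", "L", "G", "F", "H"), each = 20), collapse = "")
  lay <- data.frame(
    resid = bio3d::aa123(strsplit(seqs, "")[[1]]),
    resno = seq_len(nchar(seqs)),
    distance = runif(nchar(seqs), 1, 30)
  )
  m <- simulate_structure(lay, seed = 9)
  mp <- map_model_to_sequence(m, seqs)
  expect_equal(mp$offset, 0)
  expect_equal(nrow(mp$mismatches), 0)

  # model numbered from 0: offset +1 detected
  m0 <- m
  m0$atoms$resno[!m0$atoms$is_metal] <- m0$atoms$resno[!m0$atoms$is_metal] - 1L
  mp0 <- map_model_to_sequence(m0, seqs)
  expect_equal(mp0$offset, 1)

  # three deliberate mismatches of 100 are reported exactly
  m3 <- m
  idx <- which(!m3$atoms$is_metal)[c(10, 50, 90)]
  m3$atoms$resid[idx] <- "TRP"
  mp3 <- map_model_to_sequence(m3, seqs, offset = 0)
  expect_equal(sort(mp3$mismatches$resno), m3$atoms$resno[idx])

  # too many mismatches -> mapping error
  mbad <- m
  mbad$atoms$resid[!mbad$atoms$is_metal] <-
    rev(mbad$atoms$resid[!mbad$atoms$is_metal])
  expect_error(map_model_to_sequence(mbad, seqs, offset = 0), "renumber")
})
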