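#!/usr/bin/env Rscript
# Optional helper (requires network): fetches the nine desaturase sequences
# used in the package's integration checks from NCBI into
# tests/testthat/integration/, one FASTA per accession plus a group-label
# TSV. The package itself never needs network; everything else runs on
# simulated data.

accessions <- c(
  AtFAD2 = "AEE75153.1", `6803_DesA` = "WP_010872792.1",
  AtFAD6 = "NP_194824.1", Fm1 = "XP_018759876.1", Fm2 = "ABB88515.1",
  AtFAD8 = "NP_196177.1", AtFAD7 = "NP_187727.1", AtFAD3 = "NP_180559.1",
  `6803_DesB` = "WP_010872924.1"
)
groups <- c(AtFAD2 = "delta12", `6803_DesA` = "delta12", AtFAD6 = "delta12",
            Fm1 = "query", Fm2 = "other", AtFAD8 = "omega3",
            AtFAD7 = "omega3", AtFAD3 = "omega3", `6803_DesB` = "omega3")

outdir <- file.path("tests", "testthat", "integration")
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"
for (name in names(accessions)) {
  acc <- accessions[[name]]
  dest <- file.path(outdir, paste0(acc, ".fasta"))
  if (file.exists(dest)) next
  url <- paste0(base, "?db=protein&id=", acc, "&rettype=fasta&retmode=text")
  message("fetching ", acc, " (", name, ")")
  download.file(url, dest, quiet = TRUE)
  Sys.sleep(0.5)  # NCBI rate limit
}
write.table(data.frame(id = unname(accessions), group = unname(groups)),
            file.path(outdir, "groups.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
message("done; integration tests will now run")
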