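# Shared fixture builders. Everything is generated in code; no binary data.

# A fixed 6-chromosome table with a visible positive trend.
fix_table6 <- function() {
  partition_table(
    chrom = paste0("chr", 1:6),
    n_snp = c(120, 260, 340, 410, 520, 640),
    h2c   = c(0.012, 0.031, 0.022, 0.048, 0.039, 0.071),
    se    = c(0.011, 0.016, 0.018, 0.020, 0.023, 0.025))
}

# A random valid table drawn under the censored null for a genome preset.
rand_null_table <- function(genome = "chicken28", n_l = 10000, k = 1) {
  g <- load_genome_preset(genome)
  m <- allocate_snps(g, n_l)
  se <- k * sqrt(m)
  partition_table(chrom = g$chrom, n_snp = m,
                  h2c = censor_h2c(rnorm(length(m), 0, se)), se = se)
}

# Small custom genome for cheap full-pipeline runs.
genome3 <- function() {
  data.frame(chrom = c("cA", "cB", "cC"),
             size_bp = c(4e6, 2e6, 1e6), stringsAsFactors = FALSE)
}

# Deterministic GCTA .hsq fixture writer.
write_hsq <- function(path, h2 = 0.042318, se = 0.011275, sep = "\t",
                      drop_ratio_row = FALSE, trailing_blank = FALSE) {
  lines <- c(paste("Source", "Variance", "SE", sep = sep),
             paste("V(G)", "0.021159", "0.005731", sep = sep),
             paste("V(e)", "0.478841", "0.015227", sep = sep),
             paste("Vp", "0.500000", "0.011275", sep = sep))
  if (!drop_ratio_row) {
    lines <- c(lines, paste("V(G)/Vp", sprintf("%.6f", h2),
                            sprintf("%.6f", se), sep = sep))
  }
  lines <- c(lines, paste("logL", "-331.2", sep = sep),
             paste("n", "500", sep = sep))
  if (trailing_blank) lines <- c(lines, "", "")
  writeLines(lines, path)
  path
}
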