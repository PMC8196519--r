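# Fixture builders and independent oracles shared across the test files.

write_test_vcf <- function(path, chrom, pos, ref, alt,
                           filter = rep("PASS", length(pos)),
                           gzip = FALSE) {
  lines <- c("##fileformat=VCFv4.2",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"),
             if (length(pos)) paste(chrom, pos, ".", ref, alt, ".", filter,
                                    ".", sep = "\t"))
  con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con)
  close(con)
  path
}

write_test_maf <- function(path, barcode, chrom, pos, ref, alt,
                           variant_type = rep("SNP", length(pos)),
                           extra_cols = NULL, drop_cols = character()) {
  df <- data.frame(Hugo_Symbol = "GENE", Chromosome = chrom,
                   Start_Position = pos, Reference_Allele = ref,
                   Tumor_Seq_Allele2 = alt, Variant_Type = variant_type,
                   Tumor_Sample_Barcode = barcode, stringsAsFactors = FALSE)
  if (!is.null(extra_cols)) df <- cbind(df, extra_cols)
  df <- df[, setdiff(names(df), drop_cols), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_test_chrom_sizes <- function(path, sizes) {
  writeLines(paste(names(sizes), sizes, sep = "\t"), path)
  path
}

random_variant_table <- function(n, chroms = c("chr1", "chr2"),
                                 max_pos = 1e6, sample_id = "rnd") {
  pos <- sample.int(max_pos, n)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  variant_table(chrom = sample(chroms, n, replace = TRUE), pos = pos,
                ref = ref, alt = alt, sample_id = sample_id)
}

# Exhaustive piecewise-constant-fit oracle: enumerates every breakpoint
# placement (2^(n-1) candidates) and returns the minimum of
# sum-of-squares + gamma * n_breakpoints subject to segments >= kmin points.
# Independent of the package's dynamic program.
pcf_oracle_cost <- function(values, gamma, kmin) {
  n <- length(values)
  sse <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- values[i:j]
      sse[i, j] <- sum((v - mean(v))^2)
    }
  }
  if (n == 1 || n < kmin) return(sse[1, n])
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    bp <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 2))) > 0L)
    starts <- c(1L, bp + 1L)
    ends <- c(bp, n)
    if (any(ends - starts + 1L < kmin)) next
    cost <- sum(sse[cbind(starts, ends)]) + gamma * length(bp)
    if (cost < best) best <- cost
  }
  best
}

# objective value of a segmentation as returned by pcf_segment()
pcf_objective <- function(values, fit, gamma) {
  sse <- sum(vapply(seq_len(nrow(fit)), function(k) {
    v <- values[fit$start_index[k]:fit$end_index[k]]
    sum((v - mean(v))^2)
  }, numeric(1)))
  sse + gamma * (nrow(fit) - 1L)
}

# direct count of mutations in a 1-based inclusive genomic interval
count_in_interval <- function(table, chrom, start, end) {
  sum(table$chrom == chrom & table$pos >= start & table$pos <= end)
}
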