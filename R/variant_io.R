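BASES <- c("A", "C", "G", "T")

#' Construct a variant table
#'
#' A variant table is a plain `data.frame` with one somatic single-nucleotide
#' substitution per row and columns `chrom`, `pos` (1-based), `ref`, `alt`,
#' `filter_status`. The sample identifier and the source format are carried as
#' attributes so that downstream functions can label their output.
#'
#' @param chrom character vector of chromosome names (kept verbatim; "chr"
#'   prefixes are neither added nor stripped).
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-base character vectors (A/C/G/T); `ref != alt`.
#' @param filter_status character vector of FILTER tokens (default "PASS").
#' @param sample_id sample label.
#' @param source_format one of `"vcf"`, `"maf"`, `"simulated"`.
#' @param sort sort by (chrom, pos, alt) and drop duplicate (chrom, pos, alt)
#'   rows? Default `TRUE`.
#' @return a `data.frame` of class `variant_table`.
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          filter_status = rep("PASS", length(pos)),
                          sample_id = "sample", source_format = "simulated",
                          sort = TRUE) {
  stopifnot(length(chrom) == length(pos), length(ref) == length(pos),
            length(alt) == length(pos))
  if (length(pos) && any(pos < 1L)) stop("positions must be >= 1")
  if (length(pos) && any(ref == alt)) stop("ref and alt must differ")
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   filter_status = as.character(filter_status),
                   stringsAsFactors = FALSE)
  if (sort && nrow(df)) {
    df <- df[order(df$chrom, df$pos, df$alt), , drop = FALSE]
    df <- df[!duplicated(df[, c("chrom", "pos", "alt")]), , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(df, sample_id = sample_id, source_format = source_format,
            class = c("variant_table", "data.frame"))
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d SNVs, sample '%s' (source: %s)\n",
              nrow(x), attr(x, "sample_id"), attr(x, "source_format")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

is_snv <- function(ref, alt) {
  ref %in% BASES & alt %in% BASES & ref != alt
}

#' Read somatic SNVs from a VCF file
#'
#' Reads a VCF v4.x file (plain or bgzipped) and keeps only single-nucleotide
#' substitutions. Multi-allelic records are expanded into one row per SNV
#' allele; indels, MNVs and symbolic alleles are dropped (the dropped count is
#' reported as a message and stored in the `n_dropped` attribute). When
#' `apply_filter` is `TRUE` a crude filter on the FILTER field keeps only
#' records whose FILTER is `PASS` or `.`.
#'
#' @param path path to the VCF file.
#' @param apply_filter keep only FILTER == "PASS"/"." records? Default `TRUE`.
#' @param sample_id sample label; defaults to the file name without extension.
#' @return a [variant_table()].
#' @export
read_vcf <- function(path, apply_filter = TRUE, sample_id = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(path))
  }
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = as.integer(length(fix) > 0),
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) {
    warning("no variant records in ", path)
    return(variant_table(sample_id = sample_id, source_format = "vcf"))
  }
  filt <- fix[, "FILTER"]
  filt[is.na(filt)] <- "."
  keep <- if (apply_filter) filt %in% c("PASS", ".") else rep(TRUE, nrow(fix))
  fix <- fix[keep, , drop = FALSE]
  filt <- filt[keep]
  # expand multi-allelic ALT fields into one candidate allele per row
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep.int(seq_len(nrow(fix)), n_alt)
  ref <- toupper(fix[idx, "REF"])
  alt <- toupper(unlist(alts, use.names = FALSE))
  snv <- is_snv(ref, alt)
  n_dropped <- sum(!snv)
  if (n_dropped) {
    message(n_dropped, " non-SNV allele(s) (indel/MNV/symbolic) dropped from ",
            basename(path))
  }
  tab <- variant_table(chrom = fix[idx, "CHROM"][snv],
                       pos = as.integer(fix[idx, "POS"])[snv],
                       ref = ref[snv], alt = alt[snv],
                       filter_status = filt[idx][snv],
                       sample_id = sample_id, source_format = "vcf")
  if (nrow(tab) == 0) warning("zero variants retained from ", path)
  attr(tab, "n_dropped") <- n_dropped
  tab
}

#' Read somatic SNVs from a MAF file
#'
#' Reads a tab-delimited TCGA-style Mutation Annotation Format file. Only
#' single-nucleotide substitutions are retained: rows with
#' `Variant_Type == "SNP"`, or, when that column is absent, rows whose
#' `Reference_Allele` and `Tumor_Seq_Allele2` are distinct single A/C/G/T
#' bases. Samples can be kept separate (one table per `Tumor_Sample_Barcode`)
#' or merged.
#'
#' @param path path to the MAF file.
#' @param separate_samples return a `sample_set` (named list of variant
#'   tables, one per barcode)? If `FALSE` (default) a single merged table with
#'   `sample_id = "merged"` is returned.
#' @param apply_filter if `TRUE` and `filter_col` names a column present in
#'   the file, rows whose value is neither `"PASS"` nor empty/`"."` are
#'   dropped. Off by default because MAF filter column conventions vary.
#' @param filter_col name of the FILTER-like column, default `"FILTER"`.
#' @return a [variant_table()] or a named list of them (class `sample_set`).
#' @export
read_maf <- function(path, separate_samples = FALSE, apply_filter = FALSE,
                     filter_col = "FILTER") {
  if (!file.exists(path)) stop("MAF file not found: ", path)
  maf <- data.table::fread(path, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
  needed <- c("Chromosome", "Start_Position", "Reference_Allele",
              "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")
  missing_cols <- setdiff(needed, names(maf))
  if (length(missing_cols)) {
    stop("MAF is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ref <- toupper(maf$Reference_Allele)
  alt <- toupper(maf$Tumor_Seq_Allele2)
  keep <- if ("Variant_Type" %in% names(maf)) {
    maf$Variant_Type == "SNP" & is_snv(ref, alt)
  } else {
    is_snv(ref, alt)
  }
  if (apply_filter && filter_col %in% names(maf)) {
    fv <- as.character(maf[[filter_col]])
    keep <- keep & (fv %in% c("PASS", "", ".") | is.na(fv))
  }
  maf <- maf[keep, , drop = FALSE]
  ref <- ref[keep]; alt <- alt[keep]
  fs <- if (filter_col %in% names(maf)) as.character(maf[[filter_col]]) else
    rep("PASS", nrow(maf))
  build <- function(rows, id) {
    variant_table(chrom = as.character(maf$Chromosome[rows]),
                  pos = as.integer(maf$Start_Position[rows]),
                  ref = ref[rows], alt = alt[rows],
                  filter_status = fs[rows],
                  sample_id = id, source_format = "maf")
  }
  if (!separate_samples) return(build(seq_len(nrow(maf)), "merged"))
  ids <- unique(as.character(maf$Tumor_Sample_Barcode))
  out <- lapply(ids, function(id)
    build(which(maf$Tumor_Sample_Barcode == id), id))
  names(out) <- ids
  structure(out, class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set: %d sample(s)\n", length(x)))
  for (id in names(x)) cat(sprintf("  %s: %d SNVs\n", id, nrow(x[[id]])))
  invisible(x)
}

#' Write a variant table as a minimal VCF v4.2 file
#'
#' Emits a minimal valid VCF: `##fileformat` line, optional `##contig` lines,
#' and the eight mandatory columns with `ID = .`, `QUAL = .`,
#' `FILTER = PASS`, `INFO = .`. Reading the file back with [read_vcf()]
#' reproduces (chrom, pos, ref, alt) exactly.
#'
#' @param table a [variant_table()] (sorted; [variant_table()] sorts on
#'   construction).
#' @param path output file path.
#' @param chrom_sizes optional named vector of chromosome lengths used to emit
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path, chrom_sizes = NULL) {
  hdr <- "##fileformat=VCFv4.2"
  if (!is.null(chrom_sizes)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_sizes), as.integer(chrom_sizes)))
  }
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", sep = "\t"))
  recs <- if (nrow(table)) {
    paste(table$chrom, table$pos, ".", table$ref, table$alt, ".", "PASS", ".",
          sep = "\t")
  } else character()
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot write VCF to '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(hdr, recs), con)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Reads a tab-delimited file whose first two columns are chromosome name and
#' length in bp (UCSC `chrom.sizes` convention). The order of appearance is
#' preserved; genome-wide rainfall plots lay chromosomes out in this order.
#'
#' @param path path to the file.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("chrom-sizes file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("chrom-sizes file needs >= 2 tab-separated columns")
  sz <- suppressWarnings(as.numeric(tab[[2]]))
  if (anyNA(sz) || any(sz != floor(sz)) || any(sz <= 0)) {
    stop("chromosome sizes must be positive integers")
  }
  if (anyDuplicated(tab[[1]])) {
    stop("duplicate chromosome in chrom-sizes file: ",
         paste(unique(tab[[1]][duplicated(tab[[1]])]), collapse = ", "))
  }
  stats::setNames(as.integer(sz), as.character(tab[[1]]))
}
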