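#' Compute inter-mutational distances
#'
#' Sorts the variants genomically and, per chromosome, attaches to each
#' variant the distance in bp to the preceding variant on the same chromosome
#' (the inter-mutational distance, IMD). The first variant of each chromosome
#' has an undefined IMD (`NA`): distances are defined only between
#' neighbouring variants and never cross chromosome boundaries. Variants at
#' duplicate (chrom, pos) are collapsed to a single record (first by alt
#' order) so that log-scale IMDs are always finite; the number collapsed is
#' reported and stored in the `n_collapsed` attribute.
#'
#' @param table a [variant_table()].
#' @return a `data.frame` of class `imd_table` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `imd`, `subst_class` (six-class pyrimidine-referenced
#'   substitution type).
#' @export
compute_imd <- function(table) {
  sid <- attr(table, "sample_id")
  if (is.null(sid)) sid <- "sample"
  if (nrow(table) == 0) {
    warning("empty variant table: no inter-mutational distances to compute")
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(), imd = integer(),
                      subst_class = character(), stringsAsFactors = FALSE)
    return(structure(out, sample_id = sid, n_collapsed = 0L,
                     class = c("imd_table", "data.frame")))
  }
  df <- as.data.frame(table)[order(table$chrom, table$pos, table$alt), ]
  dup <- duplicated(df[, c("chrom", "pos")])
  n_collapsed <- sum(dup)
  if (n_collapsed) {
    message(n_collapsed, " variant(s) at duplicate positions collapsed")
    df <- df[!dup, , drop = FALSE]
  }
  new_chrom <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)])
  imd <- c(NA_integer_, diff(df$pos))
  imd[new_chrom] <- NA_integer_
  out <- data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref,
                    alt = df$alt, imd = as.integer(imd),
                    subst_class = classify_substitution(df$ref, df$alt),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, sample_id = sid, n_collapsed = n_collapsed,
            class = c("imd_table", "data.frame"))
}

#' @export
print.imd_table <- function(x, ...) {
  cat(sprintf("imd_table: %d variants on %d chromosome(s), sample '%s'\n",
              nrow(x), length(unique(x$chrom)), attr(x, "sample_id")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Drop samples with too few variants
#'
#' Samples with fewer than `min_variants` SNVs cannot support inter-mutational
#' distance analysis and are removed, with a warning naming each removed
#' sample.
#'
#' @param samples a `sample_set` (named list of variant tables) as returned by
#'   [read_maf()] with `separate_samples = TRUE`.
#' @param min_variants minimum SNV count to keep a sample; default 2, the
#'   minimum needed for one distance.
#' @return the filtered `sample_set`.
#' @export
drop_sparse_samples <- function(samples, min_variants = 2L) {
  stopifnot(min_variants >= 2L)
  sizes <- vapply(samples, nrow, integer(1))
  drop <- sizes < min_variants
  if (any(drop)) {
    warning("dropped sample(s) with fewer than ", min_variants,
            " variants: ", paste(names(samples)[drop], collapse = ", "))
  }
  kept <- samples[!drop]
  if (length(kept) == 0 && length(samples) > 0) {
    warning("all ", length(samples), " samples dropped as too sparse")
  }
  structure(kept, class = "sample_set")
}

#' Export an IMD table as TSV
#'
#' @param imd an `imd_table` from [compute_imd()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imd_tsv <- function(imd, path) {
  utils::write.table(as.data.frame(imd), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
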