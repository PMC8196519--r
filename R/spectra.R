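SUBST_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a substitution into the six pyrimidine-referenced classes
#'
#' Somatic substitutions are conventionally collapsed to six classes by
#' reverse-complementing purine-referenced changes so the mutated base is
#' reported as the pyrimidine (C or T) of its base pair: G>T becomes C>A,
#' A>G becomes T>C, and so on.
#'
#' @param ref,alt single-base character vectors (A/C/G/T), `ref != alt`.
#' @return character vector with values in
#'   `C>A, C>G, C>T, T>A, T>C, T>G`.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% BASES) || any(!alt %in% BASES)) {
    stop("ref and alt must be single A/C/G/T bases")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  ref[flip] <- COMPLEMENT[ref[flip]]
  alt[flip] <- COMPLEMENT[alt[flip]]
  paste0(ref, ">", alt)
}

#' Count the substitution spectrum of a variant set
#'
#' Tallies SNVs by six-class substitution type, optionally restricted to
#' variants falling inside called kataegis foci.
#'
#' @param table a [variant_table()] or `imd_table`.
#' @param foci optional focus `data.frame` (columns `chrom`, `start_pos`,
#'   `end_pos`) from [kata()]; when given, only variants inside a focus are
#'   counted and `scope` is `"foci"`.
#' @return named integer vector over the six classes with attribute `scope`.
#' @export
spectrum <- function(table, foci = NULL) {
  scope <- "all"
  if (!is.null(foci) && nrow(table)) {
    scope <- "foci"
    inside <- rep(FALSE, nrow(table))
    if (NROW(foci)) {
      for (k in seq_len(nrow(foci))) {
        inside <- inside | (table$chrom == foci$chrom[k] &
                              table$pos >= foci$start_pos[k] &
                              table$pos <= foci$end_pos[k])
      }
    }
    table <- table[inside, , drop = FALSE]
  }
  cls <- if (nrow(table)) classify_substitution(table$ref, table$alt)
         else character()
  counts <- table(factor(cls, levels = SUBST_CLASSES))
  structure(stats::setNames(as.integer(counts), SUBST_CLASSES), scope = scope)
}

#' Nucleotide content of kataegis foci and their flanks
#'
#' Counts A/C/G/T base fractions over the union of focus intervals and over
#' the union of their flanking intervals (`flank_bp` on each side, clipped to
#' chromosome bounds and excluding the foci themselves). Overlapping
#' intervals are merged so no base is counted twice; counting is
#' case-insensitive and N bases are excluded from the denominator.
#'
#' @param foci focus `data.frame` (columns `chrom`, `start_pos`, `end_pos`).
#' @param fasta path to a FASTA file or a [Biostrings::DNAStringSet].
#' @param flank_bp flank width in bp on each side of a focus; default 1000,
#'   the kataegis window scale.
#' @return a `data.frame` with columns `region` (focus/flank), `A`, `C`, `G`,
#'   `T` (fractions summing to 1) and `n_bases`.
#' @export
nucleotide_content <- function(foci, fasta, flank_bp = 1000L) {
  stopifnot(flank_bp >= 1L, NROW(foci) >= 1L)
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  missing_chr <- setdiff(unique(foci$chrom), names(seqs))
  if (length(missing_chr)) {
    stop("chromosome(s) absent from FASTA: ",
         paste(missing_chr, collapse = ", "))
  }
  count_regions <- function(chrom, starts, ends) {
    tot <- stats::setNames(rep(0, 4), BASES)
    for (chr in unique(chrom)) {
      len <- length(seqs[[chr]])
      i <- chrom == chr
      rng <- IRanges::restrict(IRanges::IRanges(starts[i], ends[i]),
                               start = 1L, end = len)
      rng <- IRanges::reduce(rng[IRanges::width(rng) > 0])
      if (length(rng) == 0) next
      v <- Biostrings::Views(seqs[[chr]], rng)
      freq <- Biostrings::letterFrequency(v, letters = BASES)
      tot <- tot + colSums(freq)
    }
    tot
  }
  focus_counts <- count_regions(foci$chrom, foci$start_pos, foci$end_pos)
  flank_counts <- count_regions(
    rep(foci$chrom, 2),
    c(foci$start_pos - flank_bp, foci$end_pos + 1L),
    c(foci$start_pos - 1L, foci$end_pos + flank_bp))
  mk <- function(counts, region) {
    n <- sum(counts)
    if (n == 0) {
      warning("empty ", region, " region after clipping to chromosome bounds")
      return(NULL)
    }
    data.frame(region = region, t(counts / n), n_bases = n,
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(focus_counts, "focus"), mk(flank_counts, "flank"))
  rownames(out) <- NULL
  out
}
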