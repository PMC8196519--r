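SUBST_PALETTE <- c("C>A" = "#2EBAED", "C>G" = "#000000", "C>T" = "#DE1C14",
                   "T>A" = "#ADCC54", "T>C" = "#D4D2D2", "T>G" = "#F0D0CE")

BASE_PALETTE <- c(A = "#4daf4a", C = "#377eb8", G = "#ff7f00", T = "#e41a1c")

#' Plot specification
#'
#' Controls output format and nominal size of the plotting functions. Every
#' plot also writes the table of plotted values next to the image
#' (`<out_path>.tsv` with the image extension replaced), so plotted data can
#' be inspected or re-plotted without image parsing.
#'
#' @param out_path output image path; its extension may be overridden by
#'   `format`.
#' @param format one of `"png"`, `"pdf"`, `"svg"`.
#' @param width,height nominal size in inches.
#' @param chrom_filter optional character vector restricting rainfall plots
#'   to one or several chromosomes.
#' @return list of class `plot_spec`.
#' @export
plot_spec <- function(out_path, format = c("png", "pdf", "svg"),
                      width = 8, height = 4.5, chrom_filter = NULL) {
  format <- match.arg(format)
  stopifnot(width > 0, height > 0)
  out_path <- paste0(tools::file_path_sans_ext(out_path), ".", format)
  structure(list(out_path = out_path, format = format, width = width,
                 height = height, chrom_filter = chrom_filter),
            class = "plot_spec")
}

open_device <- function(spec) {
  switch(spec$format,
         png = grDevices::png(spec$out_path, width = spec$width,
                              height = spec$height, units = "in", res = 150),
         pdf = grDevices::pdf(spec$out_path, width = spec$width,
                              height = spec$height),
         svg = grDevices::svg(spec$out_path, width = spec$width,
                              height = spec$height))
}

data_path <- function(spec) paste0(tools::file_path_sans_ext(spec$out_path),
                                   ".tsv")

write_plot_data <- function(df, spec) {
  utils::write.table(df, data_path(spec), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Rainfall plot of inter-mutational distances
#'
#' Scatter of log10(IMD) against genomic position, points colored by the six
#' substitution classes. Genome-wide plots concatenate chromosomes in the
#' order of `chrom_sizes` on a cumulative axis with boundary marks; a
#' `chrom_filter` in the spec restricts the plot to one or several
#' chromosomes. Clusters of low-IMD points are the visual signature of
#' kataegis; called foci can be highlighted.
#'
#' @param imd an `imd_table` from [compute_imd()].
#' @param chrom_sizes named vector of chromosome lengths
#'   ([read_chrom_sizes()]); every plotted chromosome must be present.
#' @param spec a [plot_spec()].
#' @param foci optional focus `data.frame` from [kata()] to highlight.
#' @return the image path, invisibly. The plotted table (columns `chrom`,
#'   `pos`, `x`, `imd`, `log10_imd`, `subst_class`) is written alongside.
#' @export
plot_rainfall <- function(imd, chrom_sizes, spec, foci = NULL) {
  if (nrow(imd) == 0) stop("empty IMD table")
  chroms <- names(chrom_sizes)
  if (!is.null(spec$chrom_filter)) {
    chroms <- intersect(chroms, spec$chrom_filter)
    imd <- imd[imd$chrom %in% chroms, , drop = FALSE]
    if (!is.null(foci)) foci <- foci[foci$chrom %in% chroms, , drop = FALSE]
  }
  missing_chr <- setdiff(unique(imd$chrom), chroms)
  if (length(missing_chr)) {
    stop("chromosome(s) missing from chrom_sizes: ",
         paste(missing_chr, collapse = ", "))
  }
  offsets <- stats::setNames(
    cumsum(c(0, as.numeric(chrom_sizes[chroms])))[seq_along(chroms)], chroms)
  pts <- imd[!is.na(imd$imd), , drop = FALSE]
  pts$x <- pts$pos + offsets[pts$chrom]
  pts$log10_imd <- log10(pts$imd)
  df <- pts[, c("chrom", "pos", "x", "imd", "log10_imd", "subst_class")]
  write_plot_data(df, spec)
  open_device(spec)
  on.exit(grDevices::dev.off())
  xmax <- sum(as.numeric(chrom_sizes[chroms]))
  ymax <- max(c(df$log10_imd, 1))
  graphics::plot(NA, xlim = c(0, xmax), ylim = c(0, ymax * 1.05),
                 xlab = "genomic position", ylab = "log10 inter-mutational distance (bp)",
                 xaxt = if (length(chroms) > 1) "n" else "s",
                 main = "Rainfall plot")
  if (length(chroms) > 1) {
    bounds <- cumsum(as.numeric(chrom_sizes[chroms]))
    graphics::abline(v = bounds[-length(bounds)], col = "grey80", lty = 2)
    graphics::axis(1, at = offsets + as.numeric(chrom_sizes[chroms]) / 2,
                   labels = chroms, tick = FALSE, cex.axis = 0.7)
  }
  if (!is.null(foci) && NROW(foci)) {
    graphics::rect(foci$start_pos + offsets[foci$chrom], 0,
                   foci$end_pos + offsets[foci$chrom], ymax * 1.05,
                   col = grDevices::adjustcolor("gold", 0.35), border = NA)
  }
  graphics::points(df$x, df$log10_imd, pch = 16, cex = 0.5,
                   col = SUBST_PALETTE[df$subst_class])
  graphics::legend("topright", legend = names(SUBST_PALETTE), pch = 16,
                   col = SUBST_PALETTE, cex = 0.6, ncol = 6, bty = "n")
  invisible(spec$out_path)
}

#' Horizontal bar plot of the substitution spectrum
#'
#' One horizontal bar per substitution class in the fixed order C>A, C>G,
#' C>T, T>A, T>C, T>G, with bar length proportional to the count.
#'
#' @param counts named counts from [spectrum()].
#' @param spec a [plot_spec()].
#' @return the image path, invisibly; bar data written alongside.
#' @export
plot_spectrum <- function(counts, spec) {
  counts <- counts[SUBST_CLASSES]
  df <- data.frame(subst_class = SUBST_CLASSES, count = as.integer(counts),
                   stringsAsFactors = FALSE)
  write_plot_data(df, spec)
  open_device(spec)
  on.exit(grDevices::dev.off())
  graphics::barplot(rev(df$count), names.arg = rev(df$subst_class),
                    horiz = TRUE, las = 1, col = rev(SUBST_PALETTE),
                    xlab = "mutations",
                    main = "Substitution spectrum")
  invisible(spec$out_path)
}

#' Stacked bar plot of nucleotide content
#'
#' One stacked bar per region (focus, flank), the A/C/G/T fractions of each
#' stacking to 1.
#'
#' @param profiles `data.frame` from [nucleotide_content()].
#' @param spec a [plot_spec()].
#' @return the image path, invisibly; profile data written alongside.
#' @export
plot_content <- function(profiles, spec) {
  stopifnot(NROW(profiles) >= 1)
  write_plot_data(profiles, spec)
  open_device(spec)
  on.exit(grDevices::dev.off())
  m <- t(as.matrix(profiles[, BASES]))
  colnames(m) <- profiles$region
  graphics::barplot(m, col = BASE_PALETTE[BASES], ylab = "fraction",
                    main = "Nucleotide content", ylim = c(0, 1.25),
                    legend.text = BASES,
                    args.legend = list(horiz = TRUE, bty = "n"))
  invisible(spec$out_path)
}
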