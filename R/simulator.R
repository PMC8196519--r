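#' Configuration for the kataegis mutation simulator
#'
#' @param chrom_name name of the simulated chromosome.
#' @param seq_length length (bp) of the uniform-random sequence to simulate;
#'   ignored when `sequence` is supplied.
#' @param sequence optional template sequence: a single character string, a
#'   [Biostrings::DNAString], or a path to a FASTA file (first record used).
#' @param tmb tumor mutational burden: background mutations per Mb.
#' @param kataegis_mode plant kataegis foci? When `TRUE`, `n_foci` windows of
#'   at most `focus_window_bp` each receive 7-20 clustered mutations; when
#'   `FALSE`, background positions keep a minimum gap of
#'   `focus_window_bp + 1` so no 1-kb window can ever hold more than 6
#'   mutations.
#' @param n_foci number of planted foci (kataegis mode only).
#' @param focus_mut_range integer pair: range of mutation counts per focus,
#'   default `c(7, 20)` (at least 7, i.e. "more than 6"; foci are small).
#' @param focus_window_bp width of a focus window, default (and maximum) 1000.
#' @param seed integer seed; identical configurations give byte-identical
#'   output.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(chrom_name = "chrSim", seq_length = 1e6,
                       sequence = NULL, tmb = 10, kataegis_mode = FALSE,
                       n_foci = 3L, focus_mut_range = c(7L, 20L),
                       focus_window_bp = 1000L, seed = 1L) {
  stopifnot(tmb > 0, focus_mut_range[1] >= 7L,
            focus_mut_range[1] <= focus_mut_range[2],
            focus_window_bp >= 1L, focus_window_bp <= 1000L)
  if (kataegis_mode && n_foci < 1L) {
    stop("kataegis mode requires n_foci >= 1")
  }
  structure(list(chrom_name = chrom_name, seq_length = as.integer(seq_length),
                 sequence = sequence, tmb = tmb,
                 kataegis_mode = isTRUE(kataegis_mode),
                 n_foci = as.integer(n_foci),
                 focus_mut_range = as.integer(focus_mut_range),
                 focus_window_bp = as.integer(focus_window_bp),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a uniform-random DNA sequence
#'
#' @param length sequence length in bp.
#' @param seed optional seed.
#' @return a single character string over A/C/G/T.
#' @export
random_sequence <- function(length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, length, replace = TRUE), collapse = "")
}

resolve_sequence <- function(config) {
  s <- config$sequence
  if (is.null(s)) {
    return(random_sequence(config$seq_length))
  }
  if (inherits(s, "DNAString")) return(as.character(s))
  if (is.character(s) && length(s) == 1 && file.exists(s) &&
      grepl("\\.(fa|fasta|fna)(\\.gz)?$", s)) {
    return(as.character(Biostrings::readDNAStringSet(s)[[1]]))
  }
  toupper(as.character(s))
}

# n positions in 1..L, uniformly at random among all sets whose consecutive
# sorted gaps are >= min_gap (min_gap = 1 gives distinct positions)
spaced_positions <- function(n, L, min_gap) {
  if (n == 0) return(integer(0))
  L_eff <- L - (n - 1) * (min_gap - 1)
  if (L_eff < n) {
    stop("sequence too short (", L, " bp) to host ", n,
         " mutations at minimum spacing ", min_gap, " bp")
  }
  x <- sort(sample.int(L_eff, n))
  as.integer(x + (seq_len(n) - 1L) * (min_gap - 1L))
}

#' Simulate somatic SNVs with or without planted kataegis
#'
#' Mutates a template sequence at a given tumor mutational burden.
#' `round(tmb * length / 1e6)` background mutations are drawn; in kataegis
#' mode, `n_foci` non-overlapping windows of at most `focus_window_bp` are
#' additionally placed uniformly at random, each receiving a uniform-random
#' number of mutations in `focus_mut_range` at uniform-random positions
#' within the window (background positions never fall inside a focus window).
#' Outside kataegis mode, background positions keep a minimum gap of
#' `focus_window_bp + 1`, which guarantees that no window of
#' `focus_window_bp` contains more than one mutation -- the sequence can
#' never satisfy the kataegis definition by chance. Every alt base is drawn
#' uniformly from the three non-reference bases.
#'
#' @param config a [sim_config()].
#' @param return_sequence also return the mutated sequence? Default `FALSE`
#'   (building it is the only expensive step for long chromosomes).
#' @return list with elements `variants` (a [variant_table()]), `truth`
#'   (`data.frame` of planted focus intervals: `chrom`, `start`, `end`,
#'   `n_mut`; empty outside kataegis mode), `total_mutations`, and
#'   `mutated_sequence` (character or `NULL`).
#' @export
simulate_mutations <- function(config, return_sequence = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seq_str <- resolve_sequence(config)
  L <- nchar(seq_str)
  w <- config$focus_window_bp
  n_bg <- round(config$tmb * L / 1e6)
  if (config$kataegis_mode) {
    # non-overlapping focus windows, then carve background around them
    win_start <- spaced_positions(config$n_foci, L - w + 1L, w)
    focus_pos <- integer(0)
    truth <- vector("list", config$n_foci)
    for (k in seq_len(config$n_foci)) {
      m <- sample(seq.int(config$focus_mut_range[1], config$focus_mut_range[2]), 1L)
      p <- win_start[k] - 1L + sort(sample.int(w, m))
      focus_pos <- c(focus_pos, p)
      truth[[k]] <- data.frame(chrom = config$chrom_name, start = min(p),
                               end = max(p), n_mut = m,
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    in_window <- unlist(lapply(win_start, function(s) seq.int(s, s + w - 1L)))
    pool <- setdiff(seq_len(L), in_window)
    if (length(pool) < n_bg) {
      stop("sequence too short to host ", n_bg,
           " background mutations outside the focus windows")
    }
    bg_pos <- sort(sample(pool, n_bg))
    pos <- sort(c(bg_pos, focus_pos))
  } else {
    pos <- spaced_positions(n_bg, L, w + 1L)
    truth <- data.frame(chrom = character(), start = integer(),
                        end = integer(), n_mut = integer(),
                        stringsAsFactors = FALSE)
  }
  ref <- vapply(pos, function(p) substr(seq_str, p, p), character(1))
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), character(1),
                USE.NAMES = FALSE)
  variants <- variant_table(chrom = rep(config$chrom_name, length(pos)),
                            pos = pos, ref = ref, alt = alt,
                            sample_id = sprintf("sim_seed%d", config$seed),
                            source_format = "simulated")
  mutated <- NULL
  if (return_sequence) {
    d <- Biostrings::DNAString(seq_str)
    mutated <- as.character(
      Biostrings::replaceLetterAt(d, pos, alt))
  }
  list(variants = variants, truth = truth,
       total_mutations = length(pos), mutated_sequence = mutated,
       template_sequence = if (return_sequence) seq_str else NULL)
}

#' Maximum mutation count in any fixed-width genomic window
#'
#' Sliding-window scan used to verify simulator guarantees: for each variant,
#' counts variants within `[pos, pos + window_bp - 1]` on the same chromosome
#' and returns the maximum over all anchors.
#'
#' @param table a [variant_table()] or `imd_table`.
#' @param window_bp window width in bp, default 1000.
#' @return integer, 0 for an empty table.
#' @export
max_window_count <- function(table, window_bp = 1000L) {
  if (nrow(table) == 0) return(0L)
  best <- 0L
  for (chr in unique(table$chrom)) {
    p <- sort(table$pos[table$chrom == chr])
    # findInterval gives, per anchor i, the last j with p[j] <= p[i]+w-1
    hi <- findInterval(p + window_bp - 1L, p)
    best <- max(best, max(hi - seq_along(p) + 1L))
  }
  as.integer(best)
}

#' Run the simulation benchmark
#'
#' Simulates `n_pos` kataegis-positive and `n_neg` kataegis-free variant sets
#' on a shared template sequence, runs the detector on each, and tallies
#' sensitivity and false positives. A positive file counts as detected iff at
#' least one focus is called; a negative file counts as a false positive iff
#' any focus is called. File `i` uses seed `base seed + i` so runs are
#' reproducible file-by-file.
#'
#' @param n_pos,n_neg number of positive / negative simulated samples.
#' @param config a [sim_config()]; its `seed` is the base seed and also seeds
#'   the shared template sequence. Its `kataegis_mode` is overridden per
#'   file; a positive run requires `n_foci >= 1`.
#' @param params detector parameters ([pcf_params()]).
#' @param out_dir optional directory; when given, each simulated sample is
#'   written as `sim_pos_###.vcf` / `sim_neg_###.vcf` plus a truth BED.
#' @return list of class `kata_benchmark`: `report` (per-file `data.frame`
#'   with `file`, `truth_kataegis`, `seed`, `n_mut`, `n_foci_called`,
#'   `detected`), `n_detected`, `n_false_pos`, `sensitivity`, `specificity`.
#' @export
run_benchmark <- function(n_pos, n_neg, config = sim_config(),
                          params = pcf_params(), out_dir = NULL) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  if (config$n_foci < 1L) {
    stop("benchmark requires a positive-capable config (n_foci >= 1)")
  }
  # one shared template sequence for every file (seeded by the base seed)
  set.seed(config$seed)
  template <- resolve_sequence(config)
  labels <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  report <- vector("list", length(labels))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  for (i in seq_along(labels)) {
    cfg_i <- config
    cfg_i$sequence <- template
    cfg_i$kataegis_mode <- labels[i]
    cfg_i$seed <- config$seed + i
    sim <- simulate_mutations(cfg_i)
    res <- kata(suppressMessages(compute_imd(sim$variants)), params)
    called <- nrow(res$foci)
    fname <- sprintf("sim_%s_%03d.vcf", if (labels[i]) "pos" else "neg", i)
    if (!is.null(out_dir)) {
      write_vcf(sim$variants, file.path(out_dir, fname),
                chrom_sizes = stats::setNames(nchar(template),
                                              config$chrom_name))
      if (labels[i]) {
        utils::write.table(sim$truth,
                           file.path(out_dir, sub("\\.vcf$", ".truth.bed", fname)),
                           sep = "\t", quote = FALSE, row.names = FALSE,
                           col.names = FALSE)
      }
    }
    report[[i]] <- data.frame(file = fname, truth_kataegis = labels[i],
                              seed = cfg_i$seed,
                              n_mut = sim$total_mutations,
                              n_foci_called = called,
                              detected = called > 0,
                              stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, report)
  n_detected <- sum(report$detected & report$truth_kataegis)
  n_false_pos <- sum(report$detected & !report$truth_kataegis)
  structure(list(report = report, n_pos = n_pos, n_neg = n_neg,
                 n_detected = n_detected, n_false_pos = n_false_pos,
                 sensitivity = n_detected / n_pos,
                 specificity = (n_neg - n_false_pos) / n_neg),
            class = "kata_benchmark")
}

#' @export
print.kata_benchmark <- function(x, ...) {
  cat(sprintf("kataegis benchmark: %d/%d positives detected, %d/%d negatives flagged\n",
              x$n_detected, x$n_pos, x$n_false_pos, x$n_neg))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
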