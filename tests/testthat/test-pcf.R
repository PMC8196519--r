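test_that("constant input yields a single segment at its mean", {
  fit <- pcf_segment(c(2, 2, 2, 2), gamma = 0.5, kmin = 2)
  expect_equal(nrow(fit), 1)
  expect_equal(fit$mean, 2)
  expect_equal(fit$start_index, 1L)
  expect_equal(fit$end_index, 4L)
})

test_that("step input splits or merges depending on the penalty", {
  v <- c(0, 0, 0, 3, 3, 3)
  # cheap breakpoint: split at the step (total cost 1 beats 13.5)
  lo <- pcf_segment(v, gamma = 1, kmin = 2)
  expect_equal(lo$start_index, c(1L, 4L))
  expect_equal(lo$end_index, c(3L, 6L))
  expect_equal(lo$mean, c(0, 3))
  expect_equal(pcf_objective(v, lo, 1), pcf_oracle_cost(v, 1, 2))
  # expensive breakpoint: one segment at the grand mean
  hi <- pcf_segment(v, gamma = 100, kmin = 2)
  expect_equal(nrow(hi), 1)
  expect_equal(hi$mean, 1.5)
  expect_equal(pcf_objective(v, hi, 100), pcf_oracle_cost(v, 100, 2))
})

test_that("dynamic program matches exhaustive enumeration on random inputs", {
  withr::with_seed(31, {
    for (rep in 1:80) {
      n <- sample(2:10, 1)
      v <- round(stats::rnorm(n, sd = 2), 3)
      gamma <- stats::runif(1, 0.1, 10)
      kmin <- sample(1:3, 1)
      fit <- suppressMessages(pcf_segment(v, gamma, kmin))
      expect_true(all(fit$end_index - fit$start_index + 1 >= min(kmin, n)))
      expect_equal(pcf_objective(v, fit, gamma),
                   pcf_oracle_cost(v, gamma, kmin),
                   tolerance = 1e-10)
    }
  })
})

test_that("segments tile the index range and respect kmin", {
  withr::with_seed(32, {
    v <- stats::rnorm(60)
  })
  fit <- pcf_segment(v, gamma = 2, kmin = 3)
  expect_equal(fit$start_index[1], 1L)
  expect_equal(fit$end_index[nrow(fit)], 60L)
  if (nrow(fit) > 1) {
    expect_equal(fit$start_index[-1], fit$end_index[-nrow(fit)] + 1L)
  }
  expect_true(all(fit$end_index - fit$start_index + 1 >= 3))
  # each mean is the arithmetic mean of its members
  for (k in seq_len(nrow(fit))) {
    expect_equal(fit$mean[k], mean(v[fit$start_index[k]:fit$end_index[k]]))
  }
})

test_that("increasing gamma never increases the number of segments", {
  withr::with_seed(33, {
    v <- c(stats::rnorm(20, 0), stats::rnorm(20, 4), stats::rnorm(20, -2))
  })
  counts <- vapply(c(0.1, 1, 5, 25, 100, 1000),
                   function(g) nrow(pcf_segment(v, g, 2)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cost ties break toward fewer segments", {
  # split cost (0 + gamma) exactly equals one-segment SSE of 1.0
  fit <- pcf_segment(c(0, 0, 1, 1), gamma = 1, kmin = 2)
  expect_equal(nrow(fit), 1)
})

test_that("degenerate inputs are handled", {
  expect_message(fit <- pcf_segment(c(1.5), gamma = 1, kmin = 2), "kmin")
  expect_equal(nrow(fit), 1)
  expect_error(pcf_segment(c(1, NA, 2), gamma = 1), "finite")
  expect_error(pcf_segment(numeric(0), gamma = 1), "empty")
})

test_that("a dense run among sparse mutations is called as one focus", {
  vt <- variant_table(chrom = rep("chrA", 7), pos = seq(1000, 1600, by = 100),
                      ref = rep("C", 7), alt = rep("T", 7))
  res <- kata(compute_imd(vt))
  expect_equal(nrow(res$foci), 1)
  expect_equal(res$foci$n_mut, 7L)
  expect_equal(res$foci$mean_imd, 100)
  expect_equal(res$foci$span_bp, 601L)
  expect_equal(res$foci$start_pos, 1000L)
  expect_equal(res$foci$end_pos, 1600L)
  # evenly sparse mutations produce no foci
  sparse <- variant_table(chrom = rep("chrA", 100),
                          pos = seq(1, by = 10000, length.out = 100),
                          ref = rep("C", 100), alt = rep("T", 100))
  expect_equal(nrow(kata(compute_imd(sparse))$foci), 0)
  # empty input warns and returns an empty result
  expect_warning(empty <- kata(suppressWarnings(compute_imd(variant_table()))),
                 "no chromosome")
  expect_equal(nrow(empty$foci), 0)
})

test_that("focus calls respect both thresholds and the segment bookkeeping", {
  withr::with_seed(34, {
    cfg <- sim_config(seq_length = 5e5, tmb = 20, kataegis_mode = TRUE,
                      n_foci = 2, seed = 77)
    sim <- simulate_mutations(cfg)
  })
  imd <- compute_imd(sim$variants)
  res <- kata(imd)
  p <- res$params
  expect_true(all(res$foci$n_mut >= p$min_mut))
  expect_true(all(res$foci$mean_imd <= p$max_mean_imd))
  failing <- res$segments$n_mut < p$min_mut |
    res$segments$mean_imd > p$max_mean_imd
  expect_equal(nrow(res$segments) - sum(failing), nrow(res$foci))
  # per chromosome: sum(n_mut) = n_variants + n_segments - 1
  for (chr in unique(res$segments$chrom)) {
    s <- res$segments[res$segments$chrom == chr, ]
    n_var <- sum(imd$chrom == chr)
    expect_equal(sum(s$n_mut), n_var + nrow(s) - 1L)
    # segments tile the variant range
    expect_equal(s$start_pos[-1], s$end_pos[-nrow(s)])
  }
})

test_that("planted dense clusters are always recovered from sparse backgrounds", {
  # property-style sweep: a >= 7-variant cluster spaced <= 1 kb in a
  # background two orders of magnitude sparser must always be called
  withr::with_seed(35, {
    for (rep in 1:20) {
      n_bg <- sample(20:60, 1)
      bg <- sort(sample.int(5e6, n_bg)) + 2e6
      m <- sample(7:15, 1)
      cl_start <- sample.int(1e6, 1)
      cl <- cl_start + sort(sample.int(1000, m)) - 1L
      pos <- sort(unique(c(bg, cl)))
      vt <- variant_table(chrom = rep("c", length(pos)), pos = pos,
                          ref = rep("C", length(pos)),
                          alt = rep("T", length(pos)))
      res <- kata(compute_imd(vt))
      hit <- res$foci$start_pos <= max(cl) & res$foci$end_pos >= min(cl)
      expect_true(any(hit))
    }
  })
})

test_that("foci export to BED with the 0-based half-open convention", {
  foci <- data.frame(chrom = "chr1", start_pos = 1000L, end_pos = 1600L,
                     n_mut = 7L, mean_imd = 100, mean_log10_imd = 2,
                     focus_id = 1L, span_bp = 601L)
  p <- write_foci_bed(foci, withr::local_tempfile(fileext = ".bed"))
  expect_equal(readLines(p), "chr1\t999\t1600\tfocus_1\t7")
  pe <- write_foci_bed(foci[0, ], withr::local_tempfile(fileext = ".bed"))
  expect_equal(length(readLines(pe)), 0)
  # round trip: BED intervals reproduce the 1-based inclusive intervals
  bed <- utils::read.table(p, sep = "\t")
  expect_equal(bed$V2 + 1L, foci$start_pos)
  expect_equal(bed$V3, foci$end_pos)
})
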