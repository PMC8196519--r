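# katadetect

Detection and visualization of **kataegis** — localized somatic
hypermutation — from high-throughput sequencing variant calls, for cancer
genomics analysts working from VCF or MAF call sets.

Kataegis foci are short regions (operationally **≥ 6 substitutions within
~1000 bp**) where somatic mutations cluster at densities far above a
sample's background rate. katadetect identifies them in four steps:

1. **Read** somatic SNVs from VCF (`read_vcf()`, with crude FILTER-field
   filtering) or multi-sample MAF (`read_maf()`, merged or per sample).
2. **Compute inter-mutational distances** (`compute_imd()`): per
   chromosome, after coordinate sorting, the distance of each variant to
   its predecessor, `d_i = pos_i − pos_{i−1}`.
3. **Segment and call** (`kata()`): the per-chromosome profile
   `v_i = log10(d_i)` is segmented by exact piecewise constant fitting —
   the partition minimizing

   ```
   Σ_segments Σ_{i∈seg} (v_i − mean_seg)²  +  γ · #breakpoints,   |seg| ≥ kmin
   ```

   solved exactly by dynamic programming (`pcf_segment()`). Segments with
   `n_mut ≥ 6` and mean IMD ≤ 1000 bp are called as kataegis foci; the full
   segment table is returned too.
4. **Visualize** (`plot_rainfall()`, `plot_spectrum()`, `plot_content()`):
   genome-wide or per-chromosome rainfall plots of log10(IMD) colored by
   the six substitution classes (C>A, C>G, C>T, T>A, T>C, T>G), spectrum
   bars of the foci, and stacked nucleotide content of foci vs. flanks.
   Every plot writes its underlying data as TSV next to the image.

A seed-controlled **simulator** (`simulate_mutations()`) plants foci of
7–20 mutations in ≤ 1-kb windows — or, in negative mode, spaces mutations
so the kataegis definition can never trigger — and emits VCF plus ground
truth, powering a sensitivity/specificity benchmark (`run_benchmark()`).

## Worked example

```r
library(katadetect)
vcf  <- system.file("extdata", "synthetic_example.vcf", package = "katadetect")
snvs <- read_vcf(vcf)        # 59 SNVs on a simulated 500-kb chromosome
imd  <- compute_imd(snvs)
res  <- kata(imd)
res
#> kataegis_result: 3 segment(s), 1 focus/foci called
#>   thresholds: n_mut >= 6, mean IMD <= 1000 bp (gamma=8, kmin=2)
#>   chrom start_pos end_pos n_mut mean_imd mean_log10_imd focus_id span_bp
#> 1  chr1    230680  237230    19 363.8889       1.848629        1    6551
```

The sample carries two planted foci ~4.8 kb apart; they are reported as one
called region of 19 mutations whose mean inter-mutational distance
(363.9 bp) is far below the 1000-bp threshold, while the ~54 background
mutations (one per ~9 kb) produce no call. The foci-restricted spectrum and
BED export follow naturally:

```r
spectrum(imd, res$foci)
#> C>A C>G C>T T>A T>C T>G
#>   3   0   1   6   4   5
write_foci_bed(res$foci, "foci.bed")
```

## Command line

A thin wrapper over the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","katadetect.R",package="katadetect"))')" \
    detect --vcf sample.vcf --out-prefix sample
# -> sample.segments.tsv, sample.foci.bed
```

Subcommands: `detect`, `simulate` (one VCF + truth BED), `benchmark`,
`plot`. Detector parameters `--gamma --kmin --min-mut --max-mean-imd` are
exposed on `detect`.

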