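# interpXY

Sex-unbiased between-array normalization of Infinium DNA methylation
arrays (450k/EPIC-style data) by **autosomal rank interpolation**, plus
the evaluation toolkit to audit sex bias in normalization pipelines.

## Who this is for, and why

Quantile-based between-array normalizers (dasen-style pipelines: Infinium
type I/II intensity-mode alignment, then per-type quantile normalization
of the methylated and unmethylated channels) put every probe of a sample
into one quantile pool. Sex chromosomes poison that pool: under
X inactivation, female X-linked CpGs sit at intermediate methylation
(beta ≈ 0.45), while the male's single active X is largely unmethylated
— low betas at half the total intensity — and Y probes carry signal only
in males. These sex-specific insertions displace autosomal ranks
*differently per sex*, leaking an artificial sex effect into thousands of
autosomal CpGs: spurious sex-associated positions (saDMPs), almost all
"higher in males", and an inflated sex-explained fraction of variance.

The fix implemented here is the two-step *interpolatedXY* strategy:

1. normalize **autosomes alone** (`dasenNormalize(x, "autosomes_only")`
   or any quantile-based plug-in);
2. assign every sex-chromosome probe the corrected intensity found by
   **linear interpolation of its fractional rank** within the autosomal
   raw-intensity distribution, per channel (M, U) and per design type
   (I, II):

   - sort the corrected autosomal values into a rank→value function
     *F*,
   - estimate each sex probe's fractional rank among the autosomal raw
     values by piecewise-linear interpolation,
   - read its corrected value off *F*; out-of-range values clamp to the
     extreme ranks.

Betas are recomputed as β = M/(M+U+100). Sample sex is never consulted.

Key evaluation functions: `singleSexGoldStandard()` (in a single-sex
group, normalizing sex chromosomes as ordinary autosomes is legitimate
and yields reference values; interpolated betas are scored against them
by RMSE), `sexExplainedFraction()`
(F_sex = 1 − (n_f·V_f + n_m·V_m)/((n_f+n_m)·V_total), exactly the
between-sex share of the total sum of squares), `sexEWAS()` (per-CpG
two-group F test, Bonferroni), `compareSaDMPs()`, and a seeded generator
`simulateDataset()` with ground truth retained.

## Worked example

```r
library(interpXY)

sim <- simulateDataset(simConfig(nAuto = 20000, nX = 480, nY = 48,
                                 nFemale = 150, nMale = 150, seed = 1001))
dasen <- dasenNormalize(sim$data, "all")          # classic mixed pipeline
adj   <- adjustedNormalize(sim$data, "dasen")     # two-step, sex-unbiased

varianceReport(adj)[, c("group", "vTotal", "fSex")]
#>       group      vTotal        fSex
#> 1 autosomes 0.000607921 0.003332822
#> 2         X 0.025123805 0.967551890
#> 3         Y 0.016924101 0.895373080

cmp <- compareSaDMPs(sexEWAS(dasen, scope = "autosomes"),
                     sexEWAS(adj,   scope = "autosomes"))
cmp$nAOnly                      # saDMPs only the mixed pipeline calls
#> [1] 1017
cmp$byDirection["a_only", ]
#>        higher_in_females higher_in_males
#> a_only                 0            1017
```

No true autosomal sex effect was planted, yet the mixed pipeline calls
1017 Bonferroni-significant autosomal saDMPs — every one "higher in
males", the fingerprint of the rank-displacement artifact — while the
adjusted pipeline calls none, and its autosomal sex-explained variance
stays at the null level (0.33% vs 1.22% under the mixed pipeline, 0.17%
raw). The same run shows normalization halving the autosomal per-CpG
variance (0.00126 → 0.00061).

A command-line surface wraps the same functions:

```sh
Rscript inst/scripts/interpxy.R simulate --out sim/ --seed 7
Rscript inst/scripts/interpxy.R normalize --meth sim/meth.tsv \
    --unmeth sim/unmeth.tsv --annotation sim/annotation.tsv \
    --method adjusted-dasen --out norm/
Rscript inst/scripts/interpxy.R sex-variance --beta norm/beta.tsv \
    --annotation sim/annotation.tsv --samplesheet sim/samplesheet.tsv \
    --out variance.tsv
```

All inputs/outputs are TSV (probes × samples, `probe_id` first column,
`NA` for missing, `#` provenance headers); identical config and seed give
byte-identical files.

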