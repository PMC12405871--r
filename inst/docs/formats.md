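# digenic table formats

All files are RFC-4180 CSV with a header row, UTF-8, decimal point `.`
(locale-independent). Unicode minus signs (U+2212) are normalised to `-`
on input. Genotypes are functional-allele dosages: `rc_dosage`,
`pb_dosage` in {0, 1, 2} (0 = homozygous non-functional, 1 =
heterozygote, 2 = homozygous functional).

## germination (schema v1)

One row per seed sample.

| column | type | meaning |
|---|---|---|
| sample_id | text | unique sample identifier |
| rc_dosage | 0/1/2 | Rc functional-allele dosage |
| pb_dosage | 0/1/2 | Pb functional-allele dosage |
| n_total | int > 0 | seeds plated (N) |
| d\<day\> ... | num >= 0 | one column per counting day, e.g. `d2..d7` or `d3,d5,d7` |

Counts are incremental (newly germinated on that day). Cumulative files
are accepted with `--counts cumulative` (CLI) or
`read_germination(counts = "cumulative")`; they must be non-decreasing
and are differenced at ingestion. `sum(counts) <= n_total` per row.

## imbibition (long; schema v1)

One row per sample x time point.

| column | type | meaning |
|---|---|---|
| sample_id | text | sample identifier |
| rc_dosage, pb_dosage | 0/2 | homozygous dosages |
| time_h | num | hours post-soaking |
| wc | num | water-content fraction `(w_i - w0)/w0` (input-kind `wc`) |
| weight, w0 | num | gram weights (input-kind `weight`; wc derived) |

## f2_phenotype (schema v1)

| column | type | meaning |
|---|---|---|
| sample_id | text | plant identifier |
| rc_dosage, pb_dosage | 0/1/2 | genotype |
| gp, gi, ... | num | one column per response trait |

## flavonoid cell summaries (schema v1)

| column | type | meaning |
|---|---|---|
| rc_dosage, pb_dosage | 0/2 | homozygous line genotype |
| dpa | num | development time (days post-anthesis; two levels) |
| chemical | text | e.g. CA, EC, PB2, PB3, AC |
| mean, se | num | cell mean and standard error (ug/g), 3 replicates |
| detected | bool (optional) | FALSE = non-detectable cell (mean/se 0) |

## fit_report (output of `digenic fit` / `write_fit_report()`)

Rows: `mu`, one per retained term, `Total`. Columns: `term`, `effect`
(trait units), `standard_error`, `p_value`, `r2_pct` (sequential
R-squared increment, percent; the `Total` row carries the model
R-squared), `entry_order`. Numbers are written at full precision
(round-trip exact).

## CLI

```
digenic metrics    --input g.csv [--counts incremental|cumulative] [--output o.csv]
digenic fit        --input p.csv --model hom|f2|gxt --response gp
                   [--alpha 0.05] [--no-select] [--output report.csv]
digenic timecourse --input imb.csv [--input-kind wc|weight] [--output prefix]
digenic simulate   f2|germination|flavonoid|imbibition [--seed 1] [--n N]
                   [--output o.csv]
```

Exit codes: 0 success, 2 input-validation error, 1 internal/usage error.
Every run logs the package version, subcommand, and seed to stderr.
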