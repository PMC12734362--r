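# cpgpgx

Screening genetic variants that disrupt or form CpG dinucleotides and
carry pharmacogenomic significance ("CpG-PGx SNPs").

## The problem

DNA methylation acts on CpG dinucleotides, so a single-nucleotide variant
(or indel) that destroys an existing CpG — a substitution at the C or G of
a CpG site — or creates a new one — a minor allele C in an XpG context or
G in a CpY context — can remove or add a methylation substrate in cis.
When such a variant *also* has a significant variant–drug (PGx)
association, it is a candidate link between the epigenome and drug
response. `cpgpgx` implements this screen as a reusable pipeline for
researchers in pharmacoepigenomics and regulatory genomics:

* **CpG delta classifier** — for any variant against a reference sequence,
  decide whether the reference→alternate change loses and/or gains CpG
  dinucleotides.  For a SNV in window context this reduces to comparing
  the dinucleotides touching the substituted base; indels are handled by
  local-haplotype diffing: CpG sites of the reference and alternate
  windows are matched positionally (same coordinate, or shifted by the
  allele length difference `|alt| − |ref|`), so a CpG that merely moves
  with an indel counts as neither lost nor gained.  Labels:
  `disruptive` (lost > 0, gained = 0), `forming` (gained > 0, lost = 0),
  `both`, `neutral`.
* **Pathway 1 (PGx screen)** — keep variant–drug annotations with
  p < 0.05 (strict), join against the classifications, and tally CpG-PGx
  SNPs per gene and per primary function class.
* **Pathway 2 (GWAS screen)** — for panel genes *without* a significant
  PGx annotation, keep variant–trait associations with p < 5×10⁻⁸
  (strict) and MAF ≥ 0.05 (inclusive), tally CpG-SNPs per gene, and split
  candidates into disruptive / forming / both.
* **Prioritisation** — rank candidates from the most to the least common
  allele (MAF descending; structural/regulatory functions before
  intronic-only at equal MAF), and compare hub-gene candidates across
  seven factors (relevance score, significant annotations, CpG-PGx SNPs,
  variant types, formations, disruptions, PubMed titles), each won by its
  maximum.
* **Synthetic data** — seeded generators for reference sequences with a
  tunable CpG rate, variants spiked with known delta-class truth labels
  (SNVs and indels), and annotation tables with planted significance that
  straddles the screening thresholds, so the whole pipeline is testable
  end to end without any download.

The package also ships the originating screen's published summary tables
(`load_fixture("table1")` … `"table6"`) as plain-text fixtures, and can
replay the screen on them.

## Worked example

Classify a variant by hand:

```r
library(cpgpgx)
ref <- c(chr1 = "TACGGA")
v <- variant_record("chr1", 3, "C", "T", rsid = "rs_demo")
classify_batch(v, ref)[, c("rsid", "n_lost", "n_gained", "label")]
#>      rsid n_lost n_gained      label
#> 1 rs_demo      1        0 disruptive
```

Run the full screen on a synthetic scenario with planted truth:

```r
sc  <- make_scenario(seed = 7, dir = tempfile())
rep <- run_full_screen(screen_config(), sc$paths$fasta, sc$paths$vcf,
                       sc$paths$pgx, sc$paths$gwas, sc$paths$panel)
rep
#> CpG-PGx screen report
#>   variants classified: 88
#>   pathway 1: 6 genes, 69 significant annotations, 28 CpG-PGx SNPs
#>   pathway 2: 6 genes, 36 refined associations, 22 CpG-SNPs ( disruptive 11, forming 10, both 1 )
all(sc$truth$labels[rep$pathway1$candidates$rsid] ==
    rep$pathway1$candidates$label)
#> [1] TRUE
```

Here pathway 1 reports the 28 unique non-neutral variants that carry at
least one significant annotation, and pathway 2 the 22 refined GWAS
variants hitting a CpG site; every count is recomputable from the
candidate lists inside the report.

Replay the published screen from the packaged tables:

```r
run_fixture_screen()
#> CpG-PGx screen replayed on packaged tables
#>   CpG-PGx SNPs: 99 in 16 genes
#>   function tally: missense 61, intronic 25, 3'UTR 4, regulatory 4, synonymous 3, frameshift 1, splice 1
#>   hub gene: CYP2D6 with 4 of 7 factors
#>   GWAS pathway: top gene TET2 with 42 CpG-SNPs
```

A command-line wrapper with `classify`, `screen` (incl.
`--fixtures-only`), `simulate` and `report` subcommands is installed at
`inst/cli/cpgpgx`.

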