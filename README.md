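# lightsnp

SNP and short-indel (DIP) discovery from **light-coverage, multi-individual
Sanger sequencing**, with the resource statistics needed to turn a discovery
set into a genotyping resource.

When a genome is covered at only ~3-fold across several individuals, most
variant sites appear in a single read, so discovery must lean on base-level
evidence quality rather than genotype models. `lightsnp` implements the
**Neighborhood Quality Standard (NQS)** filter for this regime: a read base
is believed only when

- its own PHRED quality is ≥ 23,
- the five bases on either side all have quality ≥ 15,
- at least nine of those ten flanking bases match the consensus, and
- the neighborhood fits inside the read with no alignment gap crossing it,

and a *low upper limit* is placed on column depth (`max_depth = 8`), since
under light coverage a deep pileup is more likely a collapsed repeat than a
well-sampled locus. Qualified mismatches become per-read SNP records;
gaps ≤ 10 bp whose flanking bases both qualify become DIP records; records
merge into non-redundant sites keyed by (chromosome, position, type,
alternate allele) with the set of discovering individuals attached.
Per-individual SNP rates are reported as "one SNP per *x* bases", where *x*
= NQS-qualified bases / SNP records.

On top of the caller the package provides, all tibble-in/tibble-out:

- **Discoverer categories** A/B/C (A = discovered in an ordinary domestic
  individual; B = not only in the inbred reference animal; C = all), with
  per-chromosome count/spacing tables;
- **Windowed SNP densities** and **window-occupancy curves** (fraction of
  windows holding ≥ 1 SNP, by window size), with `autoplot()` methods;
- **Genotyping-panel design**: one category-A SNP per spacing window
  (nearest the midpoint), with B/C backfill for uncovered windows;
- **Validation arithmetic**: random candidate sampling, the 750-bp
  gap-distance testability filter, confirmation rates with the SNP and DIP
  denominator conventions, and informative-marker (singleton vs multi-cat)
  fractions with extrapolation;
- a **synthetic data generator** that emulates an eight-cat survey — six
  domestic breed cats at ~1 het site/600 bp, one inbred cat whose genome is
  ~60% homozygous tracts, one divergent wildcat — with fosmid paired-end
  Sanger-style reads (~37 kb inserts, <10% CV, PHRED-calibrated errors) and
  a full truth catalog, so the entire pipeline runs and is tested without
  any external data. Standard formats (FASTA/FASTQ/SAM/VCF/BED/bedGraph)
  round-trip through the package's readers and writers.

## Worked example

```r
library(lightsnp)

pm    <- population_model(genome_length = 1e6)   # desk-scale default: 8 cats
truth <- simulate_population(pm, seed = 7)
rs    <- simulate_reads(truth, read_model(insert_mean = 30000), seed = 7)
cs    <- call_variants(rs$reads, truth$assembly)
sites <- categorize(merge_sites(cs), individuals = truth$individuals$name)

snp_rate_table(cs, rs$reads, truth$assembly)
#> # A tibble: 8 × 4
#>   individual nqs_bases snp_count bases_per_snp
#> 1 Pixel          72376       193           375
#> 2 Zeelie         64577       133           486
#> 3 Tipper         59514       146           408
#> 4 Scooter        65913       160           412
#> 5 Speedy         69734       181           385
#> 6 Cocoa          65201       141           462
#> 7 Nancy         300161      1159           259
#> 8 Cinnamon     1802309       653          2760
```

The rate table already shows the survey's structure: the wildcat Nancy has
the highest discovery rate (one SNP per 259 NQS bases — she diverges from
the domestic consensus), the six domestic breeds cluster around one per
~400–500, and the inbred reference cat Cinnamon is lowest by an order of
magnitude (one per 2760): she founded the consensus and 60% of her genome is
homozygous, so her reads rarely disagree with it.

```r
panel_summary(design_panel(sites[sites$type == "SNP", ],
                           truth$assembly, spacing = 15000))
#> # A tibble: 1 × 5
#>   n_assays   n_A n_backfilled covered_fraction mean_gap
#> 1       67    67            0                1   14956.
```

At this site density every 15-kb window holds a category-A SNP, so the
panel needs one assay per window (67 for 1 Mb) and no backfill; the mean
inter-assay gap approaches the spacing. `run_pipeline(pipeline_config())`
chains simulate → call → stats → panel → validate and writes every artifact
(VCF, rate and category tables, bedGraph densities, occupancy curves, panel
BED, validation report) to one output directory, byte-identically for a
fixed seed.

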