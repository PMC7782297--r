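# ystrtools

Y-chromosome STR haplotype analysis for patrilineal surname and
founder-lineage studies.

Y-STR markers are male-specific and inherited father-to-son as a block, so —
barring mutation — males in one paternal line are identical by descent across
the panel, just as they share a surname. `ystrtools` implements the analyses
such studies run on 16-locus Yfiler haplotype tables:

- a haplotype data model that handles the duplicated locus **DYS385**
  (typed as an unordered allele pair) and duplicated patterns at nominally
  single-copy loci (e.g. a `{15,16}` genotype at DYS437), with a documented
  CSV dialect for reading and writing tables;
- **pairwise percent similarity**, `100 · m/k` where *m* of the *k* panel
  loci carry identical allele multisets, with full similarity matrices and
  identity-class detection (who shares a complete haplotype with whom);
- the ISFG **counting method** for haplotype match statistics:
  frequency = *X/N* (observations over database size), formatted as
  "1 in *n* individuals";
- **allele frequencies** (exact allele-set mode and per-allele carrier
  mode), modal alleles, **founder-signature matching** (e.g. the Dal Riata
  signature 13-25-14-11-13-16 over DYS393, DYS390, DYS19, DYS391, DYS389I,
  DYS389II) and per-locus **footprint sharing** against a published surname
  "genetic footprint";
- a **stepwise mutation model simulator** (symmetric ±1 repeat per event,
  configurable per-locus rates, star genealogies from founder haplotypes,
  unrelated samples drawn from allele frequency tables) for synthetic
  surname studies.

The haplotypes of a published O'Brien surname study ship as plain-text
fixtures: the surname group (`obrien`, N=10), a general Irish sample
(`irish`, N=10) and a mixed-ancestry control group (`control`, N=22),
plus the `dal_riata`, `obrien_footprint` and `sykes` founder signatures.

## Worked example

```r
library(ystrtools)

ob <- ystr_fixture("obrien")
percent_similarity(ob$members$OB8, ob$members$OB9)
#> OB8 vs OB9: 2/16 loci match, 12.50% similarity

identity_classes(ob)
#> <identity classes> 9 distinct haplotypes among 10 samples
#>   shared haplotype: OB5, OB6

haplotype_frequency(ob$members$OB5, ob)
#> <haplotype frequency> OB5 in 'obrien': X = 2, N = 10, X/N = 0.2 (1 in 5)

classify_population(combine_populations("obrien+irish", ob, ystr_fixture("irish")),
                    ystr_signature_fixture("dal_riata"), ignore = "DYS389II")
#> <signature classification> 'dal_riata': 3 of 20 samples match (ignoring DYS389II)
#>   matches: OB9, OB11, I9
```

OB8 and OB9 match at only 2 of 16 loci (12.50%): unrelated paternal lines
are easy to tell apart, the premise of Y-STR "dragnet" screening. OB5 and
OB6 — both with paternal origins in County Clare — are the only two males
sharing a complete haplotype, so that haplotype's counting-method frequency
in the group is 2/10, "1 in 5". Three of the twenty Irish-ancestry samples
carry the Dal Riata founder signature once the conventionally excepted
DYS389II locus is ignored.

A command-line interface over the same functions is installed at
`inst/scripts/ystr`:

```sh
Rscript inst/scripts/ystr matrix --fixtures obrien --out matrix.csv
Rscript inst/scripts/ystr classify --fixtures control --signature dal_riata --ignore DYS389II
Rscript inst/scripts/ystr simulate --fixtures obrien --founder-id OB1 \
    --generations 10 --mu 0.002 -n 100 --seed 1 --out lineage.csv
```

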