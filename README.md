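# dmcc — the DraI mtDNA COI-COII honey bee test, fully in silico

`dmcc` implements the classical honey bee (*Apis mellifera*) genotyping
marker — PCR of the mitochondrial COI-COII intergenic region followed by
DraI restriction (the "DmCC" test, a CAPS/PCR-RFLP assay) — as a pure
computation over Sanger consensus sequences. It is intended for honey bee
breeding programs, queen producers and population geneticists who already
sequence the extended COI-COII amplicon and want standardized,
reproducible haplotype calls instead of manual gel reading.

From a FASTA of amplicon consensus sequences (or any template, up to a
complete mitogenome) the package:

* locates primer annealing sites with mismatch tolerance and performs
  in silico PCR with the outer sequencing primers
  (COI_Seq-F `ACCACCTCTAGATCATTCACATTT`,
  COII_Seq-R `AGGATGGAACTGTTCATGAATGAA`);
* trims sequences precisely to the classical H2-E2 window (primers
  included, matching the physical amplicon the wet-lab test digests);
* digests in silico with DraI — or any registry-defined enzyme — with
  REBASE-style semantics (`TTTAAA`, cut `TTT^AAA`); overlapping sites are
  found, and ambiguous sequence bases never produce phantom cuts;
* calls the evolutionary lineage (A / M / C / O) from the trimmed length
  against configurable bins, and the haplotype/subspecies by matching the
  visible fragment ladder against a YAML registry of reference patterns;
* reports SNPs and indels against the matched reference haplotype —
  which, per the DmCC naming rule, never by themselves change a
  haplotype name;
* renders deterministic virtual gels (SVG or text) with the samples
  beside the registry reference lanes and a C2-pattern ladder.

The haplotype-calling model in brief: fragments are paired in descending
(ladder) order; a registry entry matches when counts agree and every
`|obs - exp|` is within `max(absolute_bp, relative * exp)` (defaults 3 nt
/ 2%); minimal summed deviation wins, exact ties break alphabetically
with an `AMBIGUOUS_TIE` flag, and unmatched patterns are `NOVEL`. Band
mobility on virtual gels follows `m(L) = clamp(a - b log10 L, 0, 1)`,
auto-scaled per gel.

## Worked example

The package ships a fully synthetic example registry and four synthetic
"queen" samples (`inst/extdata/`). Entry names mirror the classical
reference panel (C1, C2, C3, A2, Z1) but every sequence, fragment size
and primer in the example is generated — see the registry header for how
to populate a real one.

```r
library(dmcc)
fasta <- system.file("extdata", "example_samples.fasta", package = "dmcc")
reg   <- system.file("extdata", "example_registry.yaml", package = "dmcc")
res <- run_dmcc(run_config(fasta, reg, out = "report.tsv", gel = "gel.svg"))
res$table
```

```
 sample_id trimmed_length lineage haplotype             subspecies distance
   queen_a            620       C        C2 synthetic carnica-like        0
   queen_b            620       C        C2 synthetic carnica-like        0
   queen_c            620       C        C2 synthetic carnica-like        0
   queen_d            620       C        C2 synthetic carnica-like        0
 fragment_lengths_desc n_snps            snps flags
        247,218,110,45      1          87:G>T
        247,218,110,45      2 175:C>A;492:A>C
        247,218,110,45      0
        247,218,110,45      1         395:C>G
```

Reading the output: all four samples trim to a 620 nt H2-E2 window, which
falls in the registry's C-lineage length bin; their DraI ladders
(247/218/110/45 nt) match the C2-like entry exactly (distance 0 nt), so
they are called C2 with its subspecies label — while the per-sample point
substitutions (e.g. `87:G>T`, 1-based window coordinates) are reported
but, by the DmCC rule, do not affect the haplotype name. `report.tsv`
holds the same table; `gel.svg` shows the four sample lanes beside the
five reference lanes and the C2 ladder.

The same run from the shell:

```sh
exec/dmcc type --fasta inst/extdata/example_samples.fasta \
  --registry inst/extdata/example_registry.yaml \
  --out report.tsv --gel gel.svg
```

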