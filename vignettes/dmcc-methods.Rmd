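---
title: "The in silico DmCC test: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The in silico DmCC test: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcc)
```

## The problem

The DraI mtDNA COI-COII test ("DmCC") is the workhorse marker for
identifying honey bee (*Apis mellifera*) maternal evolutionary lineage,
haplotype and subspecies. The wet-lab protocol amplifies the mitochondrial
COI-COII intergenic region with the classical H2/E2 primer pair, digests
the amplicon with DraI (TTT^AAA), and reads two gels: the amplicon length
class on agarose gives the lineage (A, M, C or O), and the DraI fragment
ladder on polyacrylamide gives the haplotype, which maps to a subspecies
label (e.g. C1 is characteristic of *A. m. ligustica*, C2 of
*A. m. carnica*). By convention, a haplotype is defined *only* by its
visible fragment pattern: point substitutions that do not create or
destroy a DraI site do not name a new haplotype.

Sanger sequencing of the full H2-E2 window makes the whole readout
computable. Because sequencing primers cannot read their own annealing
sites, an outer primer pair is used (COI_Seq-F
`ACCACCTCTAGATCATTCACATTT`, COII_Seq-R `AGGATGGAACTGTTCATGAATGAA`,
binding in COI and COII beyond the H2-E2 region and yielding an extended
amplicon of roughly 820 bp for C-lineage templates); the consensus is then
trimmed precisely back to the H2-E2 edges before the in silico digestion.
This package implements that entire in silico pipeline:

1. in silico PCR with the outer primer pair (`amplify()`);
2. (sequencing happens in the lab; its consensus FASTA is our input);
3. trimming to the H2-E2 window (`trim_to_window()`);
4. in silico DraI restriction, haplotype calling and virtual gel
   visualization (`digest()`, `match_pattern()`, `render_gel()`).

## Sequence model and coordinates

Sequences are uppercase IUPAC DNA; `U` is accepted and mapped to `T`
(RNA-style exports), alignment gaps (`-`) are stripped with a warning, and
everything else is a parse error naming the record and position. All
internal coordinates are 0-based half-open; only human-readable report
fields (the `snps` column) are 1-based. Templates are always treated as
linear: even when the source is a circular mitogenome, the COI-COII locus
does not span the origin, so circular digestion is deliberately out of
scope.

## Primer matching

Primer sites are found by ungapped sliding-window comparison on both
strands, counting IUPAC-incompatible positions (two symbols are compatible
when their base sets intersect). The default mismatch allowance is 1 for
all primers: Sanger consensus errors near primer ends are common enough
that exact matching is brittle, while 2+ mismatches on a 20-24 nt anchor
begins to admit spurious sites. Indels inside a primer footprint are not
modelled; they are rare in consensus sequences and would break the exact
footprint arithmetic that the rest of the pipeline relies on.

Trimming returns the window *including* the H2 and E2 footprints, because
the physical amplicon that the classical test digests includes its
primers; excluding them would shift every terminal fragment size relative
to the published gel patterns. Trimming is idempotent and
orientation-insensitive (`trim(revcomp(x))` equals `trim(x)`), and any
ambiguity — a primer missing, or more than one candidate window — is a
hard error rather than a silent best guess.

## Restriction model

An enzyme is a recognition motif plus a top-strand cut offset (DraI:
`TTTAAA`, offset 3, palindromic — standard REBASE semantics, stored in the
registry so other CAPS enzymes can be swapped in). Site scanning reports
every occurrence including overlapping ones, and scans the reverse-strand
motif for non-palindromic enzymes.

Ambiguity is handled asymmetrically, and this is a deliberate contract:

* a degenerate base in the **motif** matches by IUPAC base sets;
* a degenerate base in the **sequence** is conservative — a site is
  reported only when *every* concrete resolution of the observed symbol
  matches. A low-quality `N` from Sanger base calling therefore never
  produces a phantom cut.

Fragments tile the sequence exactly (their lengths always sum to the
input length) and keep their coordinates, so SNPs can later be located
within fragments. Gel-facing outputs drop fragments below `min_visible`
(default 15 nt: shorter fragments are not resolved on 7.5%
polyacrylamide); the threshold is registry-configurable and echoed in
reports.

## Haplotype calling

The registry (YAML) carries the primers, the enzyme, inclusive lineage
length bins for the trimmed window, the matching tolerance, and the
haplotype entries (name, lineage, subspecies label, descending expected
fragment sizes, optional reference window, optional accession). Loading
validates everything, including a self-consistency check that digesting
each entry's reference reproduces its `expected_sizes` exactly.

Lineage is the unique bin containing the trimmed length (`UNRESOLVED`
otherwise — a value, not an error). Pattern matching pairs fragments in
descending order, the way ladder lanes are read on a gel; a candidate
matches when the counts agree and each `|observed - expected|` is within
`max(absolute_bp, relative * expected)`. Defaults are `absolute_bp = 3`,
`relative = 0.02`: Sanger-derived sizes are exact, so the tolerance mainly
absorbs trimming-edge ambiguity; both knobs are registry data. Among
matches the smallest summed deviation wins; exact ties break
alphabetically *with* a mandatory `AMBIGUOUS_TIE` flag, so output is
deterministic and never silently guessed. No match yields `NOVEL` with the
distance to the nearest pattern for diagnostics. When the length-bin
lineage and the matched entry's lineage disagree, the call is flagged
`LINEAGE_CONFLICT` rather than silently overridden.

SNP reporting honours the naming convention: substitutions and indels
relative to the matched reference are listed in the report but never
influence the haplotype name. Two executable consequences are tested
package-wide: a mutation that leaves the site set intact changes the SNP
report but never the name, and a mutation that destroys a site always
changes the fragment pattern. SNPs come from an end-to-end global
alignment (match +1, mismatch -1, affine gaps costing 4 to open plus 1
per gapped position — a length-L gap costs 4 + L) followed by a column
walk; positions are reported in reference coordinates, with insertion
placement following the aligner's convention when runs of identical bases
make several placements equivalent.

Structure annotation locates the region's elements (COI 3' stub,
tRNA-Leu, the non-coding Q fragment, COII 5' stub) by best local alignment
of registry exemplars, keeping hits above 80% identity that cover at
least 30% of the exemplar (the window legitimately truncates the flanking
gene stubs); overlaps resolve to the higher-identity element.

## Virtual gels

Band mobility follows the standard log-size model
`m(L) = clamp(a - b * log10 L, 0, 1)`. The constants are auto-fitted per
gel so the largest and smallest visible bands land at 5% and 95% of gel
height — the readable-gel intent, made deterministic. Rendering (SVG or a
fixed 40-row text grid) is a pure function: no timestamps, no random ids,
byte-identical output for identical input. A reference ladder lane built
from the registry's C2-like entry is prepended when one exists, mirroring
how published virtual gels are laid out against the C2 pattern ladder.

## The synthetic-fixture generator

Real reference material (published H2/E2 primer sequences, published
fragment sizes, reference accessions) is user data; the package must be
fully testable without it. The generator emulates the locus's structural
organization with exact, machine-readable truth:

* a trimmed window `H2 | COI 3' stub (60 nt) | tRNA-Leu (70 nt) |
  Q fragment (250 nt) | COII 5' fill | revcomp(E2)`, 600 nt by default,
  with DraI sites planted only inside the Q region — where the real
  polymorphic sites sit;
* optional COI/COII pads (110 nt each) carrying the real outer primer
  sequences, making the default extended amplicon exactly 820 bp;
* a mitogenome-scale stand-in (16,343 nt) embedding one such locus, used
  to exercise template-scale in silico PCR. It is explicitly a synthetic
  stand-in for a reference mitogenome, not a model of real base
  composition.

Backgrounds are uniform over A/C/G/T, and any draw that would introduce
an unplanted recognition site or a spurious primer hit (within 1
mismatch) is rejected and redrawn, so truth records are exact by
construction. Synthetic registries place 2-4 sites per entry at least
30 nt apart (every fragment stays visible), and re-draw any entry whose
visible pattern comes within twice the matching tolerance of an existing
one. Planted SNPs are constrained to be pattern-neutral: never inside a
primer footprint or a planted site, never creating a new site.

What passing these tests shows — and does not show. They demonstrate that
the pipeline's arithmetic, matching and reporting are exact on sequences
that obey the model (substitution-only noise, unambiguous primer sites,
exact patterns). They do not exercise real-data pathologies: heteroplasmy,
indel-rich low-quality consensus ends, primer sites diverged beyond one
substitution, or registry patterns measured by eye from historical gels.
The tolerance knobs exist for the last of these.

## Problem sizes and numerical choices

The shipped verification suites use the following sizes, chosen to give
each property enough random exposure to be convincing while staying
quick to re-run: 1,000 random sequences up to 5 kb against a brute-force
regex digestion oracle (also checking fragment-length conservation), 100
seeded registries for the round-trip property, 500 + 500 mutations for
the SNP-neutrality/site-destruction pair, and 100 end-to-end samples with
a full byte-identical re-run for determinism. All randomness is seeded;
the same seed reproduces every file byte for byte.

Degenerate inputs are policy, not accidents: an empty observed pattern is
an error (there is nothing to match), an all-below-threshold digest
returns an empty visible ladder with a warning flag, a missing reference
makes the SNP list empty with a note rather than failing the sample, and
a corrupt record in a batch is flagged `NO_WINDOW` while the run
continues (exit status 1 instead of 0).

## Known limitations

* No chromatogram (AB1) parsing; inputs are base-called consensus FASTA.
* No primer thermodynamics, dimer or chimera modelling; annealing is
  ungapped substitution-counting.
* No partial digestion, methylation sensitivity or star activity.
* Circular templates are digested as linear.
* The shipped example registry is synthetic; real genotyping requires a
  registry populated with the published H2/E2 primers and haplotype
  patterns, or references digested with the tool itself.
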