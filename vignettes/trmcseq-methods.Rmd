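---
title: "Calling tRNA ac4C from reduction-and-misincorporation sequencing: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tRNA ac4C from reduction-and-misincorporation sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trmcseq)
```

## The assay and its signal model

N4-acetylcytidine (ac4C) is written onto tRNA and rRNA by the
acetyltransferase NAT10. Sodium-cyanoborohydride reduction converts ac4C
into a base that reverse transcriptase misreads, so a modified cytidine
leaves a **C→T misincorporation** at its exact position in the sequencing
reads. The assay runs three chemistry arms on the same RNA:

* **reduced** — NaCNBH3 treatment; ac4C sites show the C→T signature;
* **deacetylated** — mild alkali strips the acetyl group before reduction,
  so the signature cannot form; this is the matched negative control;
* **mock** — untreated; guards against RT artifacts unrelated to the
  chemistry.

For tRNA, a small-RNA-enriched variant (TRMC mode) sequences essentially
full-length molecules after AlkB demethylation; for total RNA the input is
fragmented (total-RNA mode, also used for rRNA). Both modes share the same
downstream analysis: align with a strict mismatch cap, pile up per-position
base counts, and compare misincorporation rates across the three arms.

At a position with sequencing depth $d$ and reference base C, the
misincorporation rate is $m = 1 - n_C/d$ and the C→T rate is $n_T/d$. A
modified site is expected to satisfy $m_\mathrm{reduced} \gg
m_\mathrm{deacetylated} \approx m_\mathrm{mock} \approx$ background, with T
the dominant alternative base.

## The decision rule and its thresholds

The three-arm design fixes the comparison but not the cutoffs, so the
cutoffs are this package's documented defaults ([site_params()]), chosen
for binomial detectability rather than fitted to any dataset:

| parameter | default | why |
|---|---|---|
| `min_depth` | 50 / condition | below this, binomial noise on a 5% rate swamps the signal |
| `min_rate` | 0.05 | reduced-arm misincorporation floor |
| `min_delta` | 0.05 | margin over max(deacetylated, mock); keeps RT artifacts out |
| dominant alt | T | the chemistry's signature base |
| `fdr` | 0.05 | Benjamini–Hochberg across all candidate C positions |

The test is a **one-sided exact conditional test** (hypergeometric tail) on
the 2×2 table of (mismatch, match) counts, reduced versus deacetylated.
Deacetylated — not mock — is the tested control because it shares the
reduction treatment and therefore every treatment-induced artifact; mock
enters only through `min_delta`. Fractional alignment weights make counts
non-integral, so they are rounded to the nearest integer before the exact
test. The same machinery, two-sided and restricted to a provided site list
(its own BH family), tests knockdown-versus-control differential
modification.

## Alignment and multi-mapping

tRNA references are tiny and the signature is substitutional, so the
aligner is an exhaustive **ungapped** scan of every read against every
isodecoder group at every offset, keeping hits at the read's minimum
mismatch count when that minimum is ≤ 2 (the published cap). Indels are
deliberately unsupported; this is a documented limitation, not an
oversight. Identical mature sequences are collapsed into one isodecoder
group before alignment, and a read tying across $k$ distinct groups
contributes weight $1/k$ to each — deterministic pileups, unbiased rates,
no random assignment. External SAM/BAM is ingested through Rsamtools with
the same cap (NM tag, or recomputed for ungapped records).

Coordinates are 1-based on the mature sequence **including the 3' CCA
tail**, which is completed during loading by appending only the missing
suffix of `CCA`. Whether the printed site subscripts follow Sprinzl
canonical numbering or linear coordinates is not stated anywhere we could
check; this package uses linear coordinates throughout and documents that
assumption. Histidine G-1 is not added by default (`add_his_g1 = FALSE`)
so that default coordinates are predictable.

## What the simulator states, and what it does not

The generator ([simulate_library()]) emits, per reference, a configured
number of reads; under the reduced condition each embedded site draws C→T
with its site rate, and optionally an RT-stop truncating the read just
before the site. Background substitutions hit every base independently at
0.002 (typical Illumina scale, uniform over the three alternatives);
deacetylated and mock arms are statistically identical background, because
mild alkali removes the acetyl group before reduction. Truncated reads
shorter than 15 nt are dropped, mirroring adapter/length filtering. All
randomness flows from one seed; identical configurations are byte-identical.

The synthetic reference world ([synthetic_trna_set()]) carries the printed
site inventories: 13 sites on 13 isodecoders across 9 isoacceptors for the
total-RNA assay, and 17 sites on 16 isodecoders across 10 isoacceptors for
TRMC (adding positions 3, 50, 65 and the Val(AAC) isoacceptor). The
printed record names only one (isoacceptor, position) pair per isoacceptor
plus the totals, so the per-isoacceptor isodecoder multiplicities are this
package's allocation consistent with those totals — Ser(GCT), Leu(TAA),
Ser(TGA), Ser(AGA) and Arg(TCG) get two isodecoders where needed, and one
Ser(CGA) isodecoder carries both position 3 and position 12. Bodies are
random sequence with the anticodon at 34–36, a C at each site, and a CCA
end; leucine/serine bodies are 85 nt (long variable arm), others 76 nt.
The rRNA fixture is a labelled *synthetic* stand-in, not the real 18S.

A green simulation test therefore establishes that the pipeline recovers
*its own stated world* — exact chemistry, independent errors, no RT
sequence bias, no modification crosstalk (real tRNA carries dozens of other
modifications that AlkB only partially removes), no ligation or PCR bias,
and no real multi-mapping structure beyond identical isodecoders. It does
not establish performance on real libraries.

## Ribosome profiling readouts

Footprints of 26–32 nt whose 5' end plus the P-site offset lands in frame
0 are retained; everything else is dropped. The offset is fixed at **12 nt
for all lengths** (the canonical elongating-ribosome value); the upstream
tool the original analysis used infers per-length offsets, but its rule is
not printed, and a fixed offset keeps results deterministic. Per-length
offsets can be supplied as a named vector. Occupancy counts A-site events
(the pause interpretation); a flag switches to P-site counting. Each
codon's occupancy is normalized by the **basal occupancy** — the mean count
at the +1/+2/+3 codons downstream of the same occurrences — so uniform
density gives exactly 1 everywhere. The first and last 5 codons of each
CDS are excluded (initiation/termination artifacts; a package choice), as
are occurrences whose downstream window would cross the stop.

TE (RPF/input) and TR (RNC/input) are per-gene ratios of CPM-normalized
counts, NA at zero input. Class thresholds (|log2| ≥ 1, unadjusted
two-proportion p ≤ 0.05) are configurable defaults; the published volcano
cutoffs are not printed. Codon-frequency bias across up/down/non classes
uses a Kruskal–Wallis rank test implemented from the rank definition (with
tie correction) and cross-checked against `stats::kruskal.test` in the
suite.

## Abundance and the published DE rule

Isodecoder-level weighted counts are CPM-normalized; fold change uses a
0.5 pseudocount on raw counts. The published analysis delegates testing to
a named negative-binomial package; only its stated decision rule — **P ≤
0.05 and fold change ≥ 1.5** (applied symmetrically, so FC ≤ 1/1.5 also
qualifies; the printed rule names no direction) — is reproduced here, on
top of a simpler documented test: a pooled two-sided Fisher test below 3
replicates per side, Welch's t on log2 CPM otherwise. The boundary is
inclusive on both axes and is pinned by tests.

## Numerical choices and degenerate inputs

* Exact one-sided p-values use the closed-form hypergeometric tail; the
  suite checks agreement with explicit `choose()` enumeration on all-scale
  tables ≤ 50 and with `fisher.test`.
* Rates are NA at zero depth; low coverage is a flag/verdict, never a
  silent exclusion.
* Ties in alignment are resolved by fractional weights, never randomly;
  within one reference the smallest offset is kept.
* Kruskal–Wallis returns NA when all values tie (tie correction hits zero),
  e.g. a focus codon absent from every CDS.
* Internal coordinates are 0-based half-open only inside the C++ kernel;
  everything user-visible is 1-based closed.
* Config serialization uses JSON rather than YAML/TOML (no offline
  YAML reader is available); the round trip is lossless and tested.

## Known limitations

Ungapped alignment only; substitution-only signature by default (stops are
emitted as diagnostics, never used in verdicts); single fixed P-site
offset; simulator realism as described above; no mitochondrial tRNA
numbering; no calling of modifications other than ac4C; no mRNA calling.
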