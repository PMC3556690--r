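---
title: "Methods: measuring the impact of a protein database transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring the impact of a protein database transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoshift)
```

## The problem

When a proteomics community retires one protein sequence database (here: the
International Protein Index, IPI) in favour of another (the UniProtKB
"complete proteome" sets), two distinct things are at risk:

* **Stored results** reference source accessions. If an accession has no
  counterpart in the target — or several — the stored identification is
  degraded.
* **Future experiments** search spectra against the target's theoretical
  peptide space. Any peptide derivable from the source but not from the
  target becomes unfindable.

`proteoshift` measures both risks, plus a third question the transition
raises: for the peptides that do disappear, is there actually experimental
evidence that they exist?

## Identifier mapping

Each source record receives exactly one outcome per algorithm, with status
`mapped` (one target), `multiple` (≥ 2) or `none` (0), so the three status
counts always partition the source database.

**Logical mapping** collects the accessions stored under the `SWISS-PROT` and
`TREMBL` cross-reference namespaces of the source header. Other namespaces
(Ensembl, RefSeq, Vega, H-Inv) can never name a UniProtKB entry and are
ignored. Isoform suffixes (`O95793-1`) are preserved losslessly by the
parser but collapsed to the parent accession before mapping, and several
isoforms of one parent count as a *single* candidate — otherwise every
multi-isoform entry would spuriously report `multiple`. The candidate set is
then intersected with the accessions actually present in the supplied target
FASTA: the target *universe* is deliberately the provided complete-proteome
set, not the whole of UniProtKB, because that is exactly the transition being
measured. Supplying a larger target FASTA widens the universe.

**Sequence mapping** indexes the target by exact full-length sequence and
looks the source sequence up. This mirrors identifier cross-referencing
services built on 100% sequence identity: a mapped identifier is guaranteed
to denote the identical protein sequence. Fragments or single-residue
variants do not match; no similarity threshold exists. Equality is plain
character equality on the uppercased sequence — no I/L folding — because any
folding would break the identity guarantee the method exists to provide.

## In silico digestion

Trypsin cleaves C-terminal of K or R except when the next residue is proline
(the Keil rule). This community-default rule is the package's only enzyme.
Ambiguity codes (B, J, O, U, X, Z) are carried as ordinary residues: they
occur in real database entries of that era and must digest without error, but
they are never cleavage sites and never suppress one, since only K, R and P
have defined roles in the rule.

With `missed_cleavages = k`, peptides are all concatenations of up to
`k + 1` consecutive fragments. The default is `k = 0`: at roughly 90,000
proteins per database, fragment counting alone already yields peptide totals
of the magnitude reported for human-scale builds (~4 million), whereas each
extra missed cleavage nearly triples the multiset; `k` stays configurable
for sensitivity analysis. Peptides are ordered by (start, end) and carry
1-based closed coordinates, so with `k = 0` concatenating a protein's
peptides reproduces its sequence exactly — a law the test suite checks on
every synthetic database.

Two length filters exist and are deliberately distinct:

* the **headline** search-space comparison is *unfiltered* — the lost
  fraction refers to the full distinct-peptide sets;
* before **evidence** lookup, peptides of six or fewer residues are removed
  (`min_length = 7`), because such short sequences are not confidently
  identifiable in standard MS pipelines.

## Lost peptides and detectability

With distinct sets $P_S$ (source) and $P_T$ (target), the lost set is
$P_S \setminus P_T$ and the headline loss is
$|P_S \setminus P_T| / |P_S|$. Both digests must use identical parameters;
the package refuses to compare mismatched digests.

For every protein with at least one *qualifying* lost peptide, the remaining
detectable sequence is

$$\frac{\left|\bigcup_{p \in Q \cap P_T} [\mathrm{start}_p, \mathrm{end}_p]\right|}{L},$$

where $Q$ is the set of its qualifying peptides (length ≥ the detectability
bound) and $L$ its length. Coverage is a residue-position union, so
overlapping peptides from missed cleavages are not double-counted; at
`missed_cleavages = 0` the union equals the sum of retained peptide lengths.
The detectability bound defaults to 7 residues for the same MS-observability
reason as the evidence filter; it is a separate, configurable parameter
because the two filters serve different stages. A protein counts as "not
represented at all" when its detectable fraction is exactly 0.

## Repository evidence

Evidence is abstracted as local TSV snapshots: PeptideAtlas and GPMDB report
only *proteotypic* peptides (a boolean), PRIDE reports a per-peptide distinct
experiment count. Absent rows mean "no evidence", never an error, because
snapshots are inherently partial. Two thresholds govern PRIDE and are both
explicit in the configuration: *presence* in the Venn partition means an
experiment count ≥ 1, while *inclusion* requires ≥ 5 — the Venn describes
evidence, the inclusion rule proposes database additions, and conflating the
two would overstate either. The PRIDE counts are defined as distinct
experiments, not distinct identifications. The inclusion rule is:
proteotypic in PeptideAtlas, or proteotypic in GPMDB, or ≥ 5 PRIDE
experiments; affected proteins are the union of the candidates' parents in
the source digest.

## The synthetic generator

`generate_pair()` emulates the paired inputs of a real transition study —
a source database in IPI dialect and a target in UniProtKB dialect — with
every deviation planted and recorded in a truth manifest:

| planted class            | logical status | sequence status | search-space effect |
|--------------------------|----------------|-----------------|---------------------|
| exact shared copy        | mapped         | mapped          | none                |
| mutated shared copy      | mapped         | none            | exactly 1 lost peptide |
| source-only ("lost")     | none           | none            | whole digest lost, fraction 0 |
| duplicated target pair   | mapped         | multiple        | none                |
| two valid xrefs          | multiple       | mapped          | none                |
| dangling xref            | none           | mapped          | none                |

Construction makes the manifest *exact* rather than probabilistic: all
sequences are globally distinct except the planted duplicates; source-only
proteins are redrawn until their tryptic peptides are disjoint from the
target's distinct set and include at least one peptide of ≥ 7 residues (so
they are affected, with fraction exactly 0); the mutated-shared mode places
one point substitution inside a unique qualifying peptide, choosing original
and replacement residues outside {K, R, P} so the cleavage pattern — and
hence every other peptide — is untouched, and records position, residues and
the lost peptide in the manifest.

Residues are drawn uniformly from the 20 standard amino acids, giving K+R a
combined ~10% frequency and mean tryptic fragments of ~10 residues,
comparable to real proteomes. The generator does **not** emulate real
amino-acid composition beyond that, nor isoform sequences, homologous (rather
than identical or point-mutated) shared entries, or the ~95% homology
clustering real merged databases use. Passing the recovery tests therefore
demonstrates that the pipeline's set arithmetic, mapping logic and coverage
computation are correct — not that real databases behave like the generator.

Default counts (140 shared, 10 mutated, 40 lost, 17 multi-xref, 3 dangling,
10 duplicated pairs, 30 target-only; lengths 60–600) were chosen once so the
logical mapping proportions land near a realistic human-scale transition
(~73% mapped / 8% multiple / 20% none) while keeping a full run in seconds.
Evidence defaults (proteotypic fractions 0.2%/0.3%, PRIDE presence 4% with
counts 1–8) echo the sparsity seen in real repository snapshots, where the
large majority of lost peptides have no evidence at all. The configured
`pride_presence` field exists because a single uniform count range cannot
express "rarely present, and when present, rarely above the inclusion
threshold"; presence and count are drawn separately.

All randomness flows from one integer seed through an isolated RNG scope
(`withr::with_seed`), so identical configurations produce byte-identical
FASTA and TSV outputs; evidence draws use a fixed offset of the seed so they
are independent of database generation.

## Numerical and formatting choices

* Coordinates are 1-based closed intervals everywhere.
* All outputs are deterministically ordered: peptides by (start, end),
  mapping targets and evidence records lexicographically, report rows in
  input order. Re-running a pipeline with identical inputs rewrites
  byte-identical files.
* Report TSVs render doubles with 4 decimal places; fractions are reported
  as fractions internally and as percentages in prose.
* Degenerate inputs fail loudly: empty sequences, duplicate accessions,
  malformed headers (with line number), mismatched digestion parameters and
  mixed-algorithm summaries are all hard errors rather than silent repairs.

## Problem sizes

The test suite and the acceptance script run entirely on generated data: the
default study configuration of 220 source / 237 target proteins (~6,000
source peptides), plus a 1,000-sequence randomized comparison of the digester
against a brute-force substring oracle at up to 2 missed cleavages. These
sizes exercise every code path while keeping a full validation run around
half a minute. The pipeline itself scales linearly in total sequence length
and handles proteome-scale FASTA (~10⁵ records) in minutes.

## Known limitations

* Only trypsin/Keil digestion; no semi-tryptic peptides, masses or
  modifications.
* Logical mapping sees only header-embedded cross-references; history files
  or external mapping tables are out of scope.
* The sequence algorithm is exact identity by design; near-identical
  isoforms map to `none`, which is the correct reading of the method but can
  undercount "morally mapped" entries relative to homology-based clustering.
* Evidence snapshots are static local tables; no live repository queries.
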