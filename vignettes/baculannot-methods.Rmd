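---
title: "Methods: annotating baculovirus genomes with baculannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating baculovirus genomes with baculannot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

baculannot re-implements, as a tested pipeline, the annotation and
comparative analyses that a baculovirus genome report performs on a newly
sequenced genome: ORF calling on a circular chromosome, early/late promoter
motif classification, detection of homologous regions (hrs) as arrays of
imperfect palindromic repeats, gene-parity collinearity analysis, and
conservation-tier classification. The package ships the published SujuNPV
(Sucra jujuba nucleopolyhedrovirus, GenBank KJ676450) annotation and tier
lists as fixtures, and a synthetic-genome generator that plants all of
these features with a ground-truth record, so every stage is testable
without network access.

# Coordinates and the circular genome

All user-facing coordinates are 1-based and inclusive on both ends, the
convention of published annotation tables. A feature's `start`/`end` are
the bounds of its span along the plus strand; a separate `strand` column
carries reading direction. The single dialect for origin-spanning features
is `start > end`; `genome_subseq()` and all interval arithmetic treat
positions modulo the genome length. The coordinate origin of a
nucleopolyhedrovirus genome is conventionally the adenine of the polyhedrin
start codon; `rotate_to_zero()` re-bases a genome accordingly and is exactly
invertible.

A+T content excludes `N` bases from the denominator; the packaged genome
record has none, so this only matters for draft input.

# ORF calling

An ORF is ATG through the next in-frame stop (TAA/TAG/TGA), the stop
included in the genomic span but excluded from the amino-acid length:
`aa_length = span/3 - 1`. This arithmetic is forced by the published table
(polyhedrin spans 1..741 and prints 246 aa). All six frames are scanned on a
doubled copy of the sequence so origin-crossing ORFs are found; a
candidate's modular span never exceeds the genome length. Every ATG yields
a candidate, so nested same-stop candidates are reported by `find_orfs()`
and collapsed later. Alternative start codons are not considered: the
published aa lengths are consistent with ATG starts throughout.

The selection criterion "at least 50 aa with minimal overlap" leaves the
overlap rule unstated. `resolve_overlaps()` implements a greedy
longest-first rule: candidates in decreasing aa length (ties: smaller
start, then plus strand), rejecting a candidate whose modular overlap with
any accepted ORF exceeds 75% of its own span. This keeps slightly
overlapping neighbours and removes nested calls, is idempotent, and the cap
is configurable. Coverage (`orf_coverage()`) uses modular interval union —
a base in two ORFs counts once. On the packaged table union coverage
computes to 87.6%; the published report prints 87.9% and 89.2% in different
places without stating a rule, so neither figure is asserted by the test
suite.

# Promoter classification

The upstream window is the 150 bp immediately 5' of the start codon on the
coding strand, excluding the ATG, wrapping the origin when necessary.
Within it, a late promoter is any DTAAG (D = A/G/T); an early promoter is a
TATA element with a CAKT (K = G/T) transcription-start motif 20-40 bp
downstream. Two conventions had to be fixed where the source material is
ambiguous:

* the TATA element defaults to the IUPAC pattern `TATAA` (the canonical
  baculovirus early element) and is configurable; early-promoter counts
  therefore depend on configuration and are reported, not asserted;
* the spacer is counted from the base after the TATA element's last base to
  the CAKT match's first base, inclusive bounds 20 and 40.

Both motifs must lie wholly inside the window; matches are found with
pattern-side-only IUPAC expansion; all occurrences are recorded and one
suffices for the call. Classes partition as E / L / EL / none and always
sum to the ORF count.

# Palindromy and hr detection

Palindromy of a sequence is its global-alignment identity to its own
reverse complement (scoring below). A perfect even-length palindrome scores
1; an odd-length one at most 98/99, since the centre base cannot pair.
Under gapped alignment random sequence does *not* score near zero: AT-rich
random 99-mers centre around 0.53 with a thin tail past 0.6. The default
seed threshold of 0.6 therefore admits a small fraction of background
windows, and the clustering stage is designed to be robust to them rather
than relying on the threshold alone.

`find_repeat_seeds()` scores every circular window of the unit length
(default 99 bp, stride 1) and merges qualifying windows to locally maximal
ones: in decreasing palindromy, keeping a window only if it overlaps no
already-kept one.

`cluster_hrs()` then builds the genome-wide repeat family:

1. **Provisional family.** The highest-palindromy seed anchors a reference;
   every seed is slid (up to half a unit, either strand) to its best
   alignment against it. Windows at or above 0.75 identity join the
   provisional family — random background sits near 0.55 and drops out
   here.
2. **Phase search.** In a tandem palindrome array the most palindromic
   windows often straddle unit junctions (a rotated palindrome aligns well
   with its own reverse complement), so the provisional phase can sit
   mid-unit. The family is slid over a full unit period; at each candidate
   phase members re-snap locally (inter-unit gaps vary by a few bases) and
   the phase whose column-stack consensus the members agree with best wins.
   Because re-snapping flattens the score near the optimum, residual ties
   are broken by agreement at exactly the slid positions, preferring the
   smallest shift. With fewer than two members the phase is taken as is.
3. **Placement.** The consensus at the chosen phase is rebuilt and units
   are placed by a dense identity sweep one and a half units around every
   member, greedily keeping non-overlapping positions by decreasing
   identity; a second sweep against the rebuilt consensus pins any residual
   one-base phase offset. Units below the family-identity floor
   (default 90%) are dropped; each unit's orientation is its better-scoring
   strand against the consensus, whose own strand is fixed by majority
   vote, ties toward plus.
4. **Regions.** Retained units within `max_gap` (default 300 bp; published
   arrangements are tightly tandem) chain into regions; regions need at
   least `min_copies` (default 2) units. Labels `hr1..hrN` follow genome
   order.

Region length is `end - start` *without* the customary +1: that is the only
convention under which the packaged hr coordinates reproduce the published
590-971 bp range and 3.7% coverage, and it is applied uniformly. On
mutation-free planted arrays recovery is base-exact; at 2% per-copy
mutation copy numbers remain exact while unit boundaries may jitter by one
base (an orientation-coupled echo of the one-base phase ambiguity).
`core_palindrome()` reports the longest run of consensus columns at or
above 99% conservation; note the default generator mutates copies
uniformly, so a planted conserved core (as real hr repeats show) must be
constructed explicitly when exercising this operation.

# Pairwise alignment and identity

All identities use one declared scoring scheme: global (Needleman-Wunsch)
alignment, match +1, mismatch -1, linear gap -1. Percent identity is
matched columns over alignment length. Among score-optimal alignments the
implementation selects the one maximising matches, then minimising length —
this makes identity well defined and symmetric in its arguments, which a
pure move-preference tie-break would not guarantee; residual traceback ties
prefer the diagonal, then the vertical move. The published identities were
produced by proprietary software with unstated defaults, so the packaged
identity columns are treated as data; recomputed identities are comparable
but not expected to match digit for digit.

# Comparative analyses

Homologue pairing from the packaged table parses each reference virus's
ordinal column (entries like ranges or names carry no usable ordinal and
are skipped) and enforces one-to-one pairing by keeping the
higher-identity claimant of a duplicated ordinal. Parity points plot each
pair's ordinals, the sign of y recording strand agreement. The longest
collinear run is the longest stretch of successive points with monotone y
and per-step |dy| at most `max_jump` (default 2, tolerating single-gene
inversions and drifts). Against HearNPV this run spans Suju59-Suju90 and
covers the published Suju60-Suju86 collinear region; against AcMNPV and
CpGV the same tolerance retains shorter cores of it, so only the HearNPV
case is asserted. Shared-gene counts tally rows with any recorded
homologue; independent tallies of the packaged table give 103 and 109 for
AcMNPV and HearNPV where the publication prints 102 and 108 — a one-row
transcription ambiguity documented rather than reconciled. Mean identity
averages only rows with a recorded identity.

Conservation tiers classify ORFs by name against the packaged lists
(37 core, 24 lepidopteran-conserved, 5 unique); everything else is
"common". Unique status is data, not computation.

# The synthetic-genome generator

`sim_params()` defaults *are* the study conditions: 135,952 bp, 61.34%
background A+T, 131 ORFs with the published 60/71 strand mix and
24 E : 61 L : 10 EL : 36 none promoter proportions, seven hr arrays of 4-8
copies of a 99 bp master unit at 2% per-copy mutation. Values the
published report does not fix were set once to field-plausible choices:
ORF lengths uniform on 50-250 aa (disjoint planting must fit the genome;
real baculovirus ORFs overlap, which the generator deliberately avoids),
inter-unit gaps 0-10 bp, master-unit palindromy 0.85 (a perfect palindrome
would make unit orientation unidentifiable; real hr repeats are imperfect).

Design constraints that make recovery testable:

* ORF bodies are uniform sense codons (composition fidelity inside genes is
  not a goal, hence whole-genome A+T sits below the background value);
* promoter windows are rejection-sampled until they classify exactly as
  planted, carry no ATG/CAT on either strand (no chance ORF can start
  inside a window), and end in a fixed in-frame TAA that blocks upstream
  start-codon extensions of the planted ORF;
* the master repeat unit contains no start triplet and a stop codon in all
  six frames, so ORFs cannot thread through arrays;
* after assembly, a repair loop disrupts every remaining chance ORF of
  >= 50 aa by writing an in-frame stop into non-feature sequence (re-drawing
  any promoter window it touches), iterating to a joint fixed point. The
  result is the stop-dense background on which ORF recovery is exact:
  precision = recall = 1 at mutation 0.

One integer seed drives all randomness; identical seeds give byte-identical
genomes. `corrupt_genome()` adds uniform substitutions outside planted
start/stop codons for robustness experiments. What the generator does not
emulate: codon usage and amino-acid composition, overlapping genes, partial
repeat units at array edges, indels, and any transcription-level signal
beyond the planted motifs — passing recovery tests therefore demonstrates
algorithmic correctness on the stated genome architecture, not performance
on real sequencing data.

# Problem sizes and numerical choices

The test suite runs the full pipeline once at the published genome scale
(135,952 bp) and otherwise uses 15-30 kb genomes, chosen to exercise every
code path several times per run. Oracle comparisons use a 20 kb genome for
ORF enumeration, 1,000 random windows for promoter classification, and
exhaustive alignment enumeration up to length 8. Alignment scores are
integers throughout; identity plateaus in the hr phase search are compared
with a 1e-9 tolerance. Degenerate inputs are defined: empty candidate sets
propagate as empty tables, a single repeat seed cannot form a region, and a
zero-length core-palindrome run is returned as such.

# Known limitations

* Ab initio reproduction of the published 131-ORF set from the raw genome
  is not claimed: the original gene finder applied internal criteria beyond
  the two stated ones, so the packaged table is the reference, and
  sequence-level reproduction is exercised on synthetic genomes instead.
* Early-promoter counts depend on the TATA-element definition, which the
  source leaves open; only the class partition is invariant.
* hr copy numbers on real genomes may count partial units, which this
  package does not call; only whole-unit placements are made.
* Detection thresholds (seed palindromy 0.6, family identity 90%) were
  chosen to separate near-identical repeat families from AT-rich random
  background and are exposed as parameters; strongly diverged repeat
  families would need them lowered.
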