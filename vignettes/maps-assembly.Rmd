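---
title: "Diversity-optimizing transcript assembly for proteogenomics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity-optimizing transcript assembly for proteogenomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`mapsr` turns spliced RNA-Seq alignments into a protein database for
shotgun-proteomics searching. Its design premise is specific to
proteogenomics: because every candidate peptide must later survive
spectral matching, the assembler should err toward *diversity* — keeping
rare isoforms, retained introns, weakly covered transcripts — and let the
proteomics evidence carry the false-positive burden. This inverts the
economy of general-purpose assemblers, which minimize assembly false
positives at the cost of recall.

The pipeline has four stages.

**1. Alignment ingestion.** Primary alignments are split into
reference-consuming blocks at N CIGAR operations; deletions are absorbed
into the surrounding block with `N` placeholders (they contribute no
consensus counts), insertions and clips consume no reference. Reads
reported at more than one locus (NH > 1 or secondary records) are removed
before they can touch any tally: coverage, junctions and consensus all see
unique mappers only. Library strand follows the fr-firststrand convention
(the read aligns antisense to its transcript); `secondstrand` and
`unstranded` modes are available. All internal coordinates are 0-based
half-open; SAM and GTF conventions are converted only at the file
boundary.

**2. Junction/exon graph.** Spliced gaps of at least `min_intron` (20 nt;
smaller gaps are treated as alignment deletions, the usual aligner
convention) are tallied into junctions keyed by donor end, acceptor start
and strand. Junctions are filtered by: read support
(`min_junction_reads`, default 2, boundary inclusive); intron length
(`max_intron`, default 1,000,000 nt — biologically implausible introns
above the cap are removed, the cap itself is retained); and endpoint
plausibility — among junctions sharing one endpoint whose free endpoints
fall within `endpoint_window` (10 nt) of each other, only the
best-supported survives. The window rule is one concrete reading of
"keep only the most probable intron endpoints"; it targets the
few-nucleotide donor/acceptor wobble produced by alignment artifacts
while leaving genuinely distinct junctions (further apart than the
window) untouched.

Coverage contigs are the maximal regions of positive depth per contig and
strand after bridging zero-coverage gaps of at most `max_fill_gap` (50 nt)
flanked by coverage on both sides. Every contig is cut at every retained
junction point inside it, and one candidate exon is emitted per pair of
boundary choices (contig edge or junction point) per side — the "all
possible exons" set — except that no candidate may overlap the intron of a
retained junction on its strand. Variants that fully contain an intron are
intron-retention candidates: they are emitted and flagged only when
`emit_retained_introns` is on (off by default, to keep the database size
controllable; the flag exists because low-abundance retained introns are
one of the transcript classes a diversity-first assembler should be able
to keep). Expression X(e) is the overlapping read count per kilobase.
Candidates below `min_exon_support` (1 read/kb) are dropped, and
junction-less candidates shorter than `short_single_exon_len` (1000 nt)
must reach `short_single_exon_support` (4 reads): without that rule the
database is dominated by short single-exon noise.

**3. Greedy assembly.** From each seed exon (an exon whose start is no
retained junction's acceptor; `seed_all` seeds from every exon, which
recovers transcripts whose 5' exon is under-covered) a chain grows by two
alternating argmax steps: the next endpoint maximizes normalized junction
support times a distance weight,

    score(p) = C(E,p) / sum_f C(E,f) * w(D(E,p)),

and the next exon is the X(e) argmax among candidates starting at the
chosen endpoint. The direction of the distance term is genuinely
ambiguous: read support should dominate, but a distance *reward* favors
implausibly distal acceptors, while splice biology and artifact
suppression favor proximal ones. `mapsr` therefore makes w(D) a switch
(`distance_weight`): `"inverse"`, w = 1/(1 + D/d0) with d0 = 10,000 nt, is
the default (proximal preference); `"linear"` (w = D, distal preference)
and `"none"` are provided, and the greedy-vs-oracle acceptance property is
checked under the default. Ties break deterministically: normalized
support, then weight, then leftmost coordinate; exon ties break to higher
X, then the longer exon.

Combinatorial explosion is controlled by two probability-based filters:
secondary endpoints spawn branches only when their normalized support
reaches `branch_cutoff` (0.15), and at most `max_per_seed` (16) chains are
emitted per seed, explored best-first so the first chain is always the
pure greedy one.

**4. Stringency filtering.** Assembled transcripts are walked in order of
decreasing exon count. A transcript is dropped when its mean exon
expression falls below `stringency * base`, where `base` defaults to the
median X(e) over all candidate exons so the threshold scales with
sequencing depth; or when its internal junction chain is a subset of an
already-accepted transcript's chain and its mean expression is below
`stringency` times that transcript's. Junction chains are compared as
sets of internal splice points; terminal exon boundaries are deliberately
excluded (coverage endpoints are noisy), and single-exon transcripts,
having no internal structure, are never dropped as "similar". This filter
is provably monotone: raising s can only shrink the accepted set, because
a transcript dropped for similarity has strictly lower expression than
its accepting transcript, so whenever the accepter later falls to the
expression threshold the dropped one falls with it. Transcript count and
total nucleotides are therefore non-increasing in s, with s = 0 the
maximal-diversity assembly — this is the package's tunable size/diversity
dial, and the default s = 0.3 balances recovery against database size on
the bundled simulations.

# Translation, consensus, and ORF extension

A per-position consensus is tallied from the aligned bases of unique
mappers, pooled across strands (a genomic substitution is
strand-symmetric). A position is called only at coverage ≥ `min_cov` (5)
and majority fraction ≥ `maj_frac` (0.8); ties are never called. The
thresholds are set to suppress sequencing-error miscalls at typical depth:
at 0.2% per-base error, an erroneous majority at 5× is vanishingly rare,
while a true homozygous SNP is essentially always called. Only
substitutions are modeled — read indels relative to the reference would
shift coordinates globally and are out of scope.

Each assembled transcript is spliced out of the consensus-corrected
genome (reverse-complemented for minus-strand transcripts) and translated
in the three sense-strand frames; stranded libraries make the sense
strand known, so antisense coding is handled by assembling the antisense
transcript itself rather than by reverse-frame translation (`six_frame`
exists for unstranded data). Stop-free stretches are extracted per frame;
codons containing N translate to X, which is not a stop. A stretch
touching the transcript 5' or 3' terminus in its frame is extended along
the genome from the terminal exon — no splicing is imputed beyond the
transcript — codon by codon to the nearest in-frame stop, up to `max_ext`
(10,000 nt) per side; the 5' extension stops one codon after the upstream
in-frame stop, so an upstream ATG revealed by the extension becomes
assignable as the true start. Hitting the contig edge or the cap
truncates the extension and sets a boundary flag; the acceptance suite
asserts every extended ORF ends at a stop or carries that flag. ORFs
shorter than `min_orf_aa` (8 aa, about the shortest useful tryptic
peptide) are not reported.

Every ORF record carries both its consensus translation and its
reference-genome translation of the same genomic span. The two differ
exactly at SNP-altered residues, which gives the mutant-exclusion logic a
clean form: a detected peptide whose reference-translation version occurs
in the reference proteome is a sample-specific mutant of an annotated
protein and is excluded from the novel list.

# Peptide annotation

Peptide matching folds I onto L throughout (isobaric residues are
indistinguishable to the MS workflow). Peptides found verbatim in the
reference proteome are labelled annotated; survivors are mapped onto the
ORF database (a peptide hitting no ORF is kept, flagged unmappable);
SNP-explained peptides are flagged as mutants; the rest get a start codon
by the standard decision tree: the upstream-most in-frame ATG at or
upstream of the peptide; else the upstream-most near-cognate codon (all
nine single-nucleotide substitutions of ATG) in a Kozak context; else the
ORF is stop-bounded. The Kozak test defaults to the weakest standard
criterion — purine at −3 *or* G at +4 — to avoid over-filtering;
`kozak_mode = "both"` tightens it. smORF status uses the 150-codon rule,
exclusive: 149 codons from the assigned start (or stop-to-stop for
stop-bounded ORFs) is a smORF, 150 is not.

# Evaluation

Two transcript sets are compared by exon overlap: a transcript is
recovered when at least one of its exons intersects an exon of some
transcript in the other set by ≥ 1 nt on the same contig. The rule is
strand-silent by default (matching its printed definition; a strand-aware
switch exists). Recall is recovered reference transcripts over all
reference transcripts; precision is matched assembled transcripts over
all assembled. A reference transcript counts once regardless of how many
assembled transcripts hit it. The production path uses interval overlap
queries and is tested against a quadratic brute force.

# The simulator: what it emulates, what it does not

The bundled generator is the package's test surface: a single-contig
genome with non-overlapping genes (multi-exon, compact: exons 120–400 nt,
introns 80–800 nt), log-normal expression (median 30×) with a floor
(10×) so every transcript is in principle assemblable, stranded
single-end 76 nt reads with uniform substitution errors (0.2% by
default), and designed sequence written back into chosen genes: annotated
CDSs whose proteins form the reference proteome, single-SNP nonsynonymous
mutants of those (reads carry the alternate allele; the genome FASTA
keeps the reference), novel smORFs of each start class built from codons
that are neither stop, ATG, nor near-cognate (so the intended class is
unambiguous; a planted near-cognate start gets its Kozak context from G
at +4, since the stop codon immediately upstream forces T at −3), and
ORFs cut by the transcript boundary whose continuation lives in the
genomic flank. Truth tables record every planted item, and one peptide is
drawn per planted protein (covering the mutated residue for mutants).

Deliberate simplifications: reads are single-end (pairing adds no
information this assembler uses — strand comes from the flag, support
from the blocks); fragmentation is uniform with no GC, PCR-duplicate or
fragment-size modeling; errors are uniform substitutions; expression is
i.i.d. log-normal. Passing tests therefore demonstrate the algorithmic
contracts — recovery under the exon-overlap rule, SNP propagation,
extension and classification logic, monotonicity, determinism — not
performance on real libraries with biased coverage, paired-end fragments
or indels.

Problem sizes in the shipped tests and acceptance script were chosen to
exercise every code path at desk scale: the recovery experiment uses 50
genes (~3 Mb of genome, ~35,000 reads), the SNP experiment plants 10
mutations at ≥ 10× pure-alternate coverage, and the annotation experiment
plants 5 novel smORFs among 20 annotated proteins with 3 single-SNP
mutant decoys. The designed-fixture experiments use error-free reads and
a tight coverage distribution (floor 15×, sdlog 0.3) so that every
planted gene clears the default stringency threshold and the expected
counts are exact; the recovery experiment keeps the realistic wide
distribution, which is why its recall is high but not 1.

# Numerical and degenerate-input choices

Identical inputs and configuration give byte-identical outputs: every
tie in the assembler breaks on explicit deterministic keys, transcript
identifiers are assigned after a genomic sort, and volatile header lines
(date stamps) are stripped from exported GTF. Empty inputs are legal
everywhere: an empty transcript set writes a valid header-only GTF, an
empty ORF set a valid empty FASTA; evaluation against an empty reference
reports NA rather than dividing by zero. Consensus application is
idempotent. A cycle in the junction graph is impossible by construction
(junction distance is strictly positive), so chain growth always
terminates.

# Known limitations

No probabilistic abundance estimation (no EM over isoforms) — X(e) is a
raw length-normalized count, and shared exons accumulate support from all
overlapping transcripts, which inflates the expression-threshold base in
dense loci. No indel-aware consensus, no fusion/chimeric junctions, no
de novo (genome-free) mode. The endpoint-plausibility window and the
distance-weight direction are documented judgment calls exposed as
configuration, not settled facts. The annotation stage reimplements the
reference-database search as exact in-memory substring matching (with I/L
folding); it does not perform alignment-based homology search, so a
peptide differing from an annotated protein by more than its planted
SNPs will not be attributed to that protein.
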