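---
title: "Linking ophthalmic imaging archives to a registry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking ophthalmic imaging archives to a registry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculink)
```

## The problem

Ophthalmic practices accumulate millions of DICOM files — OCT volumes,
fundus photographs, autofluorescence, angiography — while the clinical
context for those images (diagnoses, visits, demographics) lives in an EHR
registry. Neither side carries a shared key. What both sides do carry are
ordinary patient identifiers: name, birthdate, gender, a practice-local
medical record number (MRN), and the practice itself. `oculink` implements a
deterministic, auditable pipeline that links the two sides at the patient
level using exactly those identifiers, then propagates patient links to
every image and to OCT key-measurement documents, masks protected health
information (PHI), and reports linkage quality.

Deterministic linkage was chosen over probabilistic (Fellegi–Sunter style)
scoring deliberately: after harmonization the identifiers either agree or
they do not, every link is explainable by the rule that produced it, and
failure modes surface as explicit quality flags rather than borderline
scores.

## Metadata extraction

DICOM Part-10 files are parsed by a streaming reader (explicit and implicit
little-endian transfer syntaxes, defined and undefined lengths). Only the
first two metadata levels are retained: top-level attributes (depth 0) and
attributes inside top-level sequence items (depth 1). Content nested deeper
is parsed and discarded; in practice the identifier-bearing attributes of
ophthalmic exports live at these two levels, and the flat tag map keeps
each tag key unique (first occurrence wins). Pixel data is seeked past, so
memory use is independent of image resolution.

Field conventions:

* the MRN is read from the `PatientID` attribute, its standard carrier;
* the image type (OCT, FAF, IR, COLOR, FA, ICGA, BR, OTHER) comes from a
  configurable mapping table over Modality / ImageType / SOP class /
  manufacturer, because vendors do not encode the category uniformly —
  unmapped combinations go to OTHER, never dropped;
* key-measurement files are recognized by the encapsulated-PDF SOP class
  and carry the referenced SOP instance UID of their source scan;
* one calendar acquisition date per patient defines one imaging visit;
* dates in DICOM `DA` form (`YYYYMMDD`) that fail to parse become missing
  values, not errors.

Imaging-side patients are deduplicated on (location, raw name, birthdate,
MRN). Consolidation is idempotent, and conflicting gender values within a
deduplicated identity keep the modal value with a logged conflict.

## Harmonization and exclusion flags

Both sides are normalized to one comparable identity: names are upper-cased,
single-spaced, assembled as `FAMILY GIVEN MIDDLE [SUFFIX]` from components
when available, with formatting punctuation (periods, commas, the PN caret)
removed; MRNs lose whitespace and leading zeros; gender maps to `M`/`F`/`O`;
dates become ISO. Normalization is idempotent, and missingness always
propagates — it never silently becomes a value.

One deliberate subtlety: digits and unexpected special characters in names
are *preserved* by normalization. The quality flags below must be able to
see them; a normalizer that scrubbed `#` or `2` out of a name would make the
corresponding exclusion rule unfireable and the quality report blind.

Three exclusion criteria mark records that cannot represent a real linkable
patient, in priority order (one flag per patient at most, so flag counts
partition the flagged set):

1. **Numeric or special-character names** — any digit in a name token, or
   any character outside upper-case letters, space, hyphen, apostrophe.
   Roman-numeral tokens (`HENRY DOE III`) are exempt: they are generational
   suffixes, not data-entry noise. The recognizer implements the canonical
   numeral grammar and is tested against exhaustive enumeration.
2. **Abnormal birthdates** — before 1900-01-01 or after the archive cutoff
   date (default: the newest acquisition date in the archive, since nobody
   can be born after their own scan).
3. **Test patients** — the phrase "test" in the name. By default a
   substring match (so `TESTER` flags); a word-boundary switch is available
   because real surnames can contain the substring.

Flagged patients stay in the linkage pass — they simply never find a
registry counterpart — and are removed from the *denominators* of the
cleaned rates, which is the arithmetic under which cleaned patient/image
rates are reproducible from cohort counts alone.

## The linkage engine

Four identifier combinations define a candidate link; all four include the
practice location:

| rule | fields |
|------|--------|
| R1 | location + name + birthdate + MRN |
| R2 | location + name + birthdate + gender |
| R3 | location + name + MRN |
| R4 | location + birthdate + MRN |

A rule is satisfied only when every field is present on both sides and
exactly equal after normalization; a missing field fails the rule rather
than wildcard-matching. This is the conservative reading: an absent MRN
must not let thousands of records agree vacuously. A pair connected by at
least one rule becomes a candidate edge weighted by the number of rules it
satisfies. The full normalized name is compared; a switch restricts the
comparison to family+given if a site's registry drops middle names.

**Blocking.** All-pairs comparison is quadratic and unnecessary: every rule
requires location plus at least one of name, birthdate, MRN, so candidate
generation joins only pairs sharing the location and one of those three
keys. This is provably equivalent to all-pairs evaluation — the test suite
checks the equivalence against a literal all-pairs oracle on full synthetic
cohorts.

**One-to-one resolution.** The candidate edges form a bipartite graph in
which an imaging patient may contest several registry patients and vice
versa. The resolver selects a matching that maximizes cardinality first
(link as many patients as possible) and total rule weight second (prefer
links supported by more evidence). The implementation decomposes the graph
into connected components and runs successive-shortest-path min-cost
augmentation with integer costs per component, which attains this
lexicographic optimum exactly; the test suite verifies optimality against
exhaustive enumeration on a thousand random instances. Edges are processed
in canonical key order, so the result is a pure function of the edge set —
permuting the input rows changes nothing. Two alternative modes exist: a
greedy heaviest-edge-first matcher (for comparison) and a strict mode that
drops every component whose optimum is attained by more than one matching,
for sites that prefer no link over an arbitrarily resolved tie.

**Propagation.** Every image of a linked patient is linked (no visit-level
gating — archives usually predate the registry, and discarding pre-registry
images would cost exactly the longitudinal depth the linkage is for). A
key-measurement document is linked iff its referenced SOP instance UID
identifies a linked OCT scan, from which it inherits the registry id;
references to absent UIDs are counted as dangling, never silently dropped.

## De-identification

Masking runs *after* linkage — the pipeline needs real identifiers to link,
then removes them. The PHI policy (a YAML file shipping with the package and
meant to be certified per site) maps tags to actions: `blank`,
`remove_value`, or `fixed_literal`. Masking preserves every tag's keyword
and VR at every nesting depth, so the multiset of (tag, VR) pairs — and
hence standards conformance — is untouched; only values change. Policies
naming linkage-critical UIDs (SOP/study/series instance UIDs) are rejected
outright, because masking them would orphan the measurement linkage.

The `PatientID` value is replaced by a token: HMAC-SHA-256 of the
identifier under a secret salt, truncated to 128 bits (32 hex characters).
The token is deterministic per (identifier, salt) — re-runs and incremental
loads agree — collision-free at any realistic cohort size, and reveals
nothing about the input. An empty salt is refused, since an unsalted hash of
a low-entropy identifier space is trivially reversible by enumeration. The
salt itself never appears in any output, log or manifest.

## Reporting

Rates are `100 * linked / total` with **half-up rounding** (not banker's
rounding): headline rates at 1 decimal, stratum rates at 2, matching how
such tables are conventionally printed. The cohort diagram carries initial
rates (full denominators) and cleaned rates (denominators minus flagged
patients/images, numerators unchanged).

Year strata group *images* by their patient's last imaging visit into
consecutive 12-month windows anchored at the archive cutoff, labelled
`YYYY-YYYY+1`; anchoring at the cutoff rather than calendar years makes the
newest window end exactly at the end of acquisition. Image-type strata count
*unique patients* per type, so a patient imaged with OCT and FAF appears in
both rows. Diagnosis cohorts take every linked patient whose registry record
carries a matching ICD code and count all of that patient's visits and
images — diagnosis attaches at the patient level, and multi-diagnosis
patients appear in several cohorts. The ICD sets ship as an editable YAML
approximation of common coding practice and should be replaced by a
site-certified list.

## The synthetic cohort generator

No real archive can ship with a package, so the generator emulates one, and
its defaults are the study conditions under which the tests run: two
practices; visits per patient from a shifted negative binomial with mean
4.6 and images per visit with mean 9 (≈ 41 image files per patient, the
scale of a multi-year retina archive); an image-type mix of FA 34%, IR 27%,
OCT 20%, COLOR 12%, FAF 5%, ICGA 1.4%, BR 0.6%; acquisition dates spanning
2014-01-01 to 2020-06-01; 10% of OCT scans carrying a key-measurement
document; per-field missingness of 1% (name), 2% (birthdate), 5% (gender),
10% (MRN) — metadata completeness problems concentrate in the MRN in
practice; 10% of clean imaging patients with no registry counterpart
(archives predate registries); and contamination of 4.3% numeric/special
names, 0.2% abnormal birthdates, 0.05% test names. Under these defaults the
pipeline's initial patient linkage rate lands in the mid-80s and the
cleaned rate in the high-80s, the regime the method is designed for.

Registry MRNs are stored without the zero-padding the imaging side uses,
and registry gender as `Female`/`Male` against DICOM's `F`/`M`, so the
generator exercises the harmonization layer rather than bypassing it.
Contaminated patients receive no registry counterpart and keep complete
fields, which makes planted-flag audits exact. Identities are unique per
location by construction, so with corruption disabled precision is exactly
1 — no rule can cross-link distinct identities.

What the generator does *not* model: real vendor-specific private tags,
typographical name variants (the pipeline is exact-match by design, so
fuzzy variants would only measure the generator), burned-in pixel
annotations, and visit-level registry structure. Passing tests therefore
demonstrate correctness of the mechanics — extraction, harmonization,
rules, matching, masking, arithmetic — not robustness to misspelled names,
which deterministic linkage does not claim.

`emit_dicom_fixtures()` writes each generated instance as a real Part-10
file (explicit VR little endian, tiny pixel payload, and a planted nested
sub-sequence so the two-level extraction rule is exercised), which lets the
whole pipeline run from actual files. `evaluate_linkage()` scores any link
result against the generator's ground truth (precision, recall, F1,
confusion counts).

## Numerical and degenerate-input choices

* Half-up rounding throughout the reporting surface; `round_half_up()`
  nudges by one ulp so that values stored infinitesimally below `.5`
  (decimal fractions have no exact binary form) round as printed.
* Matching tie-breaks: deterministic canonical-order processing; the strict
  mode detects genuine ambiguity by enumerating optimal matchings per
  component (components too large to enumerate are conservatively treated
  as ambiguous).
* Empty inputs (no files, empty registry, no edges) yield empty tables and
  zero counts, never errors; an undefined rate (zero denominator) is an
  error, not `NaN`.
* Records without a SOP instance UID are rejected with a logged reason —
  they can be neither deduplicated nor referenced by measurements.
* Unparseable dates become missing values; a missing birthdate can never
  satisfy a rule that needs one.

## Problem sizes used by the test suite

The suite runs synthetic cohorts of 1000 patients (≈ 40 000 image files)
for the recovery, bookkeeping and missingness-trend checks, 150–300
patients for module-level properties, 1000 random bipartite instances (≤ 8
nodes per side) against the exhaustive matching oracle, a 200-patient
cohort for the blocking-equivalence oracle, and 10^5 identifiers for the
token collision scan. These sizes were chosen so that every property that
scales (blocking soundness, matching optimality, flag partitioning) is
exercised well past its combinatorial edge cases while the whole suite
stays fast enough to run on every change.

## Known limitations

* Exact-match linkage: typos, nicknames and transliteration variants do not
  link; the quality report shows them as unlinked rather than guessing.
* The shipped PHI policy and ICD map are sensible defaults, not
  certifications; both are plain YAML precisely so a site can replace them.
* The DICOM writer emits explicit VR little endian with defined lengths
  only (the reader accepts more); compressed transfer syntaxes and
  pixel-data rewriting are out of scope.
* Burned-in annotations in pixel data are not scrubbed; masking operates on
  metadata only.
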