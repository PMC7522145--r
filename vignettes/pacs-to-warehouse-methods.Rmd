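---
title: "Methods: pseudonymized PACS-to-warehouse extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudonymized PACS-to-warehouse extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A hospital PACS (picture archiving and communication system) holds the
DICOM studies of essentially every patient, identified by the same
identifiers the hospital information system uses. A clinical research
data warehouse (DWH) holds pseudonymized routine data. Combining the two
— "find heart-failure patients with a CT study whose description
mentions the thorax, then export those images de-identified" — requires
a bridge that (a) queries and retrieves from the PACS with DICOM
query/retrieve semantics, (b) translates between PACS identifiers and
research pseudonyms without ever persisting the mapping on the bridge,
(c) strips identifying headers before anything reaches a researcher, and
(d) accounts honestly for what bulk extraction costs, because a PACS is
a production clinical system that cannot be bulk-copied casually.

`pacsdwh` implements that bridge end to end against a *synthetic*,
file-backed PACS: a generator produces a reproducible DICOM cohort on
disk and serves it through the same provider contract a networked DICOM
server adapter would implement, so every downstream component — client,
de-identifier, identity mapping, warehouse import, bulk extractor, ad
hoc service — is exercised exactly as it would be against a real
archive.

## The synthetic cohort

`cohort_spec()` describes a cohort; `sample_cohort()` draws its index
(patients, studies, series, images with all identifiers) and
`gen_cohort()` materializes it as DICOM Part 10 files plus plain-text
radiology-report stubs and a JSON index sidecar.

Counts are drawn hierarchically — studies per patient, series per
study, images per series — from rounded log-normal distributions
truncated at 1. The defaults are calibrated so a 1000-patient cohort
reproduces the per-patient shape reported for a university hospital's
production PACS:

| quantity | default | calibration target |
|---|---|---|
| patients with imaging | `p_has_imaging = 0.988` | 988 of 1000 detected |
| studies/patient | meanlog `log(3)`, sdlog 1.54 | median (quartiles) 3 (1–8) |
| series/study | meanlog `log(2.4)`, sdlog 0.80 | per-patient median 10 (3–29) series |
| images/series | meanlog `log(7.05)`, sdlog 0.90, patient effect sdlog 0.90 | per-patient median 103 images |
| payload/image | log-normal, median 566.4 KiB at `size_scale = 1` | full data set median 566.4 KiB |

The images-per-series draw carries a patient-level multiplicative
random effect: a patient's series tend to be jointly small (plain
radiographs) or jointly large (CT/MR volumes). Without it the
per-patient image distribution is far too narrow relative to its
median. With the chosen effect size the per-patient image count is
strongly right-skewed (cohort mean several times the median), though
the upper quartile remains below the extreme spread of real archives,
where single patients can exceed 30,000 images; the calibration
prioritizes stable medians, which is what the acceptance checks
measure. Medians of a 1000-patient draw vary by a few percent across
seeds; the documented tolerance for the calibration targets is ±20%.

Payload sizes default to `size_scale = 1/128` (test images around
64×64 pixels, 8-bit monochrome with a deterministic gradient pattern);
set `size_scale = 1` for realistic sizes. The log-normal payload model
uses sdlog 1.0 around the 566.4 KiB median; the strongly asymmetric
quartiles of real archives (437.9–2355.9 KiB) reflect a modality
mixture that the single distribution only approximates.

Two deliberate impurities emulate real archives:

* **External imports** — with `inconsistency_rate` (default 0.003, the
  order of the 0.264% unhandled-image rate reported for a production
  extraction) an image's *file header* carries a `SeriesInstanceUID`
  that disagrees with the PACS index, as happens with DICOM files
  imported from external hospitals whose identifiers were never
  rewritten. The index (what C-FIND answers) stays consistent; only
  full-data-set retrieval can expose the mismatch, which is why only
  extended-scope extraction quarantines such images.
* **Reports** — a deterministic fraction (`report_fraction = 0.8`) of
  studies gets a plain-text radiology-report stub named by its
  accession number, to exercise document linkage. Determinism (every
  fifth study lacks one) keeps fixtures reproducible.

The modality mix (CT 0.40, CR 0.30, MR 0.20, US 0.10) is an
assumption — production mixes are site-specific and not published for
the reference cohort — recorded here and in the spec object itself.

What the generator does **not** emulate: real pixel content (no
anatomy, no burned-in text — the ultrasound block is enforced by
modality code, not by image analysis), vendor-specific header variance,
implicit-VR or compressed transfer syntaxes, and the load behavior of a
production archive. Passing tests therefore demonstrate correctness of
the pipeline's logic, not performance or robustness against the full
diversity of real-world DICOM.

## Query/retrieve and the provider contract

`qr_provider()` exposes `find(level, filters)` and `retrieve(sop_uids)`.
`find` answers from the index and returns only the restricted header
whitelist (`basic_header_keys()`): identifiers, dates, descriptions,
modality, accession and instance numbers, study-related counts. This
mirrors the C-FIND situation, where only a restricted attribute set is
queryable; everything else (device, protocol, institution, patient
demographics) requires retrieving the complete data set, as C-MOVE
would. The contract is the seam where an adapter to a real networked
DICOM server would plug in; callers cannot tell the difference.

Conventions chosen where the behavior was genuinely open:

* Time ranges filter on **StudyDate** as a half-open interval
  `[from, to)`; dates carry no time of day. (Whether a production
  deployment filters on study or content date is site-specific.)
* Result ordering is deterministic: patient, study, series,
  InstanceNumber.
* `select_images()`: *first* is the minimal InstanceNumber; *middle* is
  position `ceiling(n/2)` in InstanceNumber order; ties and missing
  InstanceNumbers fall back to lexical SOPInstanceUID order and flag
  the result.
* Retrieval throttling (protecting the production PACS) is an optional
  fixed-window limiter with an injectable clock, off by default; the
  simulated clock makes its behavior testable without waiting.

## Identity management

The bridge translates between PACS identifiers and pseudonyms through a
connector contract with two directions (`to_pseudonyms`, `to_pacs_ids`)
and three namespaces: patient, instance UID, accession number. The
reference connector pseudonymizes with HMAC-SHA-256 under a site
secret: deterministic (stable joins across runs without any shared
state), not reversible without the secret, collisions detected and
fatal. Patient and accession pseudonyms are `PSN-`/`ACC-` plus 16 hex
digits; instance-UID pseudonyms are themselves valid UIDs under the
uuid-derived `2.25` arc so they can be written back into exported DICOM
files while preserving the study→series→image hierarchy.

Resolved mappings live only in a `transient_map` owned by the running
query and are released when it completes; `live_transient_maps()` makes
leak checking a one-liner, and the test suite asserts that a full
workload leaves zero live maps and that neither the serialized
warehouse nor the audit stream contains any raw PACS patient
identifier. The connector's own retained table models the trusted third
party (which, in production, is a separate service and *does* persist
the mapping); the bridge-side guarantee is about the bridge.

## De-identification

`anonymize()` removes a configured set of directly identifying headers
(name, birth date, addresses, other patient IDs/names,
referring/operating physician, institution address) and replaces the
linkage identifiers (PatientID, AccessionNumber, the three instance
UIDs) with pseudonyms. The removed set is configuration, not code: the
exact ruling belongs to a site's data protection officer. The operation
is atomic (an unresolvable pseudonym aborts without emitting a
partially de-identified record) and idempotent, because the
pseudonymizer recognizes and fixes its own outputs.

The modality policy is scoped precisely: **image retrieval** for
block-listed modalities (default: ultrasound, whose pixel data carries
burned-in identifying text) is denied; metadata operations are allowed
regardless, since the hazard lives in the pixels. The block is enforced
where researchers obtain images — the session-scoped ad hoc export —
and not inside bulk extraction, which runs under technical-staff
control and must visit the identical image set for every strategy for
the accounting comparison to be meaningful.

## The warehouse model

The DWH side is an entity-attribute-value store (single-file SQLite)
extended with two linkage levels: a **group** per DICOM image (all
header attributes of one image share its group) and a **document** —
the radiology report matched via the pseudonymized accession number
when one exists, else a synthetic per-study imaging document. Study-
and series-level descriptors are stored as rows of each image's group,
duplicated per image; hierarchical roll-up is left to export. That
duplication is a known modeling limitation, preferred here over
inventing a richer hierarchy the query side could not use.

Group identifiers are truncated SHA-256 digests of the three instance
UIDs joined with an unambiguous separator. Plain concatenation is
specifically avoided: it collapses distinct triples (the `("A|B","C")`
vs `("A","B|C")` class) and silently overwrites data — a failure mode
observed in practice and reproduced as a regression construction in the
tests. Re-import upserts on `(group_id, attribute)`; records whose file
header contradicts the hierarchy they were requested under are
quarantined with a reason and counted rather than imported or silently
dropped.

Values are typed text/number/date via a DICOM value-representation
mapping shipped as configuration; multi-valued attributes become one
row per value with an index suffix. Queries are conjunctive predicates
(equality, numeric comparison, date range, case-insensitive substring,
existence/non-existence) evaluated with patient-level set semantics: a
patient matches when each predicate is satisfied by at least one of
their groups or documents.

## Extraction strategies and accounting

Three strategies are first-class: `basic-first` (restricted headers,
first image per series), `basic-all` (restricted headers, every image)
and `extended-first` (full headers, first image per series, requires
retrieval). Their invariants — both first-image strategies visit
identical image sets; `basic-all` dominates `basic-first` per patient —
are asserted on every fixture. Extraction is single-threaded by
default; a production PACS should never see parallel bulk pressure.

Per-patient accounting counts bytes as serialized find-response sizes
plus retrieved file sizes, and seconds from an injectable clock.
Absolute wall-clock figures are hardware-bound and deliberately not
reproduced; what the package reproduces is the *arithmetic*: per-patient
distributions summarized as mean, median, quartiles (linear
interpolation between order statistics, `quantile` type 7 — the
convention is declared because the underlying per-patient data of the
reference evaluation is unpublished), minimum and maximum, and the
whole-hospital extrapolation

```
days = mean_seconds_per_patient × n_patients / 86400
```

rounded half-up to an integer. Fed with the published reference means
(`pacs_reference_stats`: 2.76 / 3.92 / 34.10 s per patient), 500,000
patients give 16 / 23 / 197 days — recomputed, not hard-coded, by
`scripts/acceptance.R` and the test suite.

## Sessions, audit and export

Every ad hoc operation runs inside a session created per DWH query,
holding an unguessable key and the patient pseudonyms of that query;
operations on any other patient are denied, and expiry (default 8 h —
a working day; the reference system does not state its value) is
enforced through the injected clock. Every service call appends exactly
one audit entry (timestamp, username, operation, pseudonymous
parameters, allow/deny); per-series modality denials within an image
export are recorded inside that call's entry and in the export
manifest, keeping the one-call-one-entry accounting exact. Exports
write anonymized Part 10 files or JPEG renderings (window level from
header WindowCenter/WindowWidth when present, else min/max scaling);
the manifest links every file to its warehouse group id so exported
images remain joinable to the metadata they came from. A wholly denied
request yields an explicit empty-export manifest, never silence.

## Problem sizes and numerical choices

The test suite runs against a 12-patient generated tree (~150 images at
`size_scale = 1/32`) for everything touching files, and against a
1000-patient sampled index (no files) for calibration checks — sizes
chosen so the full suite exercises every code path at comfortable
margins. Other fixed conventions: empty inputs are validation errors,
not empty successes, wherever the empty case is ambiguous
(`cohort_stats`, `select_images`, session creation); degenerate
window widths fall back to min/max scaling; generation restores the
caller's RNG state and derives every draw from the spec seed, so equal
spec and seed give byte-identical trees.

## Known limitations

* No real DICOM network layer (no association negotiation, C-GET or
  storage commitment); the provider contract is the integration seam.
* Reports are linkage stubs; no report text search or information
  extraction.
* No pixel-level redaction or OCR: burned-in-text risk is handled by
  modality blocking alone, exactly as scoped.
* The HTTP adapter of a deployment (same parameters, bearer secret
  shared with the DWH server) is intentionally out of scope; the
  functions here are the API it would wrap.
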