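---
title: "Rating confidence in synthesised qualitative findings with conqual"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rating confidence in synthesised qualitative findings with conqual}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conqual)
```

## The problem

Meta-aggregative qualitative systematic reviews end in *synthesised
findings*: review-level statements aggregating the findings of multiple
primary qualitative studies. Policy makers reading such a review need to
know how much trust to place in each synthesised finding, in the same way
GRADE ratings communicate confidence in the pooled results of quantitative
reviews. The ConQual approach fills that role for meta-aggregation. This
package implements it as a rule engine over a structured review document,
plus the Summary of Findings table that presents the result.

## The model

Confidence is expressed on the ordinal scale **High > Moderate > Low >
Very Low** (internally 4..1). No hierarchy of qualitative designs is
assumed, so every synthesised finding starts at **High** and is only ever
downgraded, on two components:

**Dependability** asks whether each primary study's research process is
logical, traceable and clearly documented. It is appraised per *study* with
five yes/no/unclear critical appraisal questions (`dependability_questions()`):
congruity of the methodology with (1) the research question, (2) the data
collection methods and (3) the representation and analysis of data; (4) a
statement locating the researcher culturally or theoretically; and (5)
whether the researcher's influence on the research is addressed. The
yes-count is banded: 4–5 yes, no change; 2–3 yes, down one level; 0–1 yes,
down two. Each finding inherits its parent study's band, and the synthesised
finding takes the band held by a strict majority of its constituent
findings.

**Credibility** rates the fit between each author finding and its supporting
illustration: *Unequivocal* (beyond reasonable doubt), *Equivocal*
(illustration lacking clear association), or *Unsupported* (not supported by
the data). The mix of levels within a synthesised finding sets the
downgrade: all unequivocal, 0; unequivocal/equivocal mix, −1; all equivocal,
−2; equivocal/unsupported mix, −3; all unsupported, −4.

The two downgrades are summed and applied once to the High baseline, and the
result is floored at Very Low. Equivalently, with dependability downgrade
$d \in \{0,1,2\}$ and credibility downgrade $c \in \{0,\dots,4\}$:

$$\mathrm{score} = \max(1,\; 4 - d - c).$$

## Design choices in paper-silent territory

The published rules leave several cases open; `conqual` resolves each the
conservative way (downgrade when in doubt, consistent with GRADE practice),
and these conventions are part of the package's contract:

* **"Unclear" responses count as not-yes.** An unclear response gives no
  evidence that a dependability criterion was met. The yes-count is what the
  banding rule consumes, so `no` and `unclear` are interchangeable there;
  both are preserved verbatim in the document schema.
* **Majority over findings, ties break upward.** Aggregation is over the
  constituent *findings* (each carrying its parent study's band). If no band
  holds a strict majority, the largest of the tied modal bands is used:
  `c(0, 0, 1, 1)` aggregates to 1, and a full three-way tie to 2.
* **Mixes are presence-based, not proportion-based.** One Equivocal finding
  among ten Unequivocal ones makes the mix unequivocal/equivocal (−1); the
  rules are stated by composition, not frequency.
* **Mixtures containing both Unequivocal and Unsupported findings** (with or
  without Equivocal) have no stated rule. They are mapped to −3: the
  presence of unsupported findings is treated as severely as the
  equivocal/unsupported mix, while −4 stays reserved for entirely
  unsupported syntheses.
* **The floor.** A total downgrade beyond three levels clamps at Very Low;
  the component magnitudes are still reported in full so nothing is hidden
  by the clamp.
* **A synthesised finding is never downgraded below what these two summed
  components imply** — in particular not to the band of its single worst
  study when that study is in the minority. Reviewers who consider one study
  disqualifying can exclude it upstream; the engine applies the stated rules
  only.

## The document schema and the worked example

Reviews are exchanged as JSON or YAML documents (formal schema in
`inst/schema/review-schema.json`): header metadata (title, population,
phenomena of interest, context), appraised `studies`, credibility-rated
`findings` with their illustrations, and `synthesised_findings` grouping
finding IDs. `load_review()` validates every structural invariant and
reports problems with the path of the offending element; `dump_review()`
serialises with fixed field order so round-trips are byte-stable. YAML bare
`yes`/`no` scalars are deliberately re-read as strings, not booleans, so
hand-written appraisals parse correctly.

The packaged worked example, `inst/extdata/imaging_review.json`, is a review
of the patient experience of high-technology medical imaging whose single
synthesised finding carries a one-level dependability downgrade (the
majority of studies had no statement locating the researcher and no
acknowledgement of their influence) and a one-level credibility downgrade (a
mix of unequivocal and equivocal findings), scoring **Low**. Only the header
metadata, the synthesised-finding statement (truncated in the published
table, kept verbatim) and those component downgrades are published;
the study-level appraisals, individual findings and illustrations in the
fixture are synthetic reconstructions chosen to reproduce exactly those
published downgrades and footnotes.

```{r worked-example}
doc <- load_review(system.file("extdata", "imaging_review.json",
                               package = "conqual"))
res <- score_review(doc)
res[[1]]
```

`build_sof()` then assembles the Summary of Findings table — header block,
one row per synthesised finding with "Downgrade N level(s)" / "No change"
cells, and dense `*`, `**`, ... footnote markers in order of first use
(rows sharing an identical rationale share a marker) — and `render_sof()`
writes it as a Markdown pipe table, an HTML5 fragment, or RFC 4180 CSV,
each deterministically. Footnote text is auto-composed from the downgrade
records (naming the most-often-unmet appraisal questions, or the credibility
mix) and can be overridden per synthesised finding and component.

## The synthetic generator, and what passing tests do and do not show

`generate_review()` emits schema-valid documents with placeholder text:
appraisal responses are i.i.d. yes with probability `p_yes` (default 0.5,
an uninformative prior over study quality; an optional `p_unclear` adds the
three-way split), credibility levels are drawn from `credibility_weights`
(default uniform), and findings are linked to studies round-robin (or
shuffled under the seed). Identical seed and configuration give
byte-identical documents, and generation never disturbs the caller's RNG
stream. Default sizes (5 studies, 12 findings, 3 synthesised findings) are
typical of a small meta-aggregative review.

The generator emulates the *structure* of a review, not its content:
findings are placeholder strings, appraisal responses are independent across
questions and studies, and credibility is independent of study quality. Real
reviews violate all three (e.g. poorly reported studies tend to fail several
questions together). Since the scoring rules consume only the yes-counts and
credibility levels — never the text or any correlation structure — passing
the simulated suites demonstrates the rule engine is correct over the whole
input space, but says nothing about the reliability of the human appraisal
judgements feeding it.

`enumerate_small_reviews()` complements the sampler with an exhaustive
enumeration of single-study reviews (yes-count 0..5 × credibility multisets
of up to 4 findings; multisets suffice because the rules are
permutation-invariant — 204 documents at the default bound). The test suite
scores all of them against an independently coded lookup-table oracle
(`max(1, 4 − d − c)` with hand-frozen band tables), checks the boundary
properties (all-yes + all-unequivocal ⇒ High; all-no + all-unsupported ⇒
Very Low) and permutation invariance over 1000 seeded random multi-study
reviews, and round-trips 100 seeded documents through both dialects. These
sizes run in seconds while covering every reachable rule combination.

## Limitations

* The engine scores documents; it does not perform meta-aggregation.
  Grouping findings into synthesised findings — and the appraisal and
  credibility judgements themselves — are expert input.
* Only the five dependability questions of the qualitative appraisal
  checklist are modelled, not the full instrument, and no alternative
  confidence frameworks (e.g. coherence-based ones) are implemented.
* Ordinal downgrading is deliberately coarse: two reviews with very
  different credibility *proportions* can receive the same score, a known
  property of presence-based mix categories.
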