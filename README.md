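# conqual

Confidence ratings for the synthesised findings of meta-aggregative
qualitative systematic reviews, using the ConQual approach — the qualitative
counterpart of a GRADE rating. The package is aimed at systematic reviewers
and methodologists who need a reproducible path from appraised studies and
credibility-rated findings to a final confidence score and a Summary of
Findings table.

## The rules

Every synthesised finding starts at **High** on the ordinal scale
High > Moderate > Low > Very Low and is downgraded on two components:

* **Dependability** — each study is appraised with five yes/no/unclear
  critical appraisal questions (methodology congruent with the research
  question, with data collection, and with analysis; researcher located
  culturally/theoretically; researcher influence addressed). The yes-count
  is banded (4–5 → no change, 2–3 → −1, 0–1 → −2); each finding inherits its
  study's band and the synthesised finding takes the majority band across
  its findings.
* **Credibility** — each finding is rated Unequivocal, Equivocal or
  Unsupported; the mix across the synthesised finding gives 0 (all
  unequivocal), −1 (unequivocal/equivocal mix), −2 (all equivocal),
  −3 (equivocal/unsupported mix) or −4 (all unsupported).

With dependability downgrade *d* and credibility downgrade *c*, the score is
`max(1, 4 − d − c)` on the 4 = High … 1 = Very Low scale. Tie-breaks and
paper-silent mixtures are resolved conservatively; see the methods vignette
(`vignettes/conqual-methods.Rmd`) for the full conventions.

## Worked example

The packaged document `inst/extdata/imaging_review.json` is a review of the
patient experience of high-technology medical imaging (study appraisals and
findings are synthetic reconstructions consistent with its published
summary):

```r
library(conqual)
doc <- load_review(system.file("extdata", "imaging_review.json",
                               package = "conqual"))
res <- score_review(doc)
res[[1]]
#> <conqual result> sf1: Low (dependability -1, credibility -1)
#>   - Downgraded one level due to common dependability issues across the
#>     included primary studies (most often unmet: q4 – Is there a statement
#>     locating the researcher culturally or theoretically; q5 – Is the
#>     influence of the researcher on the research, and vice-versa, addressed).
#>   - Downgraded one level due to a mix of unequivocal and equivocal findings.
```

The majority of the studies answered "yes" to only three of the five
dependability questions (−1), and the synthesised finding mixes unequivocal
and equivocal findings (−1), so the rating drops two levels from High to
**Low**. `build_sof(doc)` assembles the Summary of Findings table (header
metadata, one row per synthesised finding with footnoted downgrade cells)
and `render_sof()` writes it as Markdown, HTML or CSV.

The same workflow is available from the shell via the bundled CLI
(`exec/conqual` in the installed package):

```sh
conqual validate review.json
conqual score review.json --format csv
conqual sof review.json --output table.md
conqual simulate --seed 7 --output synthetic.yaml
```

`generate_review()` / `conqual simulate` produce seeded synthetic review
documents, and `enumerate_small_reviews()` enumerates every small
single-study review for exhaustive testing of the rule engine.

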