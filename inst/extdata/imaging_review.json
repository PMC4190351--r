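{
  "title": "The patient experience of high technology medical imaging: a systematic review of the qualitative evidence",
  "population": "persons who had undergone high technology medical imaging",
  "phenomena_of_interest": "the meaningfulness of a patients experience of undergoing diagnostic imaging using high technology",
  "context": "male and female adult patients presenting to a medical imaging department",
  "studies": [
    {
      "id": "s1",
      "citation": "Synthetic reconstruction: imaging-experience study 1",
      "appraisal": {"q1": "yes", "q2": "yes", "q3": "yes", "q4": "no", "q5": "no"}
    },
    {
      "id": "s2",
      "citation": "Synthetic reconstruction: imaging-experience study 2",
      "appraisal": {"q1": "yes", "q2": "yes", "q3": "yes", "q4": "no", "q5": "no"}
    },
    {
      "id": "s3",
      "citation": "Synthetic reconstruction: imaging-experience study 3",
      "appraisal": {"q1": "yes", "q2": "yes", "q3": "yes", "q4": "yes", "q5": "yes"}
    }
  ],
  "findings": [
    {
      "id": "f1",
      "study_id": "s1",
      "statement": "Patients approach the scan expecting that it will reveal the cause of their symptoms.",
      "illustration": "\"I was sure they would find something - that is why I was there.\"",
      "credibility": "Unequivocal"
    },
    {
      "id": "f2",
      "study_id": "s1",
      "statement": "Waiting for imaging results heightens anticipation of a diagnosis.",
      "illustration": "\"The days before the appointment were hard.\"",
      "credibility": "Equivocal"
    },
    {
      "id": "f3",
      "study_id": "s2",
      "statement": "The scanner environment reinforces the sense that an answer is imminent.",
      "illustration": "\"With all that technology around you, you think they must be able to see everything.\"",
      "credibility": "Unequivocal"
    },
    {
      "id": "f4",
      "study_id": "s3",
      "statement": "Patients frame the scan as the decisive step in their diagnostic journey.",
      "illustration": "\"Everything depended on what the scan would show.\"",
      "credibility": "Unequivocal"
    }
  ],
  "synthesised_findings": [
    {
      "id": "sf1",
      "statement": "People undergoing imaging often expect a health issue to be found during their scan, which can then",
      "finding_ids": ["f1", "f2", "f3", "f4"],
      "research_type": "Qualitative"
    }
  ]
}
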