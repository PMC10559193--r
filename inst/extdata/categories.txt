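# Research-priority categories in report order: the stakeholder-identified
# categories first (incarcerated people and prison health service directors),
# then the six author-created catch-all categories, with "Other" last.
# Categories with no assigned theme (e.g. Hygiene, Disability) are retained
# so the gap analysis can represent zero-output priorities.
Mental health
Health care service
Alcohol and other drug use
Education (from health to vocational)
Infectious disease and infections
Women's and maternal health
Social determinants of health
Disability
Nutrition
Hygiene
Cognitive and intellectual disability
Postrelease health maintenance
Aging prisoners
Workforce
Chronic health problems
Aboriginal prisoner health
Complex needs
Justice system
Biomedical related
Offense related
Juveniles
Behavior
Other
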