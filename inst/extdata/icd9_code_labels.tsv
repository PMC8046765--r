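code3	label
V65	Other persons seeking consultation
401	Essential hypertension
V04	Need for prophylactic vaccination and inoculation against certain diseases
272	Disorders of lipoid metabolism
V68	Encounters for administrative purposes
780	General symptoms
V72	Special investigations and examinations
786	Symptoms involving respiratory system and other chest symptoms
366	Cataract
367	Disorders of refraction and accommodation
719	Other and unspecified disorders of joint
V58	Encounter for other and unspecified procedures and aftercare
V70	General medical examination
715	Osteoarthrosis and allied disorders
V57	Care involving use of rehabilitation procedures
724	Other and unspecified disorders of back
782	Symptoms involving skin and other integumentary tissue
V81	Special screening for cardiovascular, respiratory, and genitourinary diseases
600	Hyperplasia of prostate
389	Hearing loss
530	Diseases of esophagus
427	Cardiac dysrhythmias
702	Other dermatoses
211	Benign neoplasm of other parts of digestive system
414	Other forms of chronic ischemic heart disease
411	Other acute and subacute forms of ischemic heart disease
357	Inflammatory and toxic neuropathy
250	Diabetes mellitus
584	Acute kidney failure
403	Hypertensive chronic kidney disease
511	Pleurisy
585	Chronic kidney disease
280	Iron deficiency anemias
276	Disorders of fluid electrolyte and acid-base balance
268	Vitamin D deficiency
041	Bacterial infection in conditions classified elsewhere and of unspecified site
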