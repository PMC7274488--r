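participant_id,icd10_code,diagnosis_date,histology_class,toxic_flag
p01,C73,2010-04-15,papillary,FALSE
p02,C73,2011-02-01,medullary,FALSE
p03,C73,2008-03-01,papillary,FALSE
p03,C73,2010-06-01,papillary,FALSE
p04,D34,2009-09-09,not_applicable,FALSE
p05,D34,2012-01-20,not_applicable,TRUE
p07,C73,2009-06-01,papillary,FALSE
p07,D34,2009-01-01,not_applicable,FALSE
p08,C73,2012-01-01,follicular,FALSE
p08,D34,2009-01-01,not_applicable,FALSE
p09,C50,2010-10-10,not_applicable,FALSE
p10,E03,2011-03-03,not_applicable,FALSE
p16,C73,2013-07-07,anaplastic,FALSE
p17,C73,2010-05-05,papillary,FALSE
p17,C73,2011-08-08,medullary,FALSE
p18,D34,2010-02-02,not_applicable,TRUE
p18,D34,2011-04-04,not_applicable,FALSE
p19,C73,2009-11-11,lymphoma,FALSE
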