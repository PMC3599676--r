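# Regulator drug-label changes (2009), drug_id <TAB> event_id.
# DB00073 = rituximab, DB00095 = efalizumab, DB00108 = natalizumab
# 10036807 = progressive multifocal leukoencephalopathy
# 10020751 = hypersensitivity
DB00073	10036807
DB00095	10036807
DB00108	10020751
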