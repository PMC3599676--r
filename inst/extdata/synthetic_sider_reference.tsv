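# Synthetic stand-in for a drug-label side-effect reference (SIDER-style),
# drug_id <TAB> event_id, in DrugBank / MedDRA-code identifier space.
# Constructed for examples and tests: it lists a few leaflet-known adverse
# events of three monoclonal antibodies and deliberately lacks the
# label-change pairs that only appeared on leaflets later.
# DB00073 = rituximab, DB00095 = efalizumab, DB00108 = natalizumab
DB00073	10016558
DB00073	10022891
DB00073	10037660
DB00095	10019211
DB00095	10022891
DB00108	10019211
DB00108	10022004
DB00108	10037660
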