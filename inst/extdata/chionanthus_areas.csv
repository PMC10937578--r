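quantity,km2
priority_area,385000
reserve_overlap,19300
reserves_total,1265400
study_area,9600000
total_suitable_current,1739200
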