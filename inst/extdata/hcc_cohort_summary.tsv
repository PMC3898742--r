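quantity	count
total_detected	7689
putative_germline	7644
single_individual_germline	2241
both_end_detected	1489
tumor_specific_candidate_l1	17
tumor_specific_candidate_alu	27
tumor_specific_candidate_sva	1
validated_tumor_specific_l1	12
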